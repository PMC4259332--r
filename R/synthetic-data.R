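# Synthetic tiling-array data: probe design, an origin-firing /
# fork-progression model for BrdU incorporation under HU, and a Gaussian-peak
# model for ORC ChIP signal. Tracks are generated in the REFERENCE coordinate
# frame: the array probes are designed against the reference sequence, so in
# an edited genotype probes overlapping removed spans report background only.

#' Simulation configuration
#'
#' @param fork_speed Replication fork speed in kb/min under HU (default 0.1;
#'   HU-stalled forks travel only a few kb in an hour).
#' @param t_total Labelling time in minutes after G1 release (default 60).
#' @param hu_mM HU concentration label carried into metadata (default 200).
#' @param orc_peak_sd Gaussian sd of ORC ChIP peaks in bp (default 125, half
#'   the 250 bp average sonication fragment size).
#' @param background_level Baseline log2 ratio of both assays (default 0.3).
#' @param noise_sd Probe-level Gaussian noise sd in log2 units (default 0.1).
#' @param brdu_gain log2 enrichment of a fully replicated position (default 2).
#' @param residual_k Number of jittered sub-origins carrying residual
#'   initiation near a deleted origin (default 3).
#' @param residual_jitter_bp Maximal sub-origin offset from the deleted origin
#'   midpoint before reflection outside the removed span (default 2000).
#' @param telomere_artifact If `TRUE`, adds the cross-hybridization bump near
#'   the chrVI left telomere (default `FALSE`).
#' @param seed Base RNG seed; every track derives its own stream from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fork_speed = 0.1, t_total = 60, hu_mM = 200,
                       orc_peak_sd = 125, background_level = 0.3,
                       noise_sd = 0.1, brdu_gain = 2, residual_k = 3L,
                       residual_jitter_bp = 2000, telomere_artifact = FALSE,
                       seed = 1L) {
  stopifnot(fork_speed > 0, t_total > 0, orc_peak_sd > 0, noise_sd >= 0,
            brdu_gain >= 0, residual_k >= 1, residual_jitter_bp >= 0)
  structure(list(fork_speed = fork_speed, t_total = t_total, hu_mM = hu_mM,
                 orc_peak_sd = orc_peak_sd, background_level = background_level,
                 noise_sd = noise_sd, brdu_gain = brdu_gain,
                 residual_k = as.integer(residual_k),
                 residual_jitter_bp = residual_jitter_bp,
                 telomere_artifact = telomere_artifact,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Design a tiling probe set
#'
#' Deterministic tiling from position 1 with fixed step; consecutive probes
#' overlap by `probe_length - step` bp (50-mers at step 8 give the 42 bp
#' average overlap of the emulated array). Both array strands are collapsed to
#' one forward-coordinate probe set.
#'
#' @param genome A [genome_model()] or a named vector of chromosome lengths.
#' @param probe_length Probe length in bp (default 50).
#' @param step Start-to-start distance in bp (default 8).
#' @return Named list with one `probe_set` (fields `chrom`, `starts`,
#'   `probe_length`) per chromosome.
#' @examples
#' design_probes(c(toy = 1000))$toy  # 119 probes
#' @export
design_probes <- function(genome, probe_length = 50, step = 8) {
  lens <- if (inherits(genome, "genome_model")) genome$chromosomes else genome
  if (is.null(names(lens))) stop("chromosome lengths must be named")
  stopifnot(step >= 1, probe_length >= 1)
  out <- lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    if (step >= L) stop("step (", step, ") must be smaller than ", ch,
                        " length (", L, ")")
    if (probe_length > L) stop("probe_length exceeds ", ch, " length")
    structure(list(chrom = ch,
                   starts = seq(1, L - probe_length + 1, by = step),
                   probe_length = probe_length),
              class = "probe_set")
  })
  stats::setNames(out, names(lens))
}

#' @export
print.probe_set <- function(x, ...) {
  step <- if (length(x$starts) > 1) x$starts[2] - x$starts[1] else NA
  cat(sprintf("probe_set %s: %d probes of %d bp, step %s (overlap %s bp)\n",
              x$chrom, length(x$starts), x$probe_length, format(step),
              format(x$probe_length - step)))
  invisible(x)
}

fork_reach_bp <- function(cfg, fire_time) {
  pmax(0, 1000 * cfg$fork_speed * (cfg$t_total - fire_time))
}

#' Fraction of cells having replicated a position
#'
#' Deterministic fork model under HU: an origin that fired at `fire_time`
#' reaches all positions within `fork_speed * (t_total - fire_time)` of its
#' midpoint; origins fire independently with their efficiencies, so
#' `f(x) = 1 - prod_i (1 - efficiency_i * reach_i(x))`. Converging-fork
#' interactions are ignored (fork travel under HU is short relative to
#' inter-origin spacing).
#'
#' @param x Positions in bp.
#' @param origins A data.frame with columns `position`, `efficiency`,
#'   `fire_time` (e.g. from [initiation_sites()]).
#' @param cfg A [sim_config()].
#' @return Replicated fraction in `[0, 1]` per position.
#' @export
replication_fraction <- function(x, origins, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  log_surv <- numeric(length(x))
  for (i in seq_len(NROW(origins))) {
    reach <- fork_reach_bp(cfg, origins$fire_time[i])
    hit <- abs(x - origins$position[i]) <= reach
    if (any(hit) && origins$efficiency[i] > 0)
      log_surv[hit] <- log_surv[hit] + log1p(-origins$efficiency[i])
  }
  1 - exp(log_surv)
}

#' Effective initiation sites of a genotype
#'
#' Intact origins initiate at their locus midpoint with their annotated
#' efficiency. A deleted origin retains residual initiation at `residual_k`
#' jittered sub-origins, each carrying `residual_fraction * efficiency /
#' residual_k`; jittered positions are drawn within `residual_jitter_bp` of
#' the locus midpoint and reflected to just outside the removed span (offset
#' preserved relative to the span boundary), since only sequence that still
#' exists in the mutant can initiate. Consumes the current RNG stream.
#'
#' @param genome A [genome_model()].
#' @param chrom Chromosome to expand.
#' @param cfg A [sim_config()].
#' @return data.frame with columns `position`, `efficiency`, `fire_time`,
#'   `origin`.
#' @export
initiation_sites <- function(genome, chrom, cfg) {
  o <- genome$origins[genome$origins$chrom == chrom, , drop = FALSE]
  if (nrow(o) == 0)
    return(data.frame(position = numeric(), efficiency = numeric(),
                      fire_time = numeric(), origin = character()))
  rows <- lapply(seq_len(nrow(o)), function(i) {
    mid <- (o$start[i] + o$end[i]) / 2
    if (o$status[i] == "intact") {
      data.frame(position = mid, efficiency = o$efficiency[i],
                 fire_time = o$fire_time[i], origin = o$name[i])
    } else {
      k <- cfg$residual_k
      off <- stats::runif(k, -cfg$residual_jitter_bp, cfg$residual_jitter_bp)
      e <- genome$edits[genome$edits$origin == o$name[i], , drop = FALSE]
      pos <- mid + off
      if (nrow(e) == 1) {
        pos <- ifelse(off <= 0, e$start - 1 + off, e$end + 1 + off)
      }
      pos <- pmax(1, pmin(pos, genome$chromosomes[[chrom]]))
      data.frame(position = round(pos),
                 efficiency = o$residual_fraction[i] * o$efficiency[i] / k,
                 fire_time = o$fire_time[i], origin = o$name[i])
    }
  })
  do.call(rbind, rows)
}

# Deterministic per-track RNG stream: a polynomial hash of the assay, the
# chromosome and the genome's edit table, combined with the base seed. Keyed
# on the edit set (not the genotype label) so that an edit-free "mutant" is
# bit-identical to the reference, while any real edit decorrelates the arrays.
seed_stream <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

genome_key <- function(genome) {
  if (nrow(genome$edits) == 0) return("ref")
  paste(genome$edits$origin, genome$edits$start, genome$edits$end,
        sep = ":", collapse = ";")
}

masked_probes <- function(genome, probes) {
  e <- genome$edits[genome$edits$chrom == probes$chrom, , drop = FALSE]
  m <- rep(FALSE, length(probes$starts))
  pend <- probes$starts + probes$probe_length - 1
  for (i in seq_len(nrow(e)))
    m <- m | (probes$starts <= e$end[i] & pend >= e$start[i])
  m
}

#' Simulate a BrdU-IP replication track
#'
#' Probe value = `background_level + brdu_gain * f(midpoint) + N(0, noise_sd)`
#' with `f` from [replication_fraction()] over the genotype's effective
#' initiation sites. Probes overlapping removed spans report background plus
#' noise only (the mutant lacks those sequences). Reproducible: the same seed
#' and configuration give a bit-identical track.
#'
#' @param genome A [genome_model()] (edited or not).
#' @param probes A `probe_set` from [design_probes()].
#' @param cfg A [sim_config()].
#' @return A [probe_track()] with assay metadata.
#' @export
simulate_brdu_track <- function(genome, probes, cfg) {
  stopifnot(inherits(genome, "genome_model"), inherits(probes, "probe_set"),
            inherits(cfg, "sim_config"))
  set.seed(seed_stream(cfg$seed, "brdu", probes$chrom, genome_key(genome)))
  sites <- initiation_sites(genome, probes$chrom, cfg)
  mid <- probes$starts + (probes$probe_length - 1) / 2
  v <- cfg$background_level +
    cfg$brdu_gain * replication_fraction(mid, sites, cfg)
  v[masked_probes(genome, probes)] <- cfg$background_level
  if (isTRUE(cfg$telomere_artifact) && probes$chrom == "chrVI")
    v[mid <= 4000] <- v[mid <= 4000] + 1
  v <- v + stats::rnorm(length(v), 0, cfg$noise_sd)
  probe_track(probes$chrom, probes$starts, v,
              probe_length = probes$probe_length,
              metadata = list(assay = "BrdU-IP", genotype = genome$label,
                              hu_mM = cfg$hu_mM, t_total = cfg$t_total,
                              seed = cfg$seed))
}

#' Simulate an ORC ChIP track
#'
#' Probe value = `background_level + sum_i h_i exp(-(x - pos_i)^2 /
#' (2 orc_peak_sd^2)) + N(0, noise_sd)` at probe midpoints, with
#' `h_i = residual_fraction * orc_height` for deleted origins (residual ORC
#' binding persists on the flanking sequence). Probes overlapping removed
#' spans report background plus noise only. Gaussians are truncated at
#' 6 standard deviations.
#'
#' @inheritParams simulate_brdu_track
#' @return A [probe_track()] with assay metadata.
#' @export
simulate_orc_track <- function(genome, probes, cfg) {
  stopifnot(inherits(genome, "genome_model"), inherits(probes, "probe_set"),
            inherits(cfg, "sim_config"))
  set.seed(seed_stream(cfg$seed, "orc", probes$chrom, genome_key(genome)))
  o <- genome$origins[genome$origins$chrom == probes$chrom, , drop = FALSE]
  mid <- probes$starts + (probes$probe_length - 1) / 2
  v <- rep(cfg$background_level, length(mid))
  for (i in seq_len(nrow(o))) {
    h <- if (o$status[i] == "deleted")
      o$residual_fraction[i] * o$orc_height[i] else o$orc_height[i]
    pos <- (o$start[i] + o$end[i]) / 2
    w <- which(abs(mid - pos) <= 6 * cfg$orc_peak_sd)
    v[w] <- v[w] + h * exp(-(mid[w] - pos)^2 / (2 * cfg$orc_peak_sd^2))
  }
  v[masked_probes(genome, probes)] <- cfg$background_level
  v <- v + stats::rnorm(length(v), 0, cfg$noise_sd)
  probe_track(probes$chrom, probes$starts, v,
              probe_length = probes$probe_length,
              metadata = list(assay = "Orc2-ChIP", genotype = genome$label,
                              seed = cfg$seed))
}
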