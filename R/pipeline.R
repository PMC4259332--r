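# End-to-end orchestration: simulate -> condition -> normalize -> compare ->
# call -> report, as a reproducible seeded run.

#' Pipeline run configuration
#'
#' @param genome Reference [genome_model()] (default [yeast_model()]).
#' @param edits Edit table applied to form the mutant genotype (default
#'   [ori7_edits()]; pass an empty table for a no-edit control run).
#' @param chroms Chromosomes to process (default chrVI plus the chrIII no-edit
#'   control; chrXII is omitted from the default run).
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param probe_length,step Probe design (default 50-mers, step 8).
#' @param window_bp Pseudomedian window (default 50 bp).
#' @param biweight_c Biweight tuning constant (default 5).
#' @param min_height Peak threshold; `NULL` for the noise-relative default.
#' @param min_separation_bp Minimal peak separation (default 1000).
#' @param assign_radius_bp Origin-assignment radius (default 5000).
#' @param outdir Output directory.
#' @param seed Run seed (drives every stochastic stage).
#' @return An object of class `run_config`.
#' @export
run_config <- function(genome = yeast_model(), edits = ori7_edits(),
                       chroms = c("chrVI", "chrIII"), sim = sim_config(),
                       probe_length = 50, step = 8, window_bp = 50,
                       biweight_c = 5, min_height = NULL,
                       min_separation_bp = 1000, assign_radius_bp = 5000,
                       outdir = tempfile("oritrack_run"), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(sim, "sim_config"))
  missing_ch <- setdiff(chroms, names(genome$chromosomes))
  if (length(missing_ch))
    stop("chromosome not in genome model: ", paste(missing_ch, collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(genome = genome, edits = edits, chroms = chroms, sim = sim,
                 probe_length = probe_length, step = step,
                 window_bp = window_bp, biweight_c = biweight_c,
                 min_height = min_height,
                 min_separation_bp = min_separation_bp,
                 assign_radius_bp = assign_radius_bp, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Hash of a run configuration
#'
#' Non-cryptographic polynomial hash of the JSON-serialized configuration
#' (output directory excluded); embedded in every output header so results can
#' be matched to the exact parameter set that produced them.
#'
#' @param config A [run_config()].
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  x$sim <- unclass(x$sim)
  x$genome <- list(chromosomes = x$genome$chromosomes,
                   origins = x$genome$origins, edits = x$genome$edits,
                   background = x$genome$background)
  js <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  h <- 0
  for (cc in utf8ToInt(js)) h <- (h * 31 + cc) %% 2147483647
  sprintf("%08x", h)
}

process_track <- function(raw, config, normalize = FALSE) {
  t <- biweight_adjust(raw, c = config$biweight_c)
  t <- pseudomedian_filter(t, window_bp = config$window_bp)
  if (normalize) t <- background_normalize(t, config$genome$background)
  t
}

stage_log <- function(stage, detail) {
  message(sprintf("[oritrack] %-12s %s", stage, detail))
}

#' Run the full analysis pipeline
#'
#' For the reference and edited genotypes on each configured chromosome:
#' simulates raw Orc2 ChIP and BrdU-IP tracks, conditions them (biweight
#' centring, pseudomedian smoothing; BrdU additionally background-normalized),
#' forms the wild-type minus mutant ORC difference track, detects depletion
#' sites, calls and classifies BrdU initiation peaks, and writes a per-origin
#' summary TSV. Deterministic given the configuration seed.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `paths` (named vector of output files),
#'   `summary` (per-origin data.frame), `peaks`, `depletion` (per-chromosome
#'   lists) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  wt <- config$genome
  mut <- apply_edits(wt, config$edits,
                     label = if (NROW(config$edits)) "7oriD" else wt$label)$genome
  probes <- design_probes(wt, config$probe_length, config$step)
  paths <- character(0)
  save_track <- function(track, name) {
    track$metadata$config <- hash
    p <- file.path(config$outdir, paste0(name, ".bedGraph"))
    write_bedgraph(track, p)
    paths[name] <<- p
    track
  }
  processed <- list()
  for (tag in c("wt", "mut")) {
    g <- if (tag == "wt") wt else mut
    for (ch in config$chroms) {
      stage_log("simulate", paste(tag, ch))
      orc <- simulate_orc_track(g, probes[[ch]], config$sim)
      brdu <- simulate_brdu_track(g, probes[[ch]], config$sim)
      save_track(orc, sprintf("%s_%s_orc_raw", tag, ch))
      save_track(brdu, sprintf("%s_%s_brdu_raw", tag, ch))
      stage_log("process", paste(tag, ch))
      processed[[paste(tag, ch, "orc")]] <-
        save_track(process_track(orc, config), sprintf("%s_%s_orc", tag, ch))
      processed[[paste(tag, ch, "brdu")]] <-
        save_track(process_track(brdu, config, normalize = TRUE),
                   sprintf("%s_%s_brdu", tag, ch))
    }
  }
  depletion <- list()
  brdu_peaks <- list()
  for (ch in config$chroms) {
    stage_log("compare", ch)
    d <- difference_track(processed[[paste("wt", ch, "orc")]],
                          processed[[paste("mut", ch, "orc")]])
    save_track(d, sprintf("orc_diff_%s", ch))
    depletion[[ch]] <- detect_depletion(d, mut, min_height = config$min_height,
                                        min_separation_bp = config$min_separation_bp,
                                        assign_radius_bp = config$assign_radius_bp)
    stage_log("peaks", ch)
    pk <- call_peaks(processed[[paste("mut", ch, "brdu")]],
                     min_height = config$min_height,
                     min_separation_bp = config$min_separation_bp)
    brdu_peaks[[ch]] <- classify_peaks(pk, mut, config$assign_radius_bp)
    write_peaks(depletion[[ch]],
                bed_path = file.path(config$outdir,
                                     sprintf("depletion_%s.bed", ch)),
                tsv_path = file.path(config$outdir,
                                     sprintf("depletion_%s.tsv", ch)))
    write_peaks(brdu_peaks[[ch]],
                bed_path = file.path(config$outdir,
                                     sprintf("brdu_peaks_%s.bed", ch)),
                tsv_path = file.path(config$outdir,
                                     sprintf("brdu_peaks_%s.tsv", ch)))
    paths[sprintf("depletion_%s", ch)] <-
      file.path(config$outdir, sprintf("depletion_%s.tsv", ch))
    paths[sprintf("brdu_peaks_%s", ch)] <-
      file.path(config$outdir, sprintf("brdu_peaks_%s.tsv", ch))
  }
  summary_df <- origin_summary(mut, config, depletion, brdu_peaks)
  sp <- file.path(config$outdir, "summary.tsv")
  utils::write.table(summary_df, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["summary"] <- sp
  stage_log("report", sp)
  structure(list(paths = paths, summary = summary_df, peaks = brdu_peaks,
                 depletion = depletion, config = config, hash = hash),
            class = "run_report")
}

origin_summary <- function(mut, config, depletion, brdu_peaks) {
  o <- mut$origins[mut$origins$chrom %in% config$chroms, , drop = FALSE]
  o <- o[order(o$chrom, o$start), , drop = FALSE]
  rows <- lapply(seq_len(nrow(o)), function(i) {
    dep <- depletion[[o$chrom[i]]]
    hit <- which(!is.na(dep$nearest_origin) & dep$nearest_origin == o$name[i] &
                   dep$distance_to_origin <= config$assign_radius_bp)
    dep_h <- if (length(hit)) max(dep$height[hit]) else NA_real_
    pk <- brdu_peaks[[o$chrom[i]]]
    d <- if (nrow(pk)) origin_distance(pk$summit, o[i, ]) else numeric(0)
    near <- which(d <= config$assign_radius_bp)
    has_pk <- length(near) > 0
    best <- if (has_pk) near[which.max(pk$height[near])] else NA
    data.frame(origin = o$name[i], chrom = o$chrom[i], status = o$status[i],
               orc_depletion_height = round(dep_h, 6),
               brdu_peak = has_pk,
               brdu_summit = if (has_pk) pk$summit[best] else NA_real_,
               brdu_label = if (has_pk) pk$label[best] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.run_report <- function(x, ...) {
  cat("oritrack run", x$hash, "->", x$config$outdir, "\n")
  cat(length(x$paths), "output files; per-origin summary:\n")
  print(x$summary)
  invisible(x)
}

#' Write the packaged small test fixtures
#'
#' Writes the chromosome VI annotation BED (plus background regions and the
#' deletion-edit table), a 200 kb toy chromosome annotation, and tiny seeded
#' bedGraph tracks. Deterministic: rerunning reproduces identical bytes.
#'
#' @param outdir Target directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gm <- yeast_model()
  p <- c(origins = file.path(outdir, "chrVI_origins.bed"),
         background = file.path(outdir, "background.bed"),
         edits = file.path(outdir, "ori7_edits.tsv"),
         toy_origins = file.path(outdir, "toy_origins.bed"),
         toy_track = file.path(outdir, "toy_brdu.bedGraph"))
  write_bed(gm$origins[gm$origins$chrom == "chrVI", ], p[["origins"]])
  write_bed(gm$background, p[["background"]])
  write_edit_table(ori7_edits(), p[["edits"]])
  toy <- genome_model(c(toy = 200000),
                      origin_annotations(c("ORI_A", "ORI_B"), "toy",
                                         c(49900, 149900), c(50100, 150100),
                                         efficiency = c(0.9, 0.5)),
                      label = "toy")
  write_bed(toy$origins, p[["toy_origins"]])
  cfg <- sim_config(seed = 404, noise_sd = 0.05)
  probes <- design_probes(toy, step = 200)$toy  # sparse probes: small file
  write_bedgraph(simulate_brdu_track(toy, probes, cfg), p[["toy_track"]])
  invisible(p)
}
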