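# Peak calling on processed tracks, classification against the origin
# annotation, and ORC-depletion detection on difference tracks.

#' Robust noise scale of a track
#'
#' Estimated from probe-value differences at a lag of about one smoothing
#' window (so the two probes of each pair carry independent noise even after
#' sliding-window filtering): `mad(x[i + L] - x[i]) / sqrt(2)`. Lagged
#' differencing cancels the slowly varying biological signal, so the estimate
#' is not inflated when replicated regions cover a large share of the
#' chromosome.
#'
#' @param track A [probe_track()].
#' @param lag_bp Difference lag in bp (default 50, the smoothing window).
#' @return Noise standard-deviation estimate (log2 units).
#' @export
noise_scale <- function(track, lag_bp = 50) {
  stopifnot(inherits(track, "probe_track"))
  v <- track$values
  if (length(v) < 3) return(0)
  spacing <- stats::median(diff(track$positions))
  L <- max(1L, as.integer(ceiling(lag_bp / spacing)))
  L <- min(L, length(v) - 1L)
  d <- v[-seq_len(L)] - v[seq_len(length(v) - L)]
  stats::mad(d) / sqrt(2)
}

empty_peaks <- function(chrom = character()) {
  structure(data.frame(chrom = chrom, summit = numeric(0), height = numeric(0),
                       start = numeric(0), end = numeric(0),
                       label = character(0), nearest_origin = character(0),
                       distance_to_origin = numeric(0),
                       stringsAsFactors = FALSE),
            class = c("peak_set", "data.frame"))
}

#' Call peaks on a processed track
#'
#' Local maxima (plateaus report their leftmost probe) with value at least
#' `min_height` are selected greedily by height subject to summits being at
#' least `min_separation_bp` apart, then returned sorted by position. Peak
#' extent (`start`, `end`) is the contiguous run around the summit where the
#' value stays at or above half the peak height.
#'
#' The default threshold is `5 * noise_scale(track)`: with tens of thousands
#' of probes per chromosome a 3-sigma cut would admit several spurious noise
#' maxima per track, while five sigma keeps the expected family-wise false
#' call count well below one.
#'
#' @param track A [probe_track()] (smoothed; BrdU tracks normalized).
#' @param min_height Minimum summit value; `NULL` for the noise-relative
#'   default.
#' @param min_separation_bp Minimal summit-to-summit distance (default 1000).
#' @return A `peak_set` data.frame with columns `chrom`, `summit`, `height`,
#'   `start`, `end`, `label`, `nearest_origin`, `distance_to_origin` (labels
#'   `NA` until [classify_peaks()]).
#' @export
call_peaks <- function(track, min_height = NULL, min_separation_bp = 1000) {
  stopifnot(inherits(track, "probe_track"))
  if (is.null(min_height)) min_height <- 5 * noise_scale(track)
  v <- track$values
  p <- track$positions
  r <- rle(v)
  nr <- length(r$values)
  if (nr < 2) return(empty_peaks())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prev <- c(Inf * -1, r$values[-nr])
  nxt <- c(r$values[-1], -Inf)
  prev[1] <- -Inf
  is_max <- r$values > prev & r$values > nxt
  cand <- starts[is_max & r$values >= min_height]  # leftmost probe of plateau
  if (!length(cand)) return(empty_peaks())
  cand <- cand[order(-v[cand], p[cand])]
  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) ||
        all(abs(p[i] - p[accepted]) >= min_separation_bp))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  bounds <- vapply(accepted, function(i) {
    half <- v[i] / 2
    l <- i
    while (l > 1 && v[l - 1] >= half) l <- l - 1
    u <- i
    while (u < length(v) && v[u + 1] >= half) u <- u + 1
    c(p[l], p[u])
  }, numeric(2))
  structure(data.frame(chrom = track$chrom, summit = p[accepted],
                       height = v[accepted], start = bounds[1, ],
                       end = bounds[2, ], label = NA_character_,
                       nearest_origin = NA_character_,
                       distance_to_origin = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("peak_set", "data.frame"))
}

origin_distance <- function(summit, o) {
  pmax(0, pmax(o$start - summit, summit - o$end))
}

#' Classify peaks against the origin annotation
#'
#' A peak is `canonical` when the nearest origin within `assign_radius_bp` is
#' intact, `residual` (non-canonical initiation near a deleted origin) when it
#' is deleted, and `novel` when no origin lies within the radius. Distance is
#' measured from the summit to the origin locus interval (zero inside it; for
#' deleted origins the locus is the removed span); ties are broken toward the
#' closer locus midpoint, then lexicographically by name.
#'
#' @param peaks A `peak_set` from [call_peaks()].
#' @param genome A [genome_model()] sharing the peak coordinates.
#' @param assign_radius_bp Assignment radius in bp (default 5000).
#' @return The `peak_set` with `label`, `nearest_origin` and
#'   `distance_to_origin` filled.
#' @export
classify_peaks <- function(peaks, genome, assign_radius_bp = 5000) {
  stopifnot(inherits(genome, "genome_model"))
  if (nrow(peaks) == 0) return(peaks)
  for (i in seq_len(nrow(peaks))) {
    o <- genome$origins[genome$origins$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(o)) {
      d <- origin_distance(peaks$summit[i], o)
      dmid <- abs(peaks$summit[i] - (o$start + o$end) / 2)
      ord <- order(d, dmid, o$name)
      if (d[ord[1]] <= assign_radius_bp) {
        j <- ord[1]
        peaks$nearest_origin[i] <- o$name[j]
        peaks$distance_to_origin[i] <- d[j]
        peaks$label[i] <- if (o$status[j] == "deleted") "residual" else "canonical"
        next
      }
    }
    peaks$label[i] <- "novel"
  }
  peaks
}

#' Detect ORC-depletion sites on a difference track
#'
#' Calls peaks on a wild-type minus mutant ORC difference track (peaks mark
#' binding lost in the mutant) and annotates each with the nearest deleted
#' origin. Deleted origins with no depletion peak within `assign_radius_bp`
#' are reported in the `misses` attribute.
#'
#' @param diff_track Difference track from [difference_track()] (WT - mutant).
#' @param genome The edited [genome_model()] carrying deleted-origin flags.
#' @param min_height,min_separation_bp As in [call_peaks()].
#' @param assign_radius_bp Radius for origin assignment and miss reporting.
#' @return A `peak_set` with `nearest_origin`/`distance_to_origin` referring
#'   to deleted origins only and attribute `misses` (character vector of
#'   deleted origins without a depletion peak).
#' @export
detect_depletion <- function(diff_track, genome, min_height = NULL,
                             min_separation_bp = 1000,
                             assign_radius_bp = 5000) {
  stopifnot(inherits(genome, "genome_model"))
  peaks <- call_peaks(diff_track, min_height = min_height,
                      min_separation_bp = min_separation_bp)
  del <- genome$origins[genome$origins$chrom == diff_track$chrom &
                          genome$origins$status == "deleted", , drop = FALSE]
  if (nrow(peaks)) {
    peaks$label <- "depletion"
    for (i in seq_len(nrow(peaks))) {
      if (nrow(del) == 0) break
      d <- origin_distance(peaks$summit[i], del)
      j <- order(d, abs(peaks$summit[i] - (del$start + del$end) / 2), del$name)[1]
      peaks$nearest_origin[i] <- del$name[j]
      peaks$distance_to_origin[i] <- d[j]
    }
  }
  hit <- vapply(seq_len(nrow(del)), function(j) {
    any(peaks$nearest_origin == del$name[j] &
          peaks$distance_to_origin <= assign_radius_bp, na.rm = TRUE)
  }, logical(1))
  attr(peaks, "misses") <- del$name[!hit]
  peaks
}

#' Write peaks as BED plus a TSV report
#'
#' BED name is `label:nearest_origin` and the score is
#' `1000 * min(height / max_height, 1)`; the TSV report carries all fields.
#'
#' @param peaks A `peak_set`.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Named vector of written paths, invisibly.
#' @export
write_peaks <- function(peaks, bed_path = NULL, tsv_path = NULL) {
  out <- character(0)
  if (!is.null(bed_path)) {
    if (nrow(peaks)) {
      gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(peaks$start, peaks$end))
      gr$name <- paste0(ifelse(is.na(peaks$label), "peak", peaks$label), ":",
                        ifelse(is.na(peaks$nearest_origin), ".",
                               peaks$nearest_origin))
      gr$score <- round(1000 * pmin(peaks$height / max(peaks$height), 1))
      rtracklayer::export(gr, bed_path, format = "BED")
    } else {
      writeLines(character(0), bed_path)
    }
    out <- c(out, bed = bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(peaks), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out <- c(out, tsv = tsv_path)
  }
  invisible(out)
}
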