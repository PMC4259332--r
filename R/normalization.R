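# Background-region normalization and differential tracks.

#' Normalize a track against known unreplicated regions
#'
#' Subtracts the unweighted arithmetic mean of the values of all probes whose
#' start position falls inside the union of the background intervals (regions
#' known to remain unreplicated under 200 mM HU), so that peak heights are
#' comparable across data sets. The recomputed background mean of the output
#' is zero to numerical precision and the operation is idempotent. The
#' subtracted constant is recorded as `background_offset` metadata.
#'
#' @param track A [probe_track()].
#' @param background Interval table (e.g. `genome$background`); rows on other
#'   chromosomes are ignored.
#' @return The normalized [probe_track()].
#' @export
background_normalize <- function(track, background) {
  stopifnot(inherits(track, "probe_track"))
  validate_intervals(background, "background region")
  bg <- background[background$chrom == track$chrom, , drop = FALSE]
  describe <- function(b) paste(sprintf("%s:%s-%s", b$chrom, format(b$start),
                                        format(b$end)), collapse = ", ")
  if (nrow(bg) == 0)
    stop("no background regions on ", track$chrom, " (regions checked: ",
         if (nrow(background)) describe(background) else "none", ")")
  inb <- rep(FALSE, length(track$positions))
  for (i in seq_len(nrow(bg)))
    inb <- inb | (track$positions >= bg$start[i] & track$positions <= bg$end[i])
  if (!any(inb))
    stop("no probes fall inside background regions ", describe(bg))
  offset <- mean(track$values[inb])
  out <- track
  out$values <- track$values - offset
  out$metadata$background_offset <- offset
  out
}

#' Differential (e.g. wild-type minus mutant) track
#'
#' Elementwise difference of two tracks over identical probe sets; no
#' interpolation or re-gridding is attempted.
#'
#' @param a,b [probe_track()]s on the same chromosome with identical probe
#'   position vectors.
#' @return A [probe_track()] with values `a - b`.
#' @export
difference_track <- function(a, b) {
  stopifnot(inherits(a, "probe_track"), inherits(b, "probe_track"))
  if (!identical(a$chrom, b$chrom))
    stop("tracks are on different chromosomes: ", a$chrom, " vs ", b$chrom)
  if (length(a$positions) != length(b$positions) ||
      any(a$positions != b$positions)) {
    n <- min(length(a$positions), length(b$positions))
    i <- which(a$positions[seq_len(n)] != b$positions[seq_len(n)])
    first <- if (length(i)) a$positions[i[1]] else a$positions[n + 1]
    stop("probe positions differ (first mismatch at ", a$chrom, ":",
         format(first), "); tracks must share a probe design")
  }
  probe_track(a$chrom, a$positions, a$values - b$values,
              probe_length = a$probe_length,
              metadata = list(assay = paste0("diff(",
                                a$metadata$genotype %||% "a", "-",
                                b$metadata$genotype %||% "b", ")"),
                              seed = a$metadata$seed))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
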