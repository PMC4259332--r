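# Probe-level signal tracks and their bedGraph serialization.

#' Construct a probe-level signal track
#'
#' A track holds one log2-ratio value per probe of one chromosome, anchored at
#' the probe start positions (strictly increasing).
#'
#' @param chrom Chromosome identifier.
#' @param positions Strictly increasing probe start positions (bp).
#' @param values One finite log2 ratio per position.
#' @param probe_length Probe length in bp (metadata only).
#' @param metadata Named list of labels (assay, genotype, seed, ...).
#' @return An object of class `probe_track`.
#' @export
probe_track <- function(chrom, positions, values, probe_length = 50,
                        metadata = list()) {
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values))
    stop("positions and values must have equal length")
  if (length(positions) == 0) stop("empty track")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(!is.finite(values))) stop("track values must be finite")
  structure(list(chrom = as.character(chrom), positions = positions,
                 values = values, probe_length = probe_length,
                 metadata = metadata),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("probe_track %s: %d probes [%s-%s], values in [%.3g, %.3g]\n",
              x$chrom, length(x$positions), format(min(x$positions)),
              format(max(x$positions)), min(x$values), max(x$values)))
  if (length(md))
    cat("  ", paste(names(md), unlist(lapply(md, format)), sep = "=",
                    collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.probe_track <- function(x, ...) {
  data.frame(chrom = x$chrom, position = x$positions, value = x$values)
}

#' Plot a probe track with optional annotations
#'
#' Base-graphics line plot of the signal with origin loci and called peaks
#' overlaid.
#'
#' @param x A [probe_track()].
#' @param genome Optional [genome_model()]; origin loci drawn as rug marks
#'   (deleted in grey).
#' @param peaks Optional peak table from [call_peaks()]; summits marked.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.probe_track <- function(x, genome = NULL, peaks = NULL, ...) {
  graphics::plot(x$positions / 1000, x$values, type = "l",
                 xlab = sprintf("%s position (kb)", x$chrom),
                 ylab = expression(log[2] ~ ratio), ...)
  if (!is.null(genome)) {
    o <- genome$origins[genome$origins$chrom == x$chrom, , drop = FALSE]
    if (nrow(o)) {
      mid <- (o$start + o$end) / 2 / 1000
      graphics::rug(mid[o$status == "intact"], col = "black", lwd = 2)
      graphics::rug(mid[o$status == "deleted"], col = "grey60", lwd = 2)
    }
  }
  if (!is.null(peaks) && nrow(peaks))
    graphics::points(peaks$summit / 1000, peaks$height, pch = 2, col = "red")
  invisible(x)
}

# ---- bedGraph I/O ----------------------------------------------------------
# Each probe is written as a 1 bp interval at its (0-based) start so that a
# track with overlapping 50-mers stays a valid bedGraph. Scalar metadata
# round-trips through "# key=value" header lines.

#' Write a probe track as bedGraph
#'
#' @param track A [probe_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "probe_track"))
  md <- c(list(probe_length = track$probe_length), track$metadata)
  md <- md[vapply(md, function(v) is.atomic(v) && length(v) == 1, logical(1))]
  hdr <- c("# oritrack bedGraph",
           sprintf("# %s=%s", names(md), vapply(md, as.character, character(1))),
           "track type=bedGraph")
  body <- sprintf("%s\t%d\t%d\t%s", track$chrom,
                  as.integer(track$positions - 1), as.integer(track$positions),
                  formatC(track$values, digits = 10, format = "g"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a probe track from bedGraph
#'
#' @param path A bedGraph written by [write_bedgraph()] (or any 4-column
#'   bedGraph of non-overlapping 1 bp or wider intervals; the interval start
#'   becomes the probe position).
#' @return A [probe_track()].
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  hdr <- grepl("^#", lines)
  for (l in sub("^#\\s*", "", lines[hdr])) {
    m <- regmatches(l, regexec("^([A-Za-z0-9_.]+)=(.*)$", l))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- utils::type.convert(m[3], as.is = TRUE)
  }
  body <- lines[!hdr & !grepl("^track", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("bedGraph has no data lines: ", path)
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 4)) stop("malformed bedGraph line ", which(lengths(f) < 4)[1])
  m <- matrix(unlist(f), ncol = length(f[[1]]), byrow = TRUE)
  probe_length <- if (!is.null(meta$probe_length)) meta$probe_length else 50
  meta$probe_length <- NULL
  probe_track(m[1, 1], as.numeric(m[, 2]) + 1, as.numeric(m[, 4]),
              probe_length = probe_length, metadata = meta)
}
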