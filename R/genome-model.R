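# Genome model: chromosomes, ARS annotations, deletion edits, coordinate maps.
# All internal coordinates are 1-based, fully closed; BED conversion happens at
# the I/O boundary only.

#' Construct a table of genomic intervals
#'
#' Intervals are 1-based and fully closed, so a single base is the interval
#' `[x, x]` and `span_length()` is `end - start + 1`.
#'
#' @param chrom Chromosome identifiers (recycled).
#' @param start,end Interval bounds in bp, `1 <= start <= end`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("chrVI", 68693, 68871)
#' @export
genomic_intervals <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, where = "interval") {
  for (col in c("chrom", "start", "end"))
    if (!col %in% names(df)) stop("missing column '", col, "' in ", where, " table")
  if (nrow(df) == 0) return(invisible(df))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("non-finite coordinates in ", where, " table")
  bad <- which(df$start < 1 | df$end < df$start)
  if (length(bad))
    stop(sprintf("malformed %s at row %d: start=%s end=%s (need 1 <= start <= end)",
                 where, bad[1], format(df$start[bad[1]]), format(df$end[bad[1]])))
  invisible(df)
}

#' Length spanned by closed genomic intervals
#'
#' Under the 1-based fully closed convention the span is `end - start + 1`.
#' Note that two rows of the published seven-origin deletion table print totals
#' that differ from this arithmetic by one resp. one hundred bp
#' (see [ori7_edits()]); the printed values are retained there but never used
#' for arithmetic.
#'
#' @param interval A data.frame with `chrom`, `start`, `end` columns
#'   (e.g. from [genomic_intervals()]).
#' @return Integer vector of bp counts, one per row.
#' @examples
#' span_length(genomic_intervals("chrVI", 135985, 136085))  # 101
#' @export
span_length <- function(interval) {
  validate_intervals(interval)
  as.integer(interval$end - interval$start + 1)
}

#' Construct an origin (ARS) annotation table
#'
#' Each origin carries its locus interval, an intact/deleted status, and the
#' simulation parameters used by the synthetic track generator: per-cell firing
#' probability (`efficiency`), firing time after G1 release in minutes
#' (`fire_time`), ORC ChIP peak amplitude in log2 units (`orc_height`), and the
#' multiplier applied to efficiency and ORC height when the origin is deleted
#' (`residual_fraction`).
#'
#' @param name Unique ARS identifiers.
#' @param chrom,start,end Locus interval (1-based closed).
#' @param efficiency Firing probability in `[0, 1]`.
#' @param fire_time Minutes after release.
#' @param orc_height Peak amplitude, log2 units.
#' @param residual_fraction Residual multiplier in `[0, 1]` for deleted origins.
#' @param status `"intact"` or `"deleted"`.
#' @return A `data.frame` of origin annotations.
#' @export
origin_annotations <- function(name, chrom, start, end, efficiency = 0.7,
                               fire_time = 0, orc_height = 2,
                               residual_fraction = 0.3, status = "intact") {
  if (length(name) == 0) {
    return(data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      efficiency = numeric(), fire_time = numeric(),
                      orc_height = numeric(), residual_fraction = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(name = as.character(name), chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   efficiency = efficiency, fire_time = fire_time,
                   orc_height = orc_height,
                   residual_fraction = residual_fraction,
                   status = status, stringsAsFactors = FALSE)
  validate_intervals(df, "origin")
  if (anyDuplicated(df$name))
    stop("duplicate origin name: ", df$name[anyDuplicated(df$name)])
  if (any(df$efficiency < 0 | df$efficiency > 1))
    stop("origin efficiency must lie in [0, 1]")
  if (any(df$residual_fraction < 0 | df$residual_fraction > 1))
    stop("residual_fraction must lie in [0, 1]")
  if (any(!df$status %in% c("intact", "deleted")))
    stop("origin status must be 'intact' or 'deleted'")
  df
}

#' Construct a deletion-edit table
#'
#' One row per origin deletion: the reference interval removed and the
#' replacement cassette (label and length). loxP scars are fixed at 34 bp.
#'
#' @param origin Name of the origin each edit removes.
#' @param replacement_label One of `"LEU2"`, `"ADE2"`, `"KanMX"`, `"loxP"`.
#' @param chrom,start,end Removed interval (1-based closed).
#' @param replacement_length Length in bp of the sequence inserted in place of
#'   the removed span (34 for loxP).
#' @return A `data.frame` of edits.
#' @export
deletion_edits <- function(origin, replacement_label, chrom, start, end,
                           replacement_length) {
  df <- data.frame(origin = as.character(origin),
                   replacement_label = as.character(replacement_label),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   replacement_length = as.numeric(replacement_length),
                   stringsAsFactors = FALSE)
  validate_intervals(df, "edit")
  ok <- c("LEU2", "ADE2", "KanMX", "loxP")
  if (any(!df$replacement_label %in% ok))
    stop("replacement_label must be one of: ", paste(ok, collapse = ", "))
  if (any(df$replacement_length < 0)) stop("replacement_length must be >= 0")
  bad <- which(df$replacement_label == "loxP" & df$replacement_length != 34)
  if (length(bad))
    stop("loxP replacements are a 34 bp scar; edit for ", df$origin[bad[1]],
         " has replacement_length ", df$replacement_length[bad[1]])
  if (anyDuplicated(df$origin))
    stop("duplicate edit for origin: ", df$origin[anyDuplicated(df$origin)])
  check_no_overlap(df)
  df
}

check_no_overlap <- function(edits) {
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1) {
      ov <- which(e$start[-1] <= e$end[-nrow(e)])
      if (length(ov))
        stop("overlapping edits on ", ch, ": ", e$origin[ov[1]], " and ",
             e$origin[ov[1] + 1])
    }
  }
  invisible(edits)
}

#' Assemble a genome model
#'
#' Bundles chromosome lengths, origin annotations, an applied edit table
#' (empty for the reference strain) and the background ("known unreplicated")
#' regions used for BrdU normalization. Coordinates are always in the
#' reference frame -- the frame of the array probes; edited chromosome lengths
#' are carried separately (see [edited_lengths()]).
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param origins Origin table from [origin_annotations()].
#' @param edits Edit table from [deletion_edits()], or `NULL`.
#' @param background Interval table of background regions, or `NULL`.
#' @param label Genotype label carried into track metadata.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, origins = NULL, edits = NULL,
                         background = NULL, label = "wild-type") {
  if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
    stop("chromosomes must be a named vector of lengths")
  if (any(chromosomes < 1)) stop("chromosome lengths must be >= 1")
  if (is.null(origins))
    origins <- origin_annotations(character(), character(), numeric(), numeric())
  if (is.null(background))
    background <- genomic_intervals(character(), numeric(), numeric())
  if (is.null(edits))
    edits <- deletion_edits(character(), character(), character(), numeric(),
                            numeric(), numeric())
  check_in_bounds(origins, chromosomes, "origin")
  check_in_bounds(background, chromosomes, "background region")
  check_in_bounds(edits, chromosomes, "edit")
  unknown <- setdiff(edits$origin, origins$name)
  if (length(unknown))
    stop("edit references unknown origin: ", paste(unknown, collapse = ", "))
  origins$status <- ifelse(origins$name %in% edits$origin, "deleted", "intact")
  obj <- structure(list(chromosomes = chromosomes, origins = origins,
                        edits = edits, background = background, label = label),
                   class = "genome_model")
  obj
}

check_in_bounds <- function(df, chromosomes, what) {
  if (nrow(df) == 0) return(invisible(df))
  unknown <- setdiff(df$chrom, names(chromosomes))
  if (length(unknown))
    stop(what, " on unknown chromosome: ", paste(unknown, collapse = ", "))
  bad <- which(df$end > chromosomes[df$chrom])
  if (length(bad))
    stop(sprintf("%s at row %d (%s:%s-%s) exceeds chromosome length %s",
                 what, bad[1], df$chrom[bad[1]], format(df$start[bad[1]]),
                 format(df$end[bad[1]]), format(chromosomes[[df$chrom[bad[1]]]])))
  invisible(df)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model (", x$label, ")\n", sep = "")
  cat("  chromosomes:",
      paste(sprintf("%s (%s bp)", names(x$chromosomes),
                    format(x$chromosomes, big.mark = ",", trim = TRUE)),
            collapse = ", "), "\n")
  cat("  origins:", nrow(x$origins), "(", sum(x$origins$status == "deleted"),
      "deleted )\n")
  cat("  edits:", nrow(x$edits), " background regions:", nrow(x$background), "\n")
  invisible(x)
}

#' Apply a deletion-edit table to a genome model
#'
#' Marks matching origins deleted, records the edits on the model, computes the
#' post-edit chromosome lengths (reference length minus removed spans plus
#' replacement cassettes) and builds a coordinate map from edited-genome
#' positions back to reference positions. Positions that fall inside a removed
#' span exist only in the reference and are absent from the map's image;
#' positions inside a replacement cassette map to `NA` (non-reference).
#'
#' @param genome A [genome_model()].
#' @param edits An edit table from [deletion_edits()]; may be empty.
#' @param label Genotype label of the edited model; defaults to `"edited"`
#'   when edits are present and the input label otherwise.
#' @return A list with elements `genome` (the edited model, reference frame)
#'   and `coordinate_map` (see [map_to_reference()]).
#' @examples
#' gm <- genome_model(c(toy = 1000),
#'                    origin_annotations("ORI1", "toy", 450, 550))
#' ed <- deletion_edits("ORI1", "loxP", "toy", 450, 550, 34)
#' res <- apply_edits(gm, ed)
#' edited_lengths(res$genome)  # 1000 - 101 + 34 = 933
#' @export
apply_edits <- function(genome, edits, label = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(edits))
    edits <- deletion_edits(character(), character(), character(), numeric(),
                            numeric(), numeric())
  if (is.null(label)) label <- if (nrow(edits)) "edited" else genome$label
  edited <- genome_model(genome$chromosomes, genome$origins, edits,
                         genome$background, label = label)
  removed <- tapply(span_length(edits), edits$chrom, sum)
  added <- tapply(edits$replacement_length, edits$chrom, sum)
  lens <- genome$chromosomes
  if (nrow(edits)) {
    lens[names(removed)] <- lens[names(removed)] - removed + added
  }
  edited$edited_chromosomes <- lens
  list(genome = edited, coordinate_map = build_coordinate_map(genome$chromosomes, edits))
}

#' Post-edit chromosome lengths
#'
#' @param genome A genome model, typically the `genome` element returned by
#'   [apply_edits()].
#' @return Named vector of edited chromosome lengths (reference lengths if the
#'   model carries no edits).
#' @export
edited_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.null(genome$edited_chromosomes)) genome$edited_chromosomes
  else genome$chromosomes
}

build_coordinate_map <- function(chromosomes, edits) {
  blocks <- lapply(names(chromosomes), function(ch) {
    L <- chromosomes[[ch]]
    e <- edits[edits$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    rows <- list()
    cur_ref <- 1
    cur_ed <- 1
    add <- function(len, ref) {
      if (len > 0)
        rows[[length(rows) + 1]] <<- c(cur_ed, cur_ed + len - 1, ref)
      cur_ed <<- cur_ed + max(len, 0)
    }
    for (i in seq_len(nrow(e))) {
      add(e$start[i] - cur_ref, cur_ref)
      add(e$replacement_length[i], NA_real_)
      cur_ref <- e$end[i] + 1
    }
    add(L - cur_ref + 1, cur_ref)
    m <- do.call(rbind, rows)
    data.frame(edited_start = m[, 1], edited_end = m[, 2], ref_start = m[, 3])
  })
  names(blocks) <- names(chromosomes)
  structure(list(blocks = blocks), class = "coordinate_map")
}

#' Translate edited-genome positions back to reference positions
#'
#' @param map A `coordinate_map` from [apply_edits()].
#' @param chrom Chromosome identifier.
#' @param positions Positions in the edited genome (1-based).
#' @return Numeric vector of reference positions; `NA` marks non-reference
#'   (replacement cassette) positions.
#' @export
map_to_reference <- function(map, chrom, positions) {
  stopifnot(inherits(map, "coordinate_map"))
  b <- map$blocks[[chrom]]
  if (is.null(b)) stop("unknown chromosome in coordinate map: ", chrom)
  L <- max(b$edited_end)
  if (any(positions < 1 | positions > L))
    stop("position outside edited chromosome [1, ", L, "]")
  i <- findInterval(positions, b$edited_start)
  b$ref_start[i] + (positions - b$edited_start[i])
}

# ---- BED / TSV I/O ---------------------------------------------------------

#' Read origin annotations from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to the internal
#' 1-based closed convention on import (rtracklayer does this conversion).
#' The BED name column is the ARS identifier; score and strand are unused.
#'
#' @param path BED file of origin loci.
#' @param chromosomes Optional named vector of chromosome lengths used for
#'   bounds checking (inferred from the data when `NULL`).
#' @return An origin annotation table with default simulation parameters.
#' @export
read_origins_bed <- function(path, chromosomes = NULL) {
  gr <- import_bed_checked(path)
  if (length(gr) == 0)
    return(origin_annotations(character(), character(), numeric(), numeric()))
  nm <- gr$name
  if (is.null(nm) || any(is.na(nm) | nm == ""))
    stop("origin BED requires a name column: ", path)
  dup <- which(duplicated(nm))
  if (length(dup))
    stop("duplicate origin name '", nm[dup[1]], "' at line ", dup[1], " of ", path)
  df <- origin_annotations(nm, as.character(GenomicRanges::seqnames(gr)),
                           GenomicRanges::start(gr), GenomicRanges::end(gr))
  if (!is.null(chromosomes)) check_in_bounds(df, chromosomes, "origin")
  df
}

import_bed_checked <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(txt)))) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "BED")
}

#' Write intervals or origins to BED
#'
#' @param df Interval table (origins need a `name` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  if (!is.null(df$name)) gr$name <- df$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Load a genome model from annotation files
#'
#' @param origins_path BED file of origin loci (name column = ARS id).
#' @param background_path Optional BED file of background regions.
#' @param chromosomes Named vector of chromosome lengths; when `NULL`, lengths
#'   are inferred as the maximal annotated end position per chromosome.
#' @param label Genotype label.
#' @return A [genome_model()]. Simulation parameters take their defaults
#'   (BED does not carry them); round-tripping preserves loci and names.
#' @export
load_annotations <- function(origins_path, background_path = NULL,
                             chromosomes = NULL, label = "wild-type") {
  origins <- read_origins_bed(origins_path, chromosomes)
  background <- NULL
  if (!is.null(background_path)) {
    gr <- import_bed_checked(background_path)
    background <- genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                                    GenomicRanges::start(gr),
                                    GenomicRanges::end(gr))
  }
  if (is.null(chromosomes)) {
    both <- rbind(origins[c("chrom", "end")],
                  if (!is.null(background)) background[c("chrom", "end")])
    if (is.null(both) || nrow(both) == 0)
      stop("cannot infer chromosome lengths from empty annotations; ",
           "supply `chromosomes`")
    chromosomes <- tapply(both$end, both$chrom, max)
    chromosomes <- stats::setNames(as.numeric(chromosomes), names(chromosomes))
  }
  genome_model(chromosomes, origins, background = background, label = label)
}

#' Write a genome model's annotations
#'
#' @param genome A [genome_model()].
#' @param origins_path Output BED for origin loci.
#' @param background_path Optional output BED for background regions.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_annotations <- function(genome, origins_path, background_path = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  write_bed(genome$origins, origins_path)
  out <- c(origins = origins_path)
  if (!is.null(background_path)) {
    write_bed(genome$background, background_path)
    out <- c(out, background = background_path)
  }
  invisible(out)
}

#' Read / write a deletion-edit table as TSV
#'
#' Columns: `origin`, `replacement_label`, `chrom`, `start`, `end`,
#' `replacement_length` (1-based closed coordinates, as printed in origin
#' deletion tables).
#'
#' @param path TSV path.
#' @return For `read_edit_table`, a validated edit table.
#' @export
read_edit_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  deletion_edits(df$origin, df$replacement_label, df$chrom, df$start, df$end,
                 df$replacement_length)
}

#' @param edits Edit table from [deletion_edits()].
#' @rdname read_edit_table
#' @export
write_edit_table <- function(edits, path) {
  utils::write.table(edits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
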