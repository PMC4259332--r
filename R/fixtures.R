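# Built-in annotation fixtures for the chromosomes covered by the tiling
# array (III, VI, XII). Loci outside the published deletion table are
# approximate (OriDB-style positions rounded to round numbers) and exist to
# parameterize the simulator, not to be coordinate-exact.

#' The seven-origin deletion-edit table
#'
#' Reference-frame intervals removed on the left arm of chromosome VI together
#' with the replacement cassette for each. The `printed_total` attribute keeps
#' the published per-row bp totals: for ARS600 the printed total (15,292)
#' differs from `end - start + 1` (15,392), and for ARS606 (434 vs 435); the
#' published values are retained verbatim but all arithmetic in this package
#' uses the inclusive convention. Cassette lengths for LEU2/ADE2/KanMX are
#' typical cassette sizes (approximate); the 34 bp loxP scar is exact.
#'
#' @return An edit table (see [deletion_edits()]) with attribute
#'   `printed_total`.
#' @export
ori7_edits <- function() {
  e <- deletion_edits(
    origin            = c("ARS600", "ARS601/2", "ARS603", "ARS603.5",
                          "ARS604", "ARS605", "ARS606"),
    replacement_label = c("LEU2", "loxP", "loxP", "KanMX", "loxP", "loxP", "ADE2"),
    chrom             = "chrVI",
    start             = c(5435, 32473, 68693, 118637, 127751, 135985, 167614),
    end               = c(20826, 33247, 68871, 118957, 128071, 136085, 168048),
    replacement_length = c(2230, 34, 34, 1400, 34, 34, 2280)
  )
  attr(e, "printed_total") <- c(15292, 775, 179, 321, 321, 101, 434)
  e
}

#' Reference (wild-type) genome model for the tiled chromosomes
#'
#' Chromosomes III, VI and XII with origin annotations for VI and III and the
#' known unreplicated (background) regions used for BrdU normalization under
#' 200 mM HU: chrIII 184-192 kb, chrVI 80-86 kb, chrXII 845-870 kb. Deleted
#' loci use the published per-origin coordinate ranges; the remaining loci
#' (ARS602.5, ARS603.1, ARS607-609 and the chrIII origins) are approximate.
#' Firing efficiencies and times are simulator parameters, not measurements:
#' confirmed efficient origins fire at release (0 min), late/dormant ones at
#' 30 min.
#'
#' @return A [genome_model()] labelled `"wild-type"`.
#' @export
yeast_model <- function() {
  chroms <- c(chrIII = 316620, chrVI = 270161, chrXII = 1078177)
  ori <- rbind(
    origin_annotations(
      name  = c("ARS600", "ARS601/2", "ARS602.5", "ARS603", "ARS603.1",
                "ARS603.5", "ARS604", "ARS605", "ARS606", "ARS607",
                "ARS608", "ARS609"),
      chrom = "chrVI",
      start = c(5435, 32473, 55000, 68693, 97000, 118637, 127751, 135985,
                167614, 199300, 216700, 255000),
      end   = c(20826, 33247, 55300, 68871, 97300, 118957, 128071, 136085,
                168048, 199600, 217000, 255300),
      efficiency = c(0.8, 0.8, 0.6, 0.8, 0.6, 0.7, 0.8, 0.8, 0.8, 0.9, 0.7, 0.4),
      fire_time  = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 30)
    ),
    origin_annotations(
      name  = c("ARS305", "ARS306", "ARS307", "ARS309", "ARS310",
                "ARS315", "ARS316"),
      chrom = "chrIII",
      start = c(39500, 74450, 94400, 137000, 166400, 224000, 292000),
      end   = c(39800, 74750, 94700, 137300, 166700, 224300, 292300),
      efficiency = c(0.85, 0.7, 0.75, 0.6, 0.7, 0.6, 0.4),
      fire_time  = c(0, 0, 0, 0, 0, 0, 30)
    )
  )
  bg <- genomic_intervals(c("chrIII", "chrVI", "chrXII"),
                          c(184000, 80000, 845000),
                          c(192000, 86000, 870000))
  genome_model(chroms, ori, background = bg, label = "wild-type")
}

#' Seven-origin-deleted genome model
#'
#' [yeast_model()] with the [ori7_edits()] table applied; the seven left-arm
#' chromosome VI origins are flagged deleted.
#'
#' @return A [genome_model()] labelled `"7oriD"`.
#' @export
ori7_model <- function() {
  apply_edits(yeast_model(), ori7_edits(), label = "7oriD")$genome
}
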