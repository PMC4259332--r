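# Peak calling, classification against the origin annotation, and
# ORC-depletion detection.

triangle <- function(center, apex, halfwidth, positions) {
  pmax(0, apex * (1 - abs(positions - center) / halfwidth))
}

test_that("call_peaks recovers simple geometric truths", {
  pos <- seq(1, 8001, 8)
  flat <- probe_track("c", pos, rep(0.2, length(pos)))
  expect_identical(nrow(call_peaks(flat, min_height = 0.1)), 0L)
  tri <- probe_track("c", pos, triangle(4001, 2, 1500, pos))
  pk <- call_peaks(tri, min_height = 0.5)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$summit, 4001)
  expect_equal(pk$height, 2)
  # half-height bounds: value >= 1 within 750 bp of the apex
  expect_equal(pk$start, min(pos[triangle(4001, 2, 1500, pos) >= 1]))
  expect_equal(pk$end, max(pos[triangle(4001, 2, 1500, pos) >= 1]))
  # plateau maxima report the leftmost probe of the plateau
  v <- rep(0, length(pos)); v[200:210] <- 1
  expect_equal(call_peaks(probe_track("c", pos, v), min_height = 0.5)$summit,
               pos[200])
})

test_that("two planted bumps 20 kb apart are recovered at 10x noise", {
  pos <- seq(1, 50001, 8)
  set.seed(51)
  noise_sd <- 0.1
  v <- noise_sd * rnorm(length(pos)) +
    1 * exp(-(pos - 15001)^2 / (2 * 80^2)) +
    1 * exp(-(pos - 35001)^2 / (2 * 80^2))
  tr <- pseudomedian_filter(probe_track("c", pos, v))
  pk <- call_peaks(tr, min_height = 0.5, min_separation_bp = 5000)
  expect_identical(nrow(pk), 2L)
  expect_true(all(abs(pk$summit - c(15001, 35001)) <= 16))
})

test_that("peak count is non-increasing in min_height and calls are deterministic", {
  set.seed(53)
  pos <- seq(1, 30001, 8)
  v <- rnorm(length(pos), 0, 0.3)
  tr <- probe_track("c", pos, v)
  heights <- seq(0.2, 1.2, by = 0.1)
  counts <- vapply(heights,
                   function(h) nrow(call_peaks(tr, min_height = h)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(call_peaks(tr, min_height = 0.5),
                   call_peaks(tr, min_height = 0.5))
})

test_that("classification partitions peaks into canonical/residual/novel", {
  gm <- genome_model(c(chrT = 100000),
                     origin_annotations(c("ARS_A", "ARS_B"), "chrT",
                                        c(19900, 59900), c(20100, 60100)))
  mut <- apply_edits(gm, deletion_edits("ARS_B", "loxP", "chrT",
                                        59900, 60100, 34))$genome
  pk <- structure(data.frame(chrom = "chrT",
                             summit = c(20000, 61000, 90000),
                             height = c(2, 1, 1),
                             start = c(19500, 60500, 89500),
                             end = c(20500, 61500, 90500),
                             label = NA_character_,
                             nearest_origin = NA_character_,
                             distance_to_origin = NA_real_,
                             stringsAsFactors = FALSE),
                  class = c("peak_set", "data.frame"))
  cl <- classify_peaks(pk, mut)
  expect_identical(cl$label, c("canonical", "residual", "novel"))
  expect_identical(cl$nearest_origin, c("ARS_A", "ARS_B", NA))
  # distance is measured to the locus interval: zero at the midpoint
  expect_identical(cl$distance_to_origin, c(0, 900, NA))
  expect_false(any(is.na(cl$label)))
})

test_that("classification ties break toward the closer midpoint then the name", {
  gm <- genome_model(c(chrT = 50000),
                     origin_annotations(c("ARS_L", "ARS_R"), "chrT",
                                        c(9000, 11054), c(9940, 12000)))
  pk <- call_peaks(probe_track("chrT", seq(1, 20001, 8),
                               triangle(10497, 2, 800, seq(1, 20001, 8))),
                   min_height = 1)
  # summit 10497 is 557 bp from both loci; ARS_L midpoint (9470) is 1027 away,
  # ARS_R midpoint (11527) is 1030 away -> ARS_L wins on midpoint distance
  cl <- classify_peaks(pk, gm)
  expect_identical(cl$nearest_origin, "ARS_L")
  # exact midpoint symmetry falls back to the lexicographic name
  gm2 <- genome_model(c(chrT = 50000),
                      origin_annotations(c("ARS_B", "ARS_A"), "chrT",
                                         c(9000, 11000), c(10000, 12000)))
  pk2 <- pk; pk2$summit <- 10500
  expect_identical(classify_peaks(pk2, gm2)$nearest_origin, "ARS_A")
})

test_that("depletion detection finds every deleted origin and misses honestly", {
  wt <- yeast_model()
  mut <- ori7_model()
  probes <- design_probes(wt)$chrVI
  cfg <- sim_config(noise_sd = 0)
  d <- difference_track(simulate_orc_track(wt, probes, cfg),
                        simulate_orc_track(mut, probes, cfg))
  expect_identical(nrow(detect_depletion(difference_track(d, d), mut,
                                         min_height = 0.2)), 0L)
  dep <- detect_depletion(d, mut, min_height = 0.2)
  expect_identical(nrow(dep), 7L)
  expect_setequal(dep$nearest_origin, ori7_edits()$origin)
  expect_length(attr(dep, "misses"), 0)
  # removing one origin's signal turns it into a reported miss
  d2 <- d
  mid600 <- mean(c(5435, 20826))
  d2$values[abs(d2$positions - mid600) < 2000] <- 0
  dep2 <- detect_depletion(d2, mut, min_height = 0.2)
  expect_identical(attr(dep2, "misses"), "ARS600")
})

test_that("peak export writes BED and a full TSV report", {
  d <- withr::local_tempdir()
  gm <- genome_model(c(chrT = 100000),
                     origin_annotations("ARS_A", "chrT", 19900, 20100))
  pos <- seq(1, 40001, 8)
  pk <- classify_peaks(call_peaks(probe_track("chrT", pos,
                                              triangle(20001, 2, 1000, pos)),
                                  min_height = 1), gm)
  paths <- write_peaks(pk, file.path(d, "p.bed"), file.path(d, "p.tsv"))
  bed <- strsplit(readLines(paths[["bed"]]), "\t")[[1]]
  expect_identical(bed[4], "canonical:ARS_A")
  expect_identical(bed[5], "1000")
  rep <- read.delim(paths[["tsv"]])
  expect_identical(names(rep),
                   c("chrom", "summit", "height", "start", "end", "label",
                     "nearest_origin", "distance_to_origin"))
})
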