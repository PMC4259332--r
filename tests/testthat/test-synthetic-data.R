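# Probe design, the fork-progression replication model, and track simulation.

test_that("probe design reproduces the array geometry", {
  ps <- design_probes(c(toy = 1000), probe_length = 50, step = 8)$toy
  expect_length(ps$starts, 119)  # floor((1000 - 50) / 8) + 1
  # explicit enumeration: every 50-mer fits, the next start would not
  expect_true(all(ps$starts + 49 <= 1000))
  expect_equal(ps$starts, seq(1, 951, by = 8)[seq_along(ps$starts)])
  expect_equal(unique(diff(ps$starts)), 8)
  # consecutive-probe overlap = probe_length - step
  expect_equal(50 - unique(diff(ps$starts)), 42)
  ps0 <- design_probes(c(toy = 1000), probe_length = 50, step = 50)$toy
  expect_equal(50 - unique(diff(ps0$starts)), 0)
  expect_error(design_probes(c(toy = 100), step = 100), "step")
})

test_that("replication_fraction handles certain, unreachable and joint firing", {
  cfg <- sim_config()
  one <- data.frame(position = 50000, efficiency = 1, fire_time = 0)
  expect_equal(replication_fraction(50000, one, cfg), 1)
  # beyond fork_speed * t_total = 6000 bp: untouched
  expect_equal(replication_fraction(50000 + 6001, one, cfg), 0)
  expect_equal(replication_fraction(50000 + 6000, one, cfg), 1)
  two <- data.frame(position = c(49000, 51000), efficiency = 0.5,
                    fire_time = 0)
  expect_equal(replication_fraction(50000, two, cfg), 0.75)  # 1 - 0.5 * 0.5
})

test_that("analytic replication fraction agrees with the per-cell simulator", {
  cfg <- sim_config()
  origins <- data.frame(position = c(20000, 32000, 60000),
                        efficiency = c(0.8, 0.5, 0.3),
                        fire_time = c(0, 0, 30))
  x <- c(14500, 20000, 25500, 26500, 30000, 32000, 37500, 59000, 61000, 80000)
  f <- replication_fraction(x, origins, cfg)
  set.seed(77)
  n <- 1e5
  fmc <- mc_replication_fraction(x, origins, cfg, n)
  se <- sqrt(pmax(f * (1 - f), 1e-12) / n)
  expect_true(all(abs(f - fmc) <= pmax(3 * se, 1e-12)))
})

test_that("replication_fraction is bounded and monotone in distance", {
  cfg <- sim_config()
  set.seed(5)
  for (i in 1:25) {
    o <- data.frame(position = 50000, efficiency = runif(1),
                    fire_time = runif(1, 0, 60))
    d <- sort(sample.int(10000, 50))
    f <- replication_fraction(50000 + d, o, cfg)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) <= 0))
  }
})

test_that("BrdU tracks follow the fork model with seeded noise", {
  toy <- genome_model(c(toy = 60000),
                      origin_annotations("O1", "toy", 29900, 30100,
                                         efficiency = 0.8))
  probes <- design_probes(toy)$toy
  quiet_cfg <- sim_config(noise_sd = 0, background_level = 0)
  empty <- genome_model(c(toy = 60000))
  t0 <- simulate_brdu_track(empty, probes, quiet_cfg)
  expect_true(all(t0$values == 0))
  t1 <- simulate_brdu_track(toy, probes, quiet_cfg)
  mid <- probes$starts + 24.5
  nearest <- which.min(abs(mid - 30000))
  expect_equal(t1$values[nearest], max(t1$values))
  # reproducibility: identical seed and config give bit-identical tracks
  cfg <- sim_config(seed = 9)
  a <- simulate_brdu_track(toy, probes, cfg)
  b <- simulate_brdu_track(toy, probes, cfg)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         simulate_brdu_track(toy, probes,
                                             sim_config(seed = 10))$values))
})

test_that("noise in unreachable regions averages to zero at CLT scale", {
  gm <- genome_model(c(toy = 100000),
                     origin_annotations("O1", "toy", 4900, 5100))
  cfg <- sim_config(seed = 21)
  probes <- design_probes(gm)$toy
  tr <- simulate_brdu_track(gm, probes, cfg)
  far <- which(probes$starts > 20000)[1:1000]
  expect_lt(abs(mean(tr$values[far]) - cfg$background_level),
            4 * cfg$noise_sd / sqrt(1000))
})

test_that("ORC tracks put Gaussian peaks at intact origins only", {
  toy <- genome_model(c(toy = 40000),
                      origin_annotations("O1", "toy", 19900, 20100,
                                         orc_height = 1.5))
  probes <- design_probes(toy)$toy
  cfg <- sim_config(noise_sd = 0, background_level = 0)
  t1 <- simulate_orc_track(toy, probes, cfg)
  mid <- probes$starts + 24.5
  nearest <- which.min(abs(mid - 20000))
  expect_equal(max(t1$values), t1$values[nearest])
  expect_equal(max(t1$values), 1.5, tolerance = 1e-3)
  # fully suppressed residual binding: deleted neighborhood flat at background
  toy0 <- genome_model(c(toy = 40000),
                       origin_annotations("O1", "toy", 19900, 20100,
                                          orc_height = 1.5,
                                          residual_fraction = 0))
  mut <- apply_edits(toy0, deletion_edits("O1", "loxP", "toy",
                                          19900, 20100, 34))$genome
  t2 <- simulate_orc_track(mut, probes, cfg)
  expect_true(all(t2$values == 0))
})

test_that("noiseless WT minus mutant ORC signal is confined to deleted peaks", {
  wt <- yeast_model()
  mut <- ori7_model()
  cfg <- sim_config(noise_sd = 0)
  probes <- design_probes(wt)$chrVI
  d <- difference_track(simulate_orc_track(wt, probes, cfg),
                        simulate_orc_track(mut, probes, cfg))
  del <- mut$origins[mut$origins$status == "deleted", ]
  mids <- (del$start + del$end) / 2
  # the only places WT and mutant signals can differ are the (truncated)
  # Gaussian peaks of the deleted origins
  near_deleted <- rep(FALSE, length(d$positions))
  for (m in mids)
    near_deleted <- near_deleted | (abs(d$positions + 24.5 - m) <= 6 * cfg$orc_peak_sd)
  # any nonzero difference lies within a deleted-origin neighborhood
  expect_true(all(abs(d$values[!near_deleted]) < 1e-12))
  # closed-form maxima: full orc_height where the summit probe is masked,
  # never less than (1 - residual_fraction) * orc_height
  for (j in seq_len(nrow(del))) {
    w <- abs(d$positions + 24.5 - mids[j]) <= 3 * cfg$orc_peak_sd
    mx <- max(d$values[w])
    expect_gte(mx, (1 - del$residual_fraction[j]) * del$orc_height[j] - 1e-9)
    expect_lte(mx, del$orc_height[j] + 1e-9)
  }
})
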