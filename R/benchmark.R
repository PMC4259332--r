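# Planted-truth recovery benchmark: the package's own check that the whole
# simulate -> condition -> call chain recovers what the generator planted.

#' Planted-truth recovery study
#'
#' Runs the default-configuration pipeline over `n_seeds` independent seeds
#' and measures, against the planted truth of the generator:
#' \describe{
#'   \item{intact recall}{fraction of intact origins (both genotypes, ORC
#'     tracks on chrVI and chrIII) recovered by a called peak whose summit
#'     lies within `match_radius_bp` of the origin midpoint;}
#'   \item{summit error}{mean absolute summit-to-midpoint distance of the
#'     matched ORC peaks, in probe steps;}
#'   \item{ORC depletion}{number of deleted origins with a depletion peak in
#'     the wild-type minus mutant chrVI difference track;}
#'   \item{residual initiation}{number of deleted origins (with nonzero
#'     residual fraction) showing a residual-labelled BrdU peak within the
#'     assignment radius;}
#'   \item{chrIII control}{number of depletion peaks called on the unedited
#'     chrIII difference track (expected zero).}
#' }
#'
#' @param n_seeds Number of replicate seeds (default 20).
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @param match_radius_bp Radius for matching an ORC peak to a planted origin
#'   (default 1000).
#' @param quiet Suppress per-stage logging (default `TRUE`).
#' @return A list with per-seed data.frame `per_seed` and scalar summaries
#'   `intact_recall`, `mean_summit_error_steps`, `mean_depletion_recovered`,
#'   `mean_residual_recovered`, `n_deleted`, `seeds_chrIII_clean`.
#' @export
recovery_study <- function(n_seeds = 20, seed = 1, match_radius_bp = 1000,
                           quiet = TRUE) {
  wt <- yeast_model()
  mut <- ori7_model()
  probes <- design_probes(wt)
  step <- probes$chrVI$starts[2] - probes$chrVI$starts[1]
  del <- mut$origins[mut$origins$status == "deleted", , drop = FALSE]
  run1 <- function(s) {
    cfg <- sim_config(seed = s)
    smooth <- function(g, ch, assay) {
      raw <- if (assay == "orc") simulate_orc_track(g, probes[[ch]], cfg)
             else simulate_brdu_track(g, probes[[ch]], cfg)
      t <- pseudomedian_filter(biweight_adjust(raw))
      if (assay == "brdu") t <- background_normalize(t, g$background)
      t
    }
    # ORC recall + summit error over intact origins of both genotypes
    n_intact <- 0; n_found <- 0; errs <- numeric(0)
    orc <- list()
    for (ch in c("chrVI", "chrIII")) {
      for (tag in c("wt", "mut")) {
        g <- if (tag == "wt") wt else mut
        t <- smooth(g, ch, "orc")
        orc[[paste(tag, ch)]] <- t
        pk <- call_peaks(t)
        o <- g$origins[g$origins$chrom == ch &
                         g$origins$status == "intact", , drop = FALSE]
        mids <- (o$start + o$end) / 2
        # tracks are anchored at probe starts but the signal is generated at
        # probe midpoints; compare summits to planted truth in the same frame
        summit_mid <- pk$summit + (t$probe_length - 1) / 2
        for (m in mids) {
          n_intact <- n_intact + 1
          if (nrow(pk)) {
            dm <- abs(summit_mid - m)
            if (min(dm) <= match_radius_bp) {
              n_found <- n_found + 1
              errs <- c(errs, min(dm))
            }
          }
        }
      }
    }
    dep_vi <- detect_depletion(difference_track(orc[["wt chrVI"]],
                                                orc[["mut chrVI"]]), mut)
    dep_iii <- detect_depletion(difference_track(orc[["wt chrIII"]],
                                                 orc[["mut chrIII"]]), mut)
    brdu <- smooth(mut, "chrVI", "brdu")
    bp <- classify_peaks(call_peaks(brdu), mut)
    resid_hit <- vapply(seq_len(nrow(del)), function(j) {
      if (del$residual_fraction[j] <= 0) return(NA)
      any(bp$label == "residual" & bp$nearest_origin == del$name[j] &
            bp$distance_to_origin <= 5000, na.rm = TRUE)
    }, logical(1))
    data.frame(seed = s,
               intact_total = n_intact, intact_found = n_found,
               summit_error_bp = mean(errs),
               depletion_recovered = nrow(del) - length(attr(dep_vi, "misses")),
               residual_recovered = sum(resid_hit, na.rm = TRUE),
               residual_eligible = sum(!is.na(resid_hit)),
               chrIII_depletion_peaks = nrow(dep_iii))
  }
  wrap <- if (quiet) suppressMessages else identity
  per_seed <- wrap(do.call(rbind, lapply(seed + seq_len(n_seeds) - 1, run1)))
  list(per_seed = per_seed,
       intact_recall = sum(per_seed$intact_found) / sum(per_seed$intact_total),
       mean_summit_error_steps = mean(per_seed$summit_error_bp) / step,
       mean_depletion_recovered = mean(per_seed$depletion_recovered),
       mean_residual_recovered = mean(per_seed$residual_recovered),
       n_deleted = nrow(del),
       seeds_chrIII_clean = sum(per_seed$chrIII_depletion_peaks == 0))
}
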