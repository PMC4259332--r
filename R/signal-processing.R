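# Robust track conditioning: Tukey biweight location adjustment and the
# Hodges-Lehmann pseudomedian sliding-window filter.

#' Tukey biweight location estimate
#'
#' Iteratively reweighted biweight (bisquare) location: starting from the
#' median, observations are weighted by `(1 - u^2)^2` for `|u| < 1` with
#' `u = (x - t) / (c * MAD)` and zero weight beyond, until the update falls
#' below `tol`. The MAD (scaled by 1.4826, taken about the median) is fixed at
#' its initial value; when it is zero the median is returned.
#'
#' @param x Numeric values (at least one finite value).
#' @param c Tuning constant in MAD units (default 5).
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return The location estimate.
#' @examples
#' tukey_biweight_location(c(0, 0.1, -0.1, 0.05, -0.05, 50))  # ~0
#' @export
tukey_biweight_location <- function(x, c = 5, tol = 1e-8, max_iter = 100L) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("need at least one finite value")
  t0 <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) return(t0)
  for (i in seq_len(max_iter)) {
    u <- (x - t0) / (c * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    if (sum(w) == 0) break
    t1 <- sum(w * x) / sum(w)
    done <- abs(t1 - t0) <= tol
    t0 <- t1
    if (done) break
  }
  t0
}

#' Centre a track by its Tukey biweight location
#'
#' Subtracts [tukey_biweight_location()] of the values from every probe, so
#' that recomputing the biweight location on the output gives (numerically)
#' zero; idempotent up to `tol`. The subtracted constant is recorded as
#' `biweight_offset` metadata.
#'
#' @param track A [probe_track()].
#' @inheritParams tukey_biweight_location
#' @return The adjusted [probe_track()].
#' @export
biweight_adjust <- function(track, c = 5, tol = 1e-8) {
  stopifnot(inherits(track, "probe_track"))
  offset <- tukey_biweight_location(track$values, c = c, tol = tol)
  out <- track
  out$values <- track$values - offset
  out$metadata$biweight_offset <- offset
  out
}

#' Hodges-Lehmann pseudomedian
#'
#' Median of all pairwise Walsh averages `(x_i + x_j) / 2` over `i <= j`
#' (self-pairs included); for an even count of averages, the midpoint of the
#' central pair.
#'
#' @param x Numeric values (at least one).
#' @return The pseudomedian.
#' @examples
#' pseudomedian(c(1, 2, 3))  # 2
#' @export
pseudomedian <- function(x) {
  if (length(x) == 0) stop("need at least one value")
  if (any(!is.finite(x))) stop("values must be finite")
  if (length(x) == 1) return(x)
  w <- outer(x, x, "+") / 2
  stats::median(w[upper.tri(w, diag = TRUE)])
}

#' Pseudomedian sliding-window filter
#'
#' Replaces each probe value by the pseudomedian of all probes whose start
#' position lies within `window_bp / 2` of the probe's start (a window in
#' genomic bp, not in probe counts); windows shrink at chromosome edges.
#' Positions are unchanged. Removes isolated outlier probes while preserving
#' level: the filter is shift- and (positive) scale-equivariant.
#'
#' @param track A [probe_track()].
#' @param window_bp Window width in bp (default 50).
#' @return The filtered [probe_track()].
#' @export
pseudomedian_filter <- function(track, window_bp = 50) {
  stopifnot(inherits(track, "probe_track"), window_bp >= 1)
  p <- track$positions
  v <- track$values
  half <- window_bp / 2
  lo <- findInterval(p - half, p, left.open = TRUE) + 1L
  hi <- findInterval(p + half, p)
  width <- hi - lo + 1L
  out <- numeric(length(p))
  for (k in sort(unique(width))) {
    rows <- which(width == k)
    if (k == 1L) {
      out[rows] <- v[lo[rows]]
      next
    }
    idx <- outer(lo[rows], 0:(k - 1L), "+")
    V <- matrix(v[idx], nrow = length(rows))
    pr <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    W <- (V[, pr[, 1], drop = FALSE] + V[, pr[, 2], drop = FALSE]) / 2
    m <- ncol(W)
    S <- matrix(W[order(row(W), W)], nrow = nrow(W), byrow = TRUE)
    out[rows] <- if (m %% 2L == 1L) S[, (m + 1L) %/% 2L]
                 else (S[, m %/% 2L] + S[, m %/% 2L + 1L]) / 2
  }
  res <- track
  res$values <- out
  res$metadata$pseudomedian_window_bp <- window_bp
  res
}
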