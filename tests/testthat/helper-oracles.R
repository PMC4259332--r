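# Independent brute-force oracles the fast implementations are checked
# against. Deliberately naive: loops, enumeration, per-cell simulation.

# Hodges-Lehmann pseudomedian by explicit enumeration of Walsh averages.
walsh_oracle <- function(x) {
  n <- length(x)
  w <- c()
  for (i in seq_len(n))
    for (j in i:n)
      w <- c(w, (x[i] + x[j]) / 2)
  median(w)
}

# Per-window brute-force pseudomedian filter (O(n k^2)).
pm_filter_oracle <- function(positions, values, window_bp) {
  half <- window_bp / 2
  vapply(seq_along(positions), function(i) {
    inwin <- abs(positions - positions[i]) <= half
    walsh_oracle(values[inwin])
  }, numeric(1))
}

# Per-cell Monte-Carlo fork-progression simulator: each cell independently
# fires each origin with its efficiency; a position is replicated when any
# fired origin's fork reaches it within the labelling time.
mc_replication_fraction <- function(x, origins, cfg, n_cells) {
  reach <- 1000 * cfg$fork_speed * pmax(0, cfg$t_total - origins$fire_time)
  hits <- integer(length(x))
  for (cell in seq_len(n_cells)) {
    fired <- runif(nrow(origins)) < origins$efficiency
    if (!any(fired)) next
    covered <- rep(FALSE, length(x))
    for (i in which(fired))
      covered <- covered | abs(x - origins$position[i]) <= reach[i]
    hits <- hits + covered
  }
  hits / n_cells
}

# Edited chromosome length by materializing the sequence as a symbol string
# and splicing the edits (right to left so coordinates stay valid).
edited_length_oracle <- function(ref_length, edits) {
  s <- rep("r", ref_length)
  e <- edits[order(-edits$start), , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    left <- if (e$start[i] > 1) s[1:(e$start[i] - 1)] else character(0)
    right <- if (e$end[i] < length(s)) s[(e$end[i] + 1):length(s)] else character(0)
    s <- c(left, rep("x", e$replacement_length[i]), right)
  }
  length(s)
}

# IRLS biweight recursion, written independently of the package version.
biweight_oracle <- function(x, c = 5, tol = 1e-8) {
  t <- median(x)
  s <- mad(x)
  if (s == 0) return(t)
  repeat {
    u <- (x - t) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    t2 <- sum(w * x) / sum(w)
    if (abs(t2 - t) <= tol) return(t2)
    t <- t2
  }
}

# Small random track on strictly increasing integer positions.
random_track <- function(n, step = 8, sd = 1, chrom = "chrT") {
  probe_track(chrom, seq(1, by = step, length.out = n), rnorm(n, 0, sd))
}
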