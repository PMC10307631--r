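# Independent brute-force oracles. These deliberately re-derive the
# statistics with naive loops and share no code with the package internals.

# chromVAR-style deviations by direct summation: fractional excess over the
# depth-proportional expectation, mean-centered across cells; z against the
# background replicates (sample sd).
oracle_deviations <- function(X, M, backgrounds) {
  X <- as.matrix(X); M <- as.matrix(M)
  n_motifs <- nrow(M); n_cells <- ncol(X); n_peaks <- nrow(X)
  d <- colSums(X); D <- sum(X)
  dev_for_peakset <- function(peaks) {      # peaks: integer multiset
    Tm <- 0
    for (p in peaks) Tm <- Tm + sum(X[p, ])
    dev <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      obs <- 0
      for (p in peaks) obs <- obs + X[p, i]
      E <- Tm * d[i] / D
      dev[i] <- (obs - E) / E
    }
    dev - mean(dev)
  }
  raw <- matrix(NA_real_, n_motifs, n_cells)
  z <- matrix(NA_real_, n_motifs, n_cells)
  B <- ncol(backgrounds)
  for (m in seq_len(n_motifs)) {
    peaks <- which(M[m, ] == 1)
    if (!length(peaks)) next
    raw[m, ] <- dev_for_peakset(peaks)
    bg <- matrix(0, B, n_cells)
    for (b in seq_len(B)) bg[b, ] <- dev_for_peakset(backgrounds[peaks, b])
    for (i in seq_len(n_cells)) {
      s <- sd(bg[, i])
      z[m, i] <- if (s > 0) (raw[m, i] - mean(bg[, i])) / s else NA_real_
    }
  }
  list(raw = raw, z = z)
}

# GSEA enrichment score by an explicit full running sum over all positions.
# s: rank statistic sorted decreasing; hit: logical per position.
oracle_es <- function(s, hit) {
  N <- length(s); m <- sum(hit)
  nr <- sum(abs(s[hit]))
  running <- 0
  best <- 0
  for (i in seq_len(N)) {
    running <- running + if (hit[i]) abs(s[[i]]) / nr else -1 / (N - m)
    if (abs(running) > abs(best)) best <- running
  }
  list(es = unname(best), final = unname(running))
}

# Wilcoxon rank-sum U by direct pair counting (ties count one half)
oracle_wilcoxon_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Poisson KL divergence between rates, closed form
oracle_poisson_kl <- function(t_from, t_to) t_to - t_from + t_from * log(t_from / t_to)
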