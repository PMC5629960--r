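# Shared fixtures: tiny deterministic spectra and an independent
# brute-force Kennard-Stone oracle used by the equivalence tests.

random_spectra <- function(n, p, seed = 1, wn = seq(4000, 5000, length.out = p)) {
  set.seed(seed)
  spectra_set(matrix(rnorm(n * p), n, p), wn)
}

# Small simulation config for fast tests: coarse grid, study-like structure.
tiny_cfg <- function(seed, n = 40, points = 120, ...) {
  sim_config(n_samples = n, n_points = points, seed = seed, ...)
}

# O(n^2 k) greedy max-min selection with an explicit distance matrix,
# written independently of kennard_stone(): plain loops, no shared code.
ks_oracle <- function(X, k) {
  X <- sweep(X, 2, colMeans(X))
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L); bestd <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(i) min(D[i, sel]))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}
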