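# Independent brute-force oracles. These stay deliberately naive (double
# loops, direct summation, literal formula transcription) so they cannot
# share a defect with the implementation paths they check.

# Audic-Claverie conditional kernel, summed term by term in log space.
oracle_ac_p <- function(x, y, n1, n2) {
  r <- n2 / n1
  logterm <- function(k) {
    k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1p(r)
  }
  lower <- sum(exp(logterm(0:y)))
  kmax <- max(y, ceiling((x + 1) * r)) + 2000
  upper <- sum(exp(logterm(y:kmax)))
  min(1, 2 * min(lower, upper))
}

# TOM by literal double loop over the formula.
oracle_tom <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Hypergeometric upper tail by direct enumeration of the pmf.
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(n, K)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up transcribed literally.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Pearson correlation by the raw sum formula.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Small standard synthetic data set reused by several test files.
small_sim <- function(seed = 11, n_genes = 300, module_sizes = rep(60L, 3)) {
  simulate_dataset(sim_config(n_genes = n_genes, module_sizes = module_sizes,
                              seed = seed))
}

log_expr_of <- function(sim) {
  log_transform(compute_fpkm(sim$counts, sim$gene_lengths, sim$library_sizes))
}
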