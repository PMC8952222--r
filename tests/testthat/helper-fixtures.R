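# Shared fixtures and independent oracle implementations used across tests.

tiny_msa <- function(id = "P1") {
  msa(id, c("sp1", "sp2", "sp3"),
      c("ACDEFGHIKLMN", "ACDEFGHIKLMN", "ACDEYGHIKL-N"))
}

# random binary tree with strictly positive branch lengths; its patristic
# matrix is additive by construction
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# Gotoh affine-gap global alignment score; gap of length k costs
# open + k * extend. Independent of the package's alignment path.
nw_score_oracle <- function(x, y, mat, open, extend) {
  xv <- strsplit(x, "")[[1]]; yv <- strsplit(y, "")[[1]]
  n <- length(xv); m <- length(yv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- mat[xv[i - 1], yv[j - 1]] +
        max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Benjamini-Hochberg step-up from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  ranked <- p[o] * n / seq_len(n)
  ranked <- rev(cummin(rev(ranked)))
  q[o] <- pmin(1, ranked)
  q
}

# Pooled-rate chi-squared from the definition.
chisq_oracle <- function(n_hits, n_comparisons) {
  p_hat <- sum(n_hits) / sum(n_comparisons)
  E <- n_comparisons * p_hat
  chi2 <- ifelse(E > 0, (n_hits - E)^2 / E, 0)
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# small engine config for fast tests
fast_config <- function(seed = 1, ...) {
  engine_config(seed = seed, null_samples = 1000, bootstrap_reps = 50, ...)
}
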