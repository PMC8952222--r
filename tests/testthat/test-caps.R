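star_times <- function(sp, t = 1) {
  n <- length(sp)
  m <- matrix(t, n, n, dimnames = list(sp, sp))
  diag(m) <- 0
  m
}

test_that("site variation matches a hand computation with BLOSUM62", {
  B62 <- substitution_matrix()
  sp <- c("s1", "s2", "s3", "s4")
  m <- msa("P", sp, c("A", "A", "G", "G"))
  tm <- matrix(0, 4, 4, dimnames = list(sp, sp))
  tm["s1", "s2"] <- tm["s2", "s1"] <- 0.2
  tm["s1", "s3"] <- tm["s3", "s1"] <- 0.8
  tm["s1", "s4"] <- tm["s4", "s1"] <- 1.0
  tm["s2", "s3"] <- tm["s3", "s2"] <- 0.6
  tm["s2", "s4"] <- tm["s4", "s2"] <- 0.9
  tm["s3", "s4"] <- tm["s4", "s3"] <- 0.4
  sv <- site_variation(m, 1, tm)
  # hand computation over the 6 ordered pairs (12,13,14,23,24,34)
  theta <- c(B62["A", "A"] / 0.2, B62["A", "G"] / 0.8, B62["A", "G"] / 1.0,
             B62["A", "G"] / 0.6, B62["A", "G"] / 0.9, B62["G", "G"] / 0.4)
  D_hand <- (theta - mean(theta))^2
  expect_equal(sv$theta_hat, theta)
  expect_equal(sv$D, D_hand)
  expect_true(all(sv$usable))
})

test_that("conserved columns with equal times give zero variation", {
  sp <- sprintf("s%d", 1:5)
  m <- msa("P", sp, rep("W", 5))
  sv <- site_variation(m, 1, star_times(sp, 0.7))
  expect_true(all(sv$D == 0))
})

test_that("centering identity and masking rules hold", {
  set.seed(31)
  sp <- sprintf("s%d", 1:8)
  m <- msa("P", sp, c(sample(coevscreen:::AA20, 6, TRUE), "X", "-"))
  tm <- star_times(sp)
  sv <- site_variation(m, 1, tm)
  th <- sv$theta_hat[sv$usable]
  expect_equal(mean(th - mean(th)), 0, tolerance = 1e-12)
  # pairs touching the gap or X rows are masked: 2 bad rows of 8
  expect_equal(sum(sv$usable), choose(6, 2))
  expect_equal(sv$usable_fraction, choose(6, 2) / choose(8, 2))
  # min_pair_fraction flags the site as a whole
  sv2 <- site_variation(m, 1, tm, min_pair_fraction = 0.9)
  expect_false(sv2$ok)
})

test_that("correlation is exact on linear cases and matches brute force", {
  expect_equal(correlate(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_true(is.na(correlate(c(1, 1, 1, 1), c(2, 4, 6, 8))))
  expect_true(is.na(correlate(c(1, 2, NA, NA), c(2, 4, NA, NA))))
  set.seed(7)
  for (k in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(correlate(a, b), num / den, tolerance = 1e-12)
    expect_identical(correlate(a, b), correlate(b, a))
  }
  expect_error(correlate(1:4, 1:5), class = "coev_contract")
})

test_that("permutation p-values follow the rank arithmetic", {
  null <- sort(runif(999))
  expect_equal(pvalue(2, null), 1 / 1000)
  # at the minimum every null value counts as >= rho
  expect_equal(pvalue(min(null), null), 1)
  expect_equal(pvalue(null[2], null), 999 / 1000)
  expect_equal(pvalue(-2, null), 1)
  # monotone non-increasing in rho
  x <- seq(-1, 2, by = 0.01)
  expect_true(all(diff(pvalue(x, null)) <= 0))
  # ties: p counts null values >= rho
  null2 <- c(0.1, 0.5, 0.5, 0.9)
  expect_equal(pvalue(0.5, null2), (1 + 3) / 5)
  # randomized p-values are uniform under the null (moment check)
  set.seed(8)
  obs <- sample(null, 500, replace = TRUE)
  pr <- pvalue(obs, null, randomized = TRUE)
  expect_gt(suppressWarnings(ks.test(pr, "punif"))$p.value, 0.01)
})

test_that("bootstrap support matches an independent resampling oracle", {
  set.seed(41)
  a <- rnorm(30); b <- 0.8 * a + rnorm(30, sd = 0.4)
  thr <- 0.3; reps <- 200; seed <- derive_seed(99, "boot-test")
  support <- bootstrap_support(a, b, thr, reps = reps, seed = seed)
  # oracle: same seed policy, independent code path
  set.seed(seed)
  hits <- 0
  for (r in seq_len(reps)) {
    idx <- sample.int(30, 30, replace = TRUE)
    if (stats::cor(a[idx], b[idx]) > thr) hits <- hits + 1
  }
  expect_equal(support, hits / reps)
  # collinear vectors: support 1 below threshold, 0 above an impossible one
  expect_equal(bootstrap_support(a, 2 * a, 0.9, seed = 1), 1)
  expect_equal(bootstrap_support(a, 2 * a, 1.5, seed = 1), 0)
})

test_that("null distribution is deterministic and thresholds by order statistic", {
  sim <- simulate_dataset("independent", n_proteins = 2, n_taxa = 20,
                          length = 60, seed = 51)
  pin <- build_pair_input(sim$msas[[1]], sim$msas[[2]],
                          tree_a = sim$tree, tree_b = sim$tree, min_shared = 10)
  cfg <- fast_config(seed = 51)
  sc1 <- scan_pair(pin, cfg, keep_matrices = TRUE)
  sc2 <- scan_pair(pin, cfg, keep_matrices = TRUE)
  expect_identical(sc1$null, sc2$null)
  expect_identical(sc1$hits, sc2$hits)
  N <- cfg$null_samples
  expect_equal(sc1$log$threshold, sc1$null[ceiling((1 - cfg$alpha) * N)])
})

test_that("a protein scanned against a copy of itself matches on the diagonal", {
  sim <- simulate_dataset("independent", n_proteins = 2, n_taxa = 20,
                          length = 50, seed = 61)
  a <- sim$msas[[1]]
  b <- a; b$protein_id <- "P99"
  pin <- build_pair_input(a, b, tree_a = sim$tree, tree_b = sim$tree,
                          min_shared = 10)
  sc <- scan_pair(pin, fast_config(seed = 61), keep_matrices = TRUE)
  shared <- intersect(sc$site_map_a, sc$site_map_b)
  ia <- match(shared, sc$site_map_a); ib <- match(shared, sc$site_map_b)
  expect_true(all(abs(sc$rho[cbind(ia, ib)] - 1) < 1e-12))
})

test_that("scans with too few usable columns abort cleanly", {
  sp <- sprintf("sp%02d", 1:12)
  m1 <- msa("A", sp, rep(strrep("A", 8), 12))   # invariant alignment
  m2 <- msa("B", sp, rep(strrep("C", 8), 12))
  pin <- build_pair_input(m1, m2, min_shared = 5)
  sc <- scan_pair(pin, fast_config())
  expect_true(sc$log$aborted)
  expect_match(sc$log$reason, "usable<10")
  expect_equal(nrow(sc$hits), 0)
})

test_that("bidirectional scan intersects runs and skips the reverse on zero hits", {
  # zero-hit case: invariant alignments abort, no hits, reverse skipped
  sp <- sprintf("sp%02d", 1:12)
  m1 <- msa("A", sp, rep(strrep("A", 8), 12))
  m2 <- msa("B", sp, rep(strrep("C", 8), 12))
  bs0 <- bidirectional_scan(build_pair_input(m1, m2, min_shared = 5),
                            fast_config())
  expect_null(bs0$log_rev)
  expect_equal(nrow(bs0$hits), 0)
  # coevolving pair: intersection is a subset of the forward run's hits and
  # strongly injected site pairs survive both runs
  sim <- simulate_dataset("coevolving", n_proteins = 2, n_taxa = 25,
                          length = 80, n_coupled = 4, coupling = 1, seed = 71)
  pin <- build_pair_input(sim$msas[[1]], sim$msas[[2]],
                          tree_a = sim$tree, tree_b = sim$tree, min_shared = 10)
  cfg <- engine_config(seed = 71, null_samples = 2000)
  fwd <- scan_pair(pin, cfg, stream = "fwd")
  bs <- bidirectional_scan(pin, cfg)
  key <- function(df) paste(df$site_a, df$site_b)
  expect_true(all(key(bs$hits) %in% key(fwd$hits)))
  truth_key <- paste(sim$truth$site_a, sim$truth$site_b)
  expect_gt(sum(truth_key %in% key(bs$hits)), 0)
})

test_that("scan results are invariant to the order proteins are supplied", {
  sim <- simulate_dataset("coevolving", n_proteins = 2, n_taxa = 20,
                          length = 60, n_coupled = 3, coupling = 1, seed = 81)
  cfg <- fast_config(seed = 81)
  p1 <- build_pair_input(sim$msas[[1]], sim$msas[[2]],
                         tree_a = sim$tree, tree_b = sim$tree, min_shared = 10)
  p2 <- build_pair_input(sim$msas[[2]], sim$msas[[1]],
                         tree_b = sim$tree, tree_a = sim$tree, min_shared = 10)
  expect_identical(bidirectional_scan(p1, cfg)$hits,
                   bidirectional_scan(p2, cfg)$hits)
})

test_that("engine configuration validates its ranges", {
  expect_error(engine_config(alpha = 2), class = "coev_config")
  expect_error(engine_config(bootstrap_threshold = 1.5), class = "coev_config")
  expect_error(engine_config(null_samples = 10), class = "coev_config")
  cfg <- engine_config()
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$bootstrap_threshold, 0.6)
  expect_equal(cfg$null_samples, 10000L)
})

test_that("Fitch substitution counts match the phangorn oracle", {
  skip_if_not_installed("phangorn")
  sim <- simulate_dataset("independent", n_proteins = 2, n_taxa = 15,
                          length = 40, seed = 91)
  x <- sim$msas[[1]]
  tr <- sim$tree
  ours <- coevscreen:::fitch_scores(tr, x)
  pd <- phangorn::phyDat(x$seq, type = "AA")
  theirs <- phangorn::fitch(tr, pd, site = "site")
  expect_equal(ours, as.integer(theirs[attr(pd, "index")]))
})
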