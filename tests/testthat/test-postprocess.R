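mk_results <- function(hits_df, pair_df) {
  structure(list(residue_table = hits_df, pair_table = pair_df),
            class = "coev_results")
}

test_that("BH adjustment matches the textbook step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 0)), class = "coev_domain")
  expect_error(bh_fdr(c(0.1, 1.2)), class = "coev_domain")
  set.seed(13)
  for (k in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-15)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("chi-squared per pair matches the hand-computed example", {
  pt <- data.frame(pair_id = c("A__B", "A__C", "B__C"),
                   n_hits = c(3L, 0L, 1L),
                   n_comparisons = c(10000L, 8000L, 12000L),
                   aborted = FALSE, chi2 = NA_real_, chi2_p = NA_real_,
                   min_q = NA_real_, stringsAsFactors = FALSE)
  res <- chisq_pairs(mk_results(data.frame(), pt))
  # p_hat = 4/30000, E1 = 4/3, chi2_1 = (3 - 4/3)^2 / (4/3)
  expect_equal(res$pair_table$chi2[1], (3 - 4 / 3)^2 / (4 / 3), tolerance = 1e-10)
  expect_equal(res$pair_table$chi2[1], 2.0833, tolerance = 1e-4)
  orc <- chisq_oracle(pt$n_hits, pt$n_comparisons)
  expect_equal(res$pair_table$chi2, orc$chi2)
  expect_equal(res$pair_table$chi2_p, orc$p)
  # residual identity: sum(n_hits - E) = 0 by construction of p_hat
  E <- pt$n_comparisons * sum(pt$n_hits) / sum(pt$n_comparisons)
  expect_equal(sum(pt$n_hits - E), 0, tolerance = 1e-10)
  # uniform rate -> all chi2 zero
  pt2 <- pt; pt2$n_hits <- c(10L, 8L, 12L)  # exactly proportional
  res2 <- chisq_pairs(mk_results(data.frame(), pt2))
  expect_equal(res2$pair_table$chi2, rep(0, 3), tolerance = 1e-10)
  # doubling all counts doubles chi2
  pt3 <- pt; pt3$n_hits <- pt$n_hits * 2L; pt3$n_comparisons <- pt$n_comparisons * 2L
  res3 <- chisq_pairs(mk_results(data.frame(), pt3))
  expect_equal(res3$pair_table$chi2, 2 * res$pair_table$chi2, tolerance = 1e-10)
  # all-zero hits: warning, chi2 0, p 1
  pt4 <- pt; pt4$n_hits <- 0L
  expect_warning(res4 <- chisq_pairs(mk_results(data.frame(), pt4)))
  expect_equal(res4$pair_table$chi2, rep(0, 3))
  expect_equal(res4$pair_table$chi2_p, rep(1, 3))
})

toy_tables <- function() {
  hits <- data.frame(
    pair_id = rep("A__B", 6), site_a = 1:6, ref_pos_a = 1:6,
    residue_a = "A", site_b = 1:6, ref_pos_b = 1:6, residue_b = "C",
    rho_fwd = 0.9, rho_rev = 0.9, support_fwd = 1, support_rev = 1,
    p = c(0.001, 0.004, 0.006, 0.001, 0.001, 0.002),
    gap_frac_a = c(0.1, 0.1, 0.1, 0.1, 0.25, 0.1),
    gap_frac_b = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.3),
    good_a = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    good_b = TRUE, q = 0.01, stringsAsFactors = FALSE)
  pt <- data.frame(pair_id = "A__B", n_hits = 6L, n_comparisons = 1000L,
                   aborted = FALSE, chi2 = NA_real_, chi2_p = NA_real_,
                   min_q = 0.01, stringsAsFactors = FALSE)
  mk_results(hits, pt)
}

test_that("the three printed filters keep exactly the qualifying rows", {
  res <- filter_results(toy_tables())
  # rows 1 and 2 survive: row 3 fails p, row 4 fails good, rows 5-6 fail gaps
  expect_equal(res$residue_table$site_a, c(1L, 2L))
  expect_equal(res$pair_table$n_hits, 2L)
  # identity filter
  res2 <- filter_results(toy_tables(), p_max = 1, require_good = FALSE,
                         gap_max = 1.01)
  expect_equal(nrow(res2$residue_table), 6)
  # strictness: p == p_max and gap == gap_max are excluded
  res3 <- filter_results(toy_tables(), p_max = 0.001, gap_max = 0.25)
  expect_equal(nrow(res3$residue_table), 0)
  # empty input
  empty <- filter_results(mk_results(toy_tables()$residue_table[0, ],
                                     toy_tables()$pair_table))
  expect_equal(nrow(empty$residue_table), 0)
  expect_equal(empty$pair_table$n_hits, 0L)
  # idempotence
  expect_identical(filter_results(res), res)
})

test_that("network export writes deterministic node and edge tables", {
  hits <- rbind(toy_tables()$residue_table[1:2, ],
                within(toy_tables()$residue_table[1, ],
                       pair_id <- "B__C"))
  pt <- data.frame(pair_id = c("A__B", "B__C", "A__C"),
                   n_hits = c(2L, 1L, 0L), n_comparisons = 1000L,
                   aborted = FALSE, chi2 = 1, chi2_p = 0.3, min_q = 0.01,
                   stringsAsFactors = FALSE)
  res <- mk_results(hits, pt)
  d1 <- tempfile(); d2 <- tempfile()
  export_network(res, d1)
  edges <- read.delim(file.path(d1, "edges.tsv"))
  nodes <- read.delim(file.path(d1, "nodes.tsv"))
  expect_equal(nrow(edges), 2)              # zero-hit pair excluded
  expect_equal(nodes$degree[nodes$protein == "B"], 2)
  export_network(res, d2)
  expect_identical(readLines(file.path(d1, "edges.tsv")),
                   readLines(file.path(d2, "edges.tsv")))
  expect_identical(readLines(file.path(d1, "nodes.tsv")),
                   readLines(file.path(d2, "nodes.tsv")))
  # zero surviving pairs: headers-only files
  res0 <- mk_results(hits[0, ], within(pt, n_hits <- 0L))
  d3 <- tempfile()
  export_network(res0, d3)
  expect_equal(length(readLines(file.path(d3, "edges.tsv"))), 1)
})

test_that("result collection pools hits and fills per-pair q-values", {
  sim <- simulate_dataset("coevolving", n_proteins = 3, n_taxa = 20,
                          length = 60, n_coupled = 3, coupling = 1, seed = 101)
  cfg <- fast_config(seed = 101)
  pairs <- enumerate_pairs(names(sim$msas))
  scans <- lapply(seq_len(nrow(pairs)), function(k) {
    pin <- build_pair_input(sim$msas[[pairs$a[k]]], sim$msas[[pairs$b[k]]],
                            tree_a = sim$tree, tree_b = sim$tree,
                            min_shared = 10)
    bidirectional_scan(pin, cfg)
  })
  res <- collect_results(scans)
  expect_equal(nrow(res$pair_table), 3)
  expect_true(all(res$residue_table$pair_id %in% res$pair_table$pair_id))
  expect_true(all(res$residue_table$q >= res$residue_table$p))
  if (nrow(res$residue_table))
    expect_equal(res$residue_table$q, bh_oracle(res$residue_table$p))
  expect_true(all(res$pair_table$n_hits <= res$pair_table$n_comparisons))
})
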