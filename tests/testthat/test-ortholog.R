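test_that("global alignment matches an independent dynamic-programming oracle", {
  B62 <- substitution_matrix()
  ga <- global_align("HEAGAWGHEE", "PAWHEAE", gap_open = 10, gap_extend = 1)
  expect_equal(ga$score,
               nw_score_oracle("HEAGAWGHEE", "PAWHEAE", B62, 10, 1))
  # a handful of random short sequences
  set.seed(3)
  for (k in 1:10) {
    a <- paste(sample(coevscreen:::AA20, sample(4:12, 1), TRUE), collapse = "")
    b <- paste(sample(coevscreen:::AA20, sample(4:12, 1), TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, nw_score_oracle(a, b, B62, 10, 1),
                 info = paste(a, b))
  }
})

test_that("alignment statistics behave on degenerate cases", {
  ga <- global_align("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(ga$identity_pct, 100)
  expect_equal(ga$gap_pct, 0)
  # single deletion: gaps = 100/len, identity 100 over aligned positions
  ga2 <- global_align("ACDEFGHIK", "ACDEFGHIKL")
  expect_equal(ga2$gap_pct, 100 / 10)
  expect_equal(ga2$identity_pct, 100)
  expect_error(global_align("AC1DE", "ACDE"), class = "coev_alphabet")
  expect_error(global_align("", "ACDE"), class = "coev_empty_input")
  # symmetric score for a symmetric matrix
  expect_equal(global_align("HEAGAWGHEE", "PAWHEAE")$score,
               global_align("PAWHEAE", "HEAGAWGHEE")$score)
})

test_that("best-hit selection takes the argmax and applies the filters", {
  ref <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  hs <- list(protein_id = "P1", reference = ref,
             candidates = data.frame(
               species = c("sp1", "sp1", "sp2", "sp3"),
               candidate_id = c("c1", "c2", "c3", "c4"),
               sequence = c(ref,                                  # exact
                            substr(ref, 1, 20),                   # truncated
                            ref,                                  # exact
                            paste(rep("W", 33), collapse = "")),  # unrelated
               stringsAsFactors = FALSE))
  out <- select_best_hit(hs)
  expect_identical(out$selected$candidate_id[out$selected$species == "sp1"], "c1")
  expect_true("sp2" %in% out$selected$species)
  expect_true("sp3" %in% out$rejected$species)
  expect_match(out$rejected$reason[out$rejected$species == "sp3"], "identity<35")
  # partition property: every species in exactly one of the three outputs
  all_sp <- unique(hs$candidates$species)
  expect_setequal(c(out$selected$species, out$rejected$species, out$missing),
                  all_sp)
  expect_false(any(duplicated(out$selected$species)))
})

test_that("score ties break by lexicographically smallest candidate id", {
  ref <- "ACDEFGHIKLMNPQRSTVWY"
  hs <- list(protein_id = "P1", reference = ref,
             candidates = data.frame(
               species = "sp1", candidate_id = c("z9", "a1"),
               sequence = c(ref, ref), stringsAsFactors = FALSE))
  expect_identical(select_best_hit(hs)$selected$candidate_id, "a1")
})

test_that("retention is monotone in the identity and gap thresholds", {
  ref <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  set.seed(9)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(v), k)
    v[pos] <- sample(coevscreen:::AA20, k, TRUE)
    paste(v, collapse = "")
  }
  hs <- list(protein_id = "P1", reference = ref,
             candidates = data.frame(
               species = sprintf("sp%d", 1:6), candidate_id = sprintf("c%d", 1:6),
               sequence = vapply(c(0, 3, 8, 14, 20, 26), mutate, "", s = ref),
               stringsAsFactors = FALSE))
  strict <- select_best_hit(hs, min_identity = 60, max_gaps = 10)
  loose <- select_best_hit(hs, min_identity = 35, max_gaps = 25)
  expect_true(all(strict$selected$species %in% loose$selected$species))
})

test_that("divergence screen removes the one outlier sequence", {
  set.seed(11)
  base <- paste(sample(coevscreen:::AA20, 40, TRUE), collapse = "")
  near <- vapply(1:9, function(i) {
    v <- strsplit(base, "")[[1]]
    pos <- sample(40, 2)
    v[pos] <- sample(coevscreen:::AA20, 2, TRUE)
    paste(v, collapse = "")
  }, "")
  outlier <- paste(sample(coevscreen:::AA20, 40, TRUE), collapse = "")
  seqs <- stats::setNames(c(near, outlier), sprintf("sp%02d", 1:10))
  scr <- divergence_screen(seqs, cutoff = 0.95)
  expect_identical(scr$removed$species, "sp10")
  expect_equal(length(scr$retained), 9)
  # identical sequences: nothing removed
  same <- stats::setNames(rep(base, 5), sprintf("s%d", 1:5))
  expect_equal(nrow(divergence_screen(same)$removed), 0)
  # cutoff 0: vacuous
  expect_equal(nrow(divergence_screen(seqs, cutoff = 0)$removed), 0)
  # < 4 sequences: skipped with warning
  expect_warning(out <- divergence_screen(seqs[1:3]), "skipped")
  expect_equal(length(out$retained), 3)
})
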