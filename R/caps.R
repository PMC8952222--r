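# The coevolution engine.
#
# For one protein pair, every alignment column is turned into an
# evolutionary-variation vector indexed by unordered sequence pairs (i < j):
# the BLOSUM score of the residue transition between sequences i and j,
# normalized by their patristic divergence time. Inter-protein coevolution
# is scored as the Pearson correlation between the variation vectors of a
# column of protein A and a column of protein B, assessed against an
# empirical null of random inter-protein column pairs, with bootstrap
# support over sequence pairs and a bidirectional double run.
#
# Three variation flavours are available:
#  * "binary" (default): the transition indicator 1[x_i != x_j] normalized
#    by divergence time. Robust: two coevolving columns share their
#    substitution placement regardless of which residues were exchanged.
#  * "blosum": substitution severity (mean self-score minus the exchange
#    score, zero when the residues agree) normalized by divergence time;
#    weights transitions by how radical they are.
#  * "classic": the squared centered residual (theta_hat - mean)^2 of the
#    raw time-normalized BLOSUM transition score. This is the textbook
#    correlated-variation score; it is retained for comparison but is
#    dominated by shared phylogenetic structure (see the methods vignette).

#' Engine configuration
#'
#' @param alpha Significance level for the null-quantile threshold (0.01).
#' @param bootstrap_threshold Minimum bootstrap support for a hit (0.6).
#' @param bootstrap_reps Bootstrap resamples per candidate site pair (100).
#' @param null_samples Size of the empirical null sample (10000).
#' @param seed Integer base seed; all Monte-Carlo streams derive from it.
#' @param min_pair_fraction Minimum fraction of usable sequence pairs for a
#'   column to be scored (0.5).
#' @param tail `"positive"` (default; coevolution is correlated variation)
#'   or `"two_sided"`.
#' @param matrix Scoring matrix name (default `"BLOSUM62"`).
#' @param t_min Divergence-time floor in substitutions/site (1e-6).
#' @param min_subst Minimum number of inferred substitutions (Fitch
#'   parsimony score on the pair tree) for a column to be scored (2).
#'   Columns below this carry at most one substitution event, whose
#'   placement is uninformative about coupling.
#' @param variation `"binary"` (default), `"blosum"` or `"classic"`, see
#'   Details.
#' @param null_method `"paired"` (default): null correlations from random
#'   inter-protein column pairs, matching the distribution of the observed
#'   statistic under independence. `"permuted"`: additionally permutes the
#'   sequence-pair indexing of the second column, which destroys the shared
#'   divergence-time structure and is kept only for comparison.
#' @param ref_species Species whose ungapped coordinates are reported
#'   (default: first shared species alphabetically).
#' @return A validated list of class `coev_engine_config`.
#' @export
engine_config <- function(alpha = 0.01, bootstrap_threshold = 0.6,
                          bootstrap_reps = 100, null_samples = 10000,
                          seed = 1, min_pair_fraction = 0.5,
                          tail = c("positive", "two_sided"),
                          matrix = "BLOSUM62", t_min = 1e-6, min_subst = 2,
                          variation = c("binary", "blosum", "classic"),
                          null_method = c("paired", "permuted"),
                          ref_species = NULL) {
  tail <- match.arg(tail)
  variation <- match.arg(variation)
  null_method <- match.arg(null_method)
  chk <- function(cond, what) if (!cond) stop_coev("coev_config", "invalid %s", what)
  chk(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha")
  chk(is.numeric(bootstrap_threshold) && bootstrap_threshold >= 0 &&
        bootstrap_threshold <= 1, "bootstrap_threshold")
  chk(bootstrap_reps >= 1, "bootstrap_reps")
  chk(null_samples >= 100, "null_samples")
  chk(min_pair_fraction >= 0 && min_pair_fraction <= 1, "min_pair_fraction")
  chk(t_min > 0, "t_min")
  chk(min_subst >= 0, "min_subst")
  structure(list(alpha = alpha, bootstrap_threshold = bootstrap_threshold,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 null_samples = as.integer(null_samples),
                 seed = as.integer(seed),
                 min_pair_fraction = min_pair_fraction, tail = tail,
                 matrix = matrix, t_min = t_min,
                 min_subst = as.integer(min_subst),
                 variation = variation, null_method = null_method,
                 ref_species = ref_species),
            class = "coev_engine_config")
}

# integer coding of an alignment: 1..20 = AA20, 21 = X, 22 = '-'
msa_codes <- function(x) {
  codes <- match(x$seq, c(AA20, "X", "-"))
  matrix(codes, nrow = nrow(x$seq), dimnames = dimnames(x$seq))
}

# unordered sequence-pair index (i < j) for n rows, row-major
pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Evolutionary variation of one alignment column
#'
#' For each usable sequence pair (i, j): `theta = blosum(x_i, x_j)`,
#' `theta_hat = theta / max(t_ij, t_min)`, and
#' `D = (theta_hat - mean(theta_hat))^2` with the mean over usable pairs.
#' Pairs where either residue is a gap or 'X', or whose divergence time is
#' not positive, are masked out. A column whose usable fraction falls below
#' `min_pair_fraction` is flagged unusable as a whole.
#'
#' @param x A `coev_msa`.
#' @param column Column index (1-based).
#' @param times Patristic distance matrix covering the alignment's species.
#' @param blosum Scoring matrix (default BLOSUM62).
#' @param t_min Divergence-time floor.
#' @param min_pair_fraction Minimum usable fraction.
#' @return Object of class `coev_site_variation`: `protein_id`, `column`,
#'   `theta_hat` (length n(n-1)/2, `NA` where masked), `D` (same layout),
#'   `usable` (logical), `usable_fraction`, `ok`.
#' @export
site_variation <- function(x, column, times, blosum = substitution_matrix(),
                           t_min = 1e-6, min_pair_fraction = 0.5) {
  stopifnot(inherits(x, "coev_msa"))
  n <- nrow(x$seq)
  if (column < 1 || column > ncol(x$seq))
    stop_coev("coev_shape", "column %d out of range", column)
  if (!all(x$species %in% rownames(times)))
    stop_coev("coev_contract", "times matrix does not cover all species")
  tm <- times[x$species, x$species]
  pi_ <- pair_index(n)
  tvec <- tm[pi_]
  code <- match(x$seq[, column], c(AA20, "X", "-"))
  EB <- expand_matrix(blosum)
  theta <- EB[cbind(code[pi_[, 1]], code[pi_[, 2]])]
  usable <- code[pi_[, 1]] <= 20L & code[pi_[, 2]] <= 20L & tvec > 0
  theta_hat <- rep(NA_real_, nrow(pi_))
  theta_hat[usable] <- theta[usable] / pmax(tvec[usable], t_min)
  D <- rep(NA_real_, nrow(pi_))
  if (any(usable)) {
    mu <- mean(theta_hat[usable])
    D[usable] <- (theta_hat[usable] - mu)^2
  }
  frac <- mean(usable)
  structure(list(protein_id = x$protein_id, column = column,
                 theta_hat = theta_hat, D = D, usable = usable,
                 usable_fraction = frac, ok = frac >= min_pair_fraction),
            class = "coev_site_variation")
}

# Variation matrix for all columns: rows = sequence pairs (i < j), cols =
# alignment columns; NA where the pair is unusable (gap/X or non-positive
# divergence time). `mode` selects the flavour documented at the top of
# this file.
variation_matrix <- function(x, times, blosum, t_min, mode = "binary") {
  if (mode == "classic") {
    TH <- variation_matrix(x, times, blosum, t_min, "raw")
    return(sweep(TH, 2, colMeans(TH, na.rm = TRUE), "-")^2)
  }
  n <- nrow(x$seq)
  codes <- msa_codes(x)
  pi_ <- pair_index(n)
  tm <- times[x$species, x$species]
  tvec <- pmax(tm[pi_], t_min)
  tpos <- tm[pi_] > 0
  EB <- expand_matrix(blosum)
  diag20 <- c(diag(blosum), 0, 0)
  L <- ncol(codes)
  TH <- matrix(NA_real_, nrow(pi_), L)
  for (jcol in seq_len(L)) {
    code <- codes[, jcol]
    ci <- code[pi_[, 1]]; cj <- code[pi_[, 2]]
    ok <- ci <= 20L & cj <= 20L & tpos
    th <- switch(mode,
      binary = as.numeric(ci != cj) / tvec,
      blosum = ((diag20[ci] + diag20[cj]) / 2 - EB[cbind(ci, cj)]) / tvec,
      raw = EB[cbind(ci, cj)] / tvec)
    th[!ok] <- NA_real_
    TH[, jcol] <- th
  }
  TH
}

#' Pearson correlation of two site-variation vectors
#'
#' Computed over the intersection of usable entries; undefined (`NA`) when
#' the intersection has fewer than 3 pairs or either vector is constant on
#' it. Accepts [site_variation()] objects (their `D` field) or bare numeric
#' vectors.
#'
#' @param a,b `coev_site_variation` objects or numeric vectors with `NA`
#'   at unusable entries.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
correlate <- function(a, b) {
  va <- if (inherits(a, "coev_site_variation")) a$D else a
  vb <- if (inherits(b, "coev_site_variation")) b$D else b
  if (length(va) != length(vb))
    stop_coev("coev_contract", "variation vectors use different pair indexing")
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3L) return(NA_real_)
  x <- va[ok]; y <- vb[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Permutation p-value against a sorted null sample
#'
#' `p = (1 + #\{null >= rho\}) / (N + 1)` for the positive tail; for the
#' two-sided test the smaller tail is doubled (capped at 1).
#'
#' The correlation of transition-indicator vectors is a discrete statistic:
#' distinct column pairs can tie exactly, which makes the reported p-values
#' conservative and lumpy. For calibration diagnostics, `randomized = TRUE`
#' returns the randomized (tie-broken) p-value
#' `p = (U + #\{null > rho\} + V (1 + #\{null = rho\})) / (N + 1)`, which is
#' exactly uniform under the null; it uses the current RNG stream, so seed
#' it for reproducibility. Reported hit p-values always use the
#' non-randomized, conservative form.
#'
#' @param rho_obs Observed correlation(s); vectorized.
#' @param null Sorted (ascending) numeric null sample.
#' @param tail `"positive"` or `"two_sided"`.
#' @param randomized Break ties uniformly (positive tail only).
#' @return p-value(s) in `(0, 1]`.
#' @export
pvalue <- function(rho_obs, null, tail = "positive", randomized = FALSE) {
  n <- length(null)
  if (n == 0L) stop_coev("coev_contract", "empty null sample")
  null <- sort(null)
  n_lt <- findInterval(rho_obs, null, left.open = TRUE)  # #{null < rho}
  n_le <- findInterval(rho_obs, null)                    # #{null <= rho}
  if (randomized) {
    if (tail != "positive")
      stop_coev("coev_contract", "randomized p-values are positive-tail only")
    n_eq <- n_le - n_lt
    return((stats::runif(length(rho_obs)) * (1 + n_eq) + (n - n_le)) / (n + 1))
  }
  p_pos <- (1 + n - n_lt) / (n + 1)
  if (tail == "positive") return(p_pos)
  p_neg <- (1 + n_le) / (n + 1)
  pmin(1, 2 * pmin(p_pos, p_neg))
}

#' Empirical null distribution of inter-protein column correlations
#'
#' Draws `null_samples` correlations between a random usable column of A
#' and a random usable column of B. With `null_method = "paired"` the
#' natural sequence-pair indexing is kept, so the null matches the
#' distribution of the observed statistic under independence; with
#' `"permuted"` the indexing of the B column is randomly permuted per draw.
#'
#' @param za,zb Variation matrices (sequence pairs x columns).
#' @param usable_a,usable_b Indices of usable columns.
#' @param cfg An [engine_config()].
#' @param seed Integer seed for the draw.
#' @param rho Optional precomputed correlation matrix
#'   (`length(usable_a) x length(usable_b)`) to draw paired nulls from.
#' @return List with `null` (sorted ascending) and `threshold` (the
#'   `ceiling((1-alpha) N)`-th order statistic for the positive tail).
#' @export
null_distribution <- function(za, zb, usable_a, usable_b, cfg, seed,
                              rho = NULL) {
  if (length(usable_a) < 10L || length(usable_b) < 10L)
    stop_coev("coev_too_few_columns",
              "fewer than 10 usable columns (%d, %d)",
              length(usable_a), length(usable_b))
  N <- cfg$null_samples
  nul <- with_seed(seed, function() {
    ia <- sample.int(length(usable_a), N, replace = TRUE)
    ib <- sample.int(length(usable_b), N, replace = TRUE)
    if (cfg$null_method == "paired" && !is.null(rho)) {
      rho[cbind(ia, ib)]
    } else if (cfg$null_method == "paired") {
      vapply(seq_len(N), function(k)
        correlate(za[, usable_a[ia[k]]], zb[, usable_b[ib[k]]]), 0)
    } else {
      np <- nrow(za)
      vapply(seq_len(N), function(k)
        correlate(za[, usable_a[ia[k]]], zb[sample.int(np), usable_b[ib[k]]]), 0)
    }
  })
  nul[is.na(nul)] <- 0
  nul <- sort(nul)
  k <- ceiling((1 - cfg$alpha) * N)
  if (cfg$tail == "two_sided") k <- ceiling((1 - cfg$alpha / 2) * N)
  list(null = nul, threshold = nul[k])
}

#' Bootstrap support of a site-pair correlation
#'
#' Resamples the usable sequence-pair indices with replacement and reports
#' the fraction of resamples whose correlation exceeds `threshold`.
#'
#' @param va,vb Variation vectors (`NA` at unusable entries).
#' @param threshold Correlation threshold the resamples must exceed.
#' @param reps Number of resamples.
#' @param seed Integer seed (derive one per site pair for determinism).
#' @return Support fraction in `[0, 1]`.
#' @export
bootstrap_support <- function(va, vb, threshold, reps = 100, seed = 1) {
  ok <- !is.na(va) & !is.na(vb)
  x <- va[ok]; y <- vb[ok]
  n <- length(x)
  if (n < 3L) return(0)
  with_seed(seed, function() {
    hits <- 0L
    for (r in seq_len(reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      rr <- suppressWarnings(stats::cor(x[idx], y[idx]))
      if (!is.na(rr) && rr > threshold) hits <- hits + 1L
    }
    hits / reps
  })
}

# Fitch parsimony score of one column on a tree (bitmask sets; gaps/X are
# treated as missing and contribute the full residue set).
fitch_scores <- function(tree, x, columns = NULL) {
  codes <- msa_codes(x)
  columns <- columns %||% seq_len(ncol(codes))
  po <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  ord <- match(tree$tip.label, x$species)
  full <- bitwShiftL(1L, 20L) - 1L
  vapply(columns, function(jcol) {
    code <- codes[ord, jcol]
    sets <- integer(nt + tree$Nnode)
    sets[seq_len(nt)] <- ifelse(code <= 20L, bitwShiftL(1L, code - 1L), full)
    score <- 0L
    k <- 1L
    nedge <- nrow(po$edge)
    while (k <= nedge) {
      parent <- po$edge[k, 1]
      acc <- 0L
      while (k <= nedge && po$edge[k, 1] == parent) {
        child <- sets[po$edge[k, 2]]
        if (acc == 0L) acc <- child
        else {
          inter <- bitwAnd(acc, child)
          if (inter != 0L) acc <- inter
          else { acc <- bitwOr(acc, child); score <- score + 1L }
        }
        k <- k + 1L
      }
      sets[parent] <- acc
    }
    score
  }, 0L)
}

# Infer (or prune) the tree for one protein of a pair.
pair_tree <- function(msa, tree) {
  if (!is.null(tree)) return(tree)
  root_min_height(nj_tree(protein_distance_matrix(msa)))
}

#' Scan one protein pair for coevolving column pairs
#'
#' Scores all usable column pairs; a hit requires `rho >= threshold` (the
#' null-quantile threshold at `alpha`) and bootstrap support at least
#' `bootstrap_threshold`. All Monte-Carlo draws are seeded from
#' `cfg$seed`, the pair id and `stream`, so the result is independent of
#' scheduling and input order.
#'
#' @param pair A `coev_pair_input`.
#' @param cfg An [engine_config()].
#' @param stream RNG stream label (`"fwd"` or `"rev"`).
#' @param quality_a,quality_b Optional [column_quality()] tables in
#'   original protein coordinates; computed from the trimmed alignments
#'   when absent.
#' @param keep_matrices Keep the correlation matrix and null sample in the
#'   result (for calibration work); default `FALSE`.
#' @return List of class `coev_scan`: `hits` (data.frame), `log` (counts,
#'   threshold, abort reason), and optionally `rho`, `null`, `usable_a`,
#'   `usable_b`, `site_map_a`, `site_map_b`.
#' @export
scan_pair <- function(pair, cfg = engine_config(), stream = "fwd",
                      quality_a = NULL, quality_b = NULL,
                      keep_matrices = FALSE) {
  stopifnot(inherits(pair, "coev_pair_input"))
  blosum <- substitution_matrix(cfg$matrix)
  tree_a <- pair_tree(pair$msa_a, pair$tree_a)
  tree_b <- pair_tree(pair$msa_b, pair$tree_b)
  times_a <- patristic_distances(tree_a)
  times_b <- patristic_distances(tree_b)

  prep <- function(x, times, tree) {
    Z <- variation_matrix(x, times, blosum, cfg$t_min, cfg$variation)
    usable <- colMeans(!is.na(Z)) >= cfg$min_pair_fraction
    if (cfg$min_subst > 0L) {
      fs <- fitch_scores(tree, x, which(usable))
      usable[which(usable)[fs < cfg$min_subst]] <- FALSE
    }
    # drop zero-variance columns (constant variation is uninformative)
    sds <- apply(Z, 2, stats::sd, na.rm = TRUE)
    usable <- usable & !is.na(sds) & sds > 0
    list(Z = Z, usable = which(usable))
  }
  pa <- prep(pair$msa_a, times_a, tree_a)
  pb <- prep(pair$msa_b, times_b, tree_b)

  log <- list(pair_id = pair$pair_id, stream = stream,
              n_usable_a = length(pa$usable), n_usable_b = length(pb$usable),
              n_comparisons = length(pa$usable) * length(pb$usable),
              n_candidates = 0L, n_hits = 0L, threshold = NA_real_,
              aborted = FALSE, reason = NA_character_)
  empty_hits <- data.frame(
    pair_id = character(), site_a = integer(), ref_pos_a = integer(),
    residue_a = character(), site_b = integer(), ref_pos_b = integer(),
    residue_b = character(), rho = numeric(), support = numeric(),
    p = numeric(), gap_frac_a = numeric(), gap_frac_b = numeric(),
    good_a = logical(), good_b = logical(), stringsAsFactors = FALSE)
  if (length(pa$usable) < 10L || length(pb$usable) < 10L) {
    log$aborted <- TRUE
    log$reason <- sprintf("usable<10 (%d, %d)", length(pa$usable), length(pb$usable))
    return(structure(list(hits = empty_hits, log = log), class = "coev_scan"))
  }

  ZA <- pa$Z[, pa$usable, drop = FALSE]
  ZB <- pb$Z[, pb$usable, drop = FALSE]
  rho <- suppressWarnings(stats::cor(ZA, ZB, use = "pairwise.complete.obs"))
  ncomp <- crossprod(!is.na(ZA), !is.na(ZB))
  rho[ncomp < 3] <- NA_real_

  nd <- null_distribution(pa$Z, pb$Z, pa$usable, pb$usable, cfg,
                          seed = derive_seed(cfg$seed, pair$pair_id, stream, "null"),
                          rho = rho)
  log$threshold <- nd$threshold

  cand <- which(!is.na(rho) & rho >= nd$threshold, arr.ind = TRUE)
  log$n_candidates <- nrow(cand)

  qual_lookup <- function(qual, x, col_map) {
    if (is.null(qual)) qual <- column_quality(x)
    if (nrow(qual) >= max(col_map)) qual[col_map, , drop = FALSE]
    else stop_coev("coev_contract", "quality table shorter than alignment")
  }
  # quality in trimmed-column order (rows parallel to pair columns)
  qa <- if (is.null(quality_a)) {
    q <- column_quality(pair$msa_a); q$column <- pair$col_map_a; q
  } else qual_lookup(quality_a, pair$msa_a, pair$col_map_a)
  qb <- if (is.null(quality_b)) {
    q <- column_quality(pair$msa_b); q$column <- pair$col_map_b; q
  } else qual_lookup(quality_b, pair$msa_b, pair$col_map_b)

  ref <- cfg$ref_species %||% pair$shared_species[1]
  ref_positions <- function(x, ref) {
    if (!ref %in% x$species) return(rep(NA_integer_, ncol(x$seq)))
    row <- x$seq[ref, ]
    pos <- cumsum(row != "-")
    pos[row == "-"] <- NA_integer_
    pos
  }
  rp_a <- ref_positions(pair$msa_a, ref); rr_a <- pair$msa_a$seq[ref, ]
  rp_b <- ref_positions(pair$msa_b, ref); rr_b <- pair$msa_b$seq[ref, ]

  hits <- empty_hits
  if (nrow(cand)) {
    support <- numeric(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      ca <- pa$usable[cand[k, 1]]; cb <- pb$usable[cand[k, 2]]
      support[k] <- bootstrap_support(
        pa$Z[, ca], pb$Z[, cb], nd$threshold, reps = cfg$bootstrap_reps,
        seed = derive_seed(cfg$seed, pair$pair_id, stream, "boot",
                           pair$col_map_a[ca], pair$col_map_b[cb]))
    }
    keep <- support >= cfg$bootstrap_threshold
    if (any(keep)) {
      ca <- pa$usable[cand[keep, 1]]; cb <- pb$usable[cand[keep, 2]]
      rho_k <- rho[cand[keep, , drop = FALSE]]
      hits <- data.frame(
        pair_id = pair$pair_id,
        site_a = pair$col_map_a[ca], ref_pos_a = rp_a[ca],
        residue_a = unname(rr_a[ca]),
        site_b = pair$col_map_b[cb], ref_pos_b = rp_b[cb],
        residue_b = unname(rr_b[cb]),
        rho = rho_k,
        support = support[keep],
        p = pvalue(rho_k, nd$null, cfg$tail),
        gap_frac_a = qa$gap_fraction[match(pair$col_map_a[ca], qa$column)],
        gap_frac_b = qb$gap_fraction[match(pair$col_map_b[cb], qb$column)],
        good_a = qa$good[match(pair$col_map_a[ca], qa$column)],
        good_b = qb$good[match(pair$col_map_b[cb], qb$column)],
        stringsAsFactors = FALSE)
      hits <- hits[order(hits$site_a, hits$site_b), , drop = FALSE]
      rownames(hits) <- NULL
    }
  }
  log$n_hits <- nrow(hits)
  out <- list(hits = hits, log = log)
  if (keep_matrices) {
    out$rho <- rho; out$null <- nd$null
    out$usable_a <- pa$usable; out$usable_b <- pb$usable
    out$site_map_a <- pair$col_map_a[pa$usable]
    out$site_map_b <- pair$col_map_b[pb$usable]
  }
  structure(out, class = "coev_scan")
}

#' @export
print.coev_scan <- function(x, ...) {
  l <- x$log
  cat(sprintf("<coev_scan> %s [%s]: %d x %d usable columns, %d hits%s\n",
              l$pair_id, l$stream, l$n_usable_a, l$n_usable_b, l$n_hits,
              if (l$aborted) paste0(" (aborted: ", l$reason, ")") else ""))
  invisible(x)
}

#' Bidirectional scan of a protein pair
#'
#' Runs the scan twice with independent Monte-Carlo streams (`"fwd"`, then
#' with the A/B roles swapped, `"rev"`); the second run is skipped when the
#' first yields no hits. The final hits are the exact intersection on
#' original column coordinates, reporting both runs' correlations and
#' supports and the maximum of the two p-values.
#'
#' @inheritParams scan_pair
#' @return List of class `coev_biscan`: `hits` (data.frame with
#'   `rho_fwd`, `rho_rev`, `support_fwd`, `support_rev`, `p`, quality
#'   columns), `log_fwd`, `log_rev` (`NULL` when skipped).
#' @export
bidirectional_scan <- function(pair, cfg = engine_config(),
                               quality_a = NULL, quality_b = NULL) {
  fwd <- scan_pair(pair, cfg, stream = "fwd",
                   quality_a = quality_a, quality_b = quality_b)
  empty <- data.frame(
    pair_id = character(), site_a = integer(), ref_pos_a = integer(),
    residue_a = character(), site_b = integer(), ref_pos_b = integer(),
    residue_b = character(), rho_fwd = numeric(), rho_rev = numeric(),
    support_fwd = numeric(), support_rev = numeric(), p = numeric(),
    gap_frac_a = numeric(), gap_frac_b = numeric(),
    good_a = logical(), good_b = logical(), stringsAsFactors = FALSE)
  if (nrow(fwd$hits) == 0L) {
    return(structure(list(hits = empty, log_fwd = fwd$log, log_rev = NULL),
                     class = "coev_biscan"))
  }
  swapped <- pair
  swapped$msa_a <- pair$msa_b; swapped$msa_b <- pair$msa_a
  swapped$col_map_a <- pair$col_map_b; swapped$col_map_b <- pair$col_map_a
  swapped$tree_a <- pair$tree_b; swapped$tree_b <- pair$tree_a
  rev <- scan_pair(swapped, cfg, stream = "rev",
                   quality_a = quality_b, quality_b = quality_a)
  rh <- rev$hits
  # map rev hits back: rev site_a is protein B's column
  key_fwd <- paste(fwd$hits$site_a, fwd$hits$site_b)
  key_rev <- paste(rh$site_b, rh$site_a)
  common <- intersect(key_fwd, key_rev)
  f <- fwd$hits[match(common, key_fwd), , drop = FALSE]
  r <- rh[match(common, key_rev), , drop = FALSE]
  hits <- if (nrow(f)) data.frame(
    pair_id = f$pair_id, site_a = f$site_a, ref_pos_a = f$ref_pos_a,
    residue_a = f$residue_a, site_b = f$site_b, ref_pos_b = f$ref_pos_b,
    residue_b = f$residue_b,
    rho_fwd = f$rho, rho_rev = r$rho,
    support_fwd = f$support, support_rev = r$support,
    p = pmax(f$p, r$p),
    gap_frac_a = f$gap_frac_a, gap_frac_b = f$gap_frac_b,
    good_a = f$good_a, good_b = f$good_b, stringsAsFactors = FALSE)
  else empty
  hits <- hits[order(hits$site_a, hits$site_b), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits, log_fwd = fwd$log, log_rev = rev$log),
            class = "coev_biscan")
}

#' @export
print.coev_biscan <- function(x, ...) {
  cat(sprintf("<coev_biscan> %s: %d bidirectional hits%s\n",
              x$log_fwd$pair_id, nrow(x$hits),
              if (is.null(x$log_rev)) " (reverse run skipped)" else ""))
  invisible(x)
}
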