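# Post-processing: pooled FDR correction, the per-pair chi-squared
# enrichment test, the printed-threshold result filters, and the two result
# tables plus Cytoscape-ready network export.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone in p, each adjusted value at least its
#' p and at most 1.
#'
#' @param pvalues Numeric vector with all values in `(0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop_coev("coev_domain", "p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Assemble the two result tables from per-pair scans
#'
#' The residue table pools every bidirectional hit; the pair table has one
#' row per scanned protein pair (including zero-hit and aborted pairs) with
#' hit and comparison counts. Hit q-values are Benjamini-Hochberg adjusted
#' across the pooled residue table by default (`fdr_scope = "pooled"`), or
#' within each protein pair (`"per_pair"`).
#'
#' @param scans List of `coev_biscan` results.
#' @param fdr_scope `"pooled"` (default) or `"per_pair"`.
#' @return Object of class `coev_results`: list with `residue_table` and
#'   `pair_table`.
#' @export
collect_results <- function(scans, fdr_scope = c("pooled", "per_pair")) {
  fdr_scope <- match.arg(fdr_scope)
  hits <- do.call(rbind, c(lapply(scans, `[[`, "hits"), make.row.names = FALSE))
  logs <- lapply(scans, `[[`, "log_fwd")
  pair_table <- data.frame(
    pair_id = vapply(logs, `[[`, "", "pair_id"),
    n_hits = vapply(scans, function(s) nrow(s$hits), 0L),
    n_comparisons = vapply(logs, `[[`, 0L, "n_comparisons"),
    aborted = vapply(logs, `[[`, FALSE, "aborted"),
    chi2 = NA_real_, chi2_p = NA_real_, min_q = NA_real_,
    stringsAsFactors = FALSE)
  pair_table <- pair_table[order(pair_table$pair_id), , drop = FALSE]
  rownames(pair_table) <- NULL
  if (nrow(hits)) {
    hits$q <- if (fdr_scope == "pooled") bh_fdr(hits$p) else
      stats::ave(hits$p, hits$pair_id, FUN = bh_fdr)
    hits <- hits[order(hits$pair_id, hits$site_a, hits$site_b), , drop = FALSE]
    rownames(hits) <- NULL
    minq <- tapply(hits$q, hits$pair_id, min)
    pair_table$min_q <- as.numeric(minq[pair_table$pair_id])
  } else {
    hits$q <- numeric(0)
  }
  structure(list(residue_table = hits, pair_table = pair_table),
            class = "coev_results")
}

#' @export
print.coev_results <- function(x, ...) {
  cat(sprintf("<coev_results> %d hits across %d protein pairs (%d with >= 1 hit)\n",
              nrow(x$residue_table), nrow(x$pair_table),
              sum(x$pair_table$n_hits > 0)))
  invisible(x)
}

#' Per-pair chi-squared enrichment test
#'
#' Tests each protein pair's hit count against the pooled hit rate:
#' `p_hat = sum(n_hits) / sum(n_comparisons)`, `E = n_comparisons * p_hat`,
#' `chi2 = (n_hits - E)^2 / E` (0 when E = 0), upper tail of the
#' chi-squared distribution with 1 degree of freedom.
#'
#' @param results A `coev_results` (needs >= 2 pairs with comparisons).
#' @return The `coev_results` with `chi2` and `chi2_p` filled in the pair
#'   table.
#' @export
chisq_pairs <- function(results) {
  pt <- results$pair_table
  if (sum(pt$n_comparisons > 0) < 2L)
    stop_coev("coev_shape", "need >= 2 pairs with comparisons")
  tot_hits <- sum(pt$n_hits)
  if (tot_hits == 0L) {
    warning("no hits in any pair; chi2 = 0, chi2_p = 1 throughout")
    pt$chi2 <- 0; pt$chi2_p <- 1
  } else {
    p_hat <- tot_hits / sum(pt$n_comparisons)
    E <- pt$n_comparisons * p_hat
    pt$chi2 <- ifelse(E > 0, (pt$n_hits - E)^2 / E, 0)
    pt$chi2_p <- stats::pchisq(pt$chi2, df = 1, lower.tail = FALSE)
  }
  results$pair_table <- pt
  results
}

#' Filter the residue table by the printed thresholds
#'
#' Residue rows are kept iff `p < p_max`, both good-block flags are true
#' (when `require_good`), and both gap fractions are below `gap_max`
#' (strict inequalities). The pair table's hit counts and minimum q are
#' recomputed from the surviving rows (comparison counts are kept).
#'
#' @param results A `coev_results`.
#' @param p_max Maximum p-value (default 0.005).
#' @param require_good Require both columns in good blocks (default TRUE).
#' @param gap_max Maximum column gap fraction (default 0.20).
#' @return Filtered `coev_results`.
#' @export
filter_results <- function(results, p_max = 0.005, require_good = TRUE,
                           gap_max = 0.20) {
  rt <- results$residue_table
  if (nrow(rt)) {
    keep <- rt$p < p_max & rt$gap_frac_a < gap_max & rt$gap_frac_b < gap_max
    if (require_good) keep <- keep & rt$good_a & rt$good_b
    rt <- rt[keep, , drop = FALSE]
    rownames(rt) <- NULL
  }
  pt <- results$pair_table
  counts <- table(factor(rt$pair_id, levels = pt$pair_id))
  pt$n_hits <- as.integer(counts)
  pt$min_q <- NA_real_
  if (nrow(rt)) {
    minq <- tapply(rt$q, rt$pair_id, min)
    pt$min_q <- as.numeric(minq[pt$pair_id])
  }
  structure(list(residue_table = rt, pair_table = pt), class = "coev_results")
}

#' Write the residue and pair tables as TSV
#'
#' @param results A `coev_results`.
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_result_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rp <- file.path(dir, "residue_table.tsv")
  pp <- file.path(dir, "pair_table.tsv")
  utils::write.table(format_table(results$residue_table), rp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(format_table(results$pair_table), pp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(rp, pp))
}

# stable numeric formatting so re-exports are byte-identical
format_table <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.10g", df[[nm]])
  }
  df
}

#' Export node and edge tables for network visualization
#'
#' Edge table: one row per protein pair with at least one (surviving) hit;
#' node table: one row per protein with its degree and summed hit count.
#' Row order is sorted, so re-export is byte-identical.
#'
#' @param results A `coev_results` (chi-squared columns filled or `NA`).
#' @param out_dir Output directory.
#' @return Paths of `edges.tsv` and `nodes.tsv`, invisibly.
#' @export
export_network <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pt <- results$pair_table[results$pair_table$n_hits >= 1L, , drop = FALSE]
  rt <- results$residue_table
  split_id <- strsplit(pt$pair_id, "__", fixed = TRUE)
  edges <- data.frame(
    source = vapply(split_id, `[`, "", 1),
    target = vapply(split_id, `[`, "", 2),
    n_hits = pt$n_hits,
    min_p = vapply(pt$pair_id, function(id) {
      v <- rt$p[rt$pair_id == id]; if (length(v)) min(v) else NA_real_
    }, 0),
    min_q = pt$min_q, chi2 = pt$chi2, chi2_p = pt$chi2_p,
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  proteins <- sort(unique(c(edges$source, edges$target)))
  nodes <- data.frame(
    protein = proteins,
    degree = vapply(proteins, function(p)
      sum(edges$source == p | edges$target == p), 0L),
    total_hits = vapply(proteins, function(p)
      sum(edges$n_hits[edges$source == p | edges$target == p]), 0L),
    stringsAsFactors = FALSE)
  ep <- file.path(out_dir, "edges.tsv")
  np <- file.path(out_dir, "nodes.tsv")
  utils::write.table(format_table(edges), ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(format_table(nodes), np, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ep, np))
}
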