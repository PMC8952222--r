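# Alignment column quality: per-column gap fraction, conservation class,
# and a block-based good/poor label in the spirit of conserved-block
# selection tools. Only the per-column label is consumed downstream, so the
# block logic is reduced to three rules (see good_blocks).

#' Per-column gap fraction and conservation class
#'
#' A column is `highly_conserved` when its most frequent residue occurs in
#' more than 85% of rows, `conserved` when it occurs in more than
#' `floor(n/2)` rows, and `nonconserved` otherwise. Columns with gap
#' fraction above one half are forced to `nonconserved` regardless of their
#' residues (the "allowed gaps: half" rule).
#'
#' @param x A `coev_msa`.
#' @return Data.frame with one row per column: `column` (1-based),
#'   `gap_fraction`, `class` (character), `good` (logical, `NA` until
#'   [good_blocks()] is applied).
#' @export
column_stats <- function(x) {
  stopifnot(inherits(x, "coev_msa"))
  n <- nrow(x$seq)
  L <- ncol(x$seq)
  gap_fraction <- numeric(L)
  cls <- character(L)
  half <- n %/% 2
  for (j in seq_len(L)) {
    col <- x$seq[, j]
    gaps <- sum(col == "-")
    gap_fraction[j] <- gaps / n
    res <- col[col != "-"]
    top <- if (length(res)) max(tabulate(factor(res, levels = c(AA20, "X")))) else 0L
    cls[j] <- if (gap_fraction[j] > 0.5) "nonconserved"
      else if (top > 0.85 * n) "highly_conserved"
      else if (top > half) "conserved"
      else "nonconserved"
  }
  data.frame(column = seq_len(L), gap_fraction = gap_fraction,
             class = cls, good = NA, stringsAsFactors = FALSE)
}

#' Mark columns belonging to good alignment blocks
#'
#' A good block is a maximal run of columns that (i) contains no stretch of
#' more than `max_nonconserved_stretch` contiguous nonconserved columns,
#' (ii) is trimmed at both ends to start and end on a conserved-or-better
#' column, and (iii) has length at least `min_block` after trimming.
#'
#' @param cq Output of [column_stats()].
#' @param min_block Minimum block length (default 10).
#' @param max_nonconserved_stretch Longest tolerated run of nonconserved
#'   columns inside a block (default 8).
#' @return `cq` with the `good` column filled (logical).
#' @export
good_blocks <- function(cq, min_block = 10, max_nonconserved_stretch = 8) {
  L <- nrow(cq)
  noncons <- cq$class == "nonconserved"
  good <- rep(FALSE, L)
  # breaker stretches: runs of > max_nonconserved_stretch nonconserved columns
  r <- rle(noncons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  breaker <- rep(FALSE, L)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] > max_nonconserved_stretch)
      breaker[starts[k]:ends[k]] <- TRUE
  }
  # segments between breakers
  seg <- rle(breaker)
  seg_ends <- cumsum(seg$lengths)
  seg_starts <- seg_ends - seg$lengths + 1L
  for (k in seq_along(seg$lengths)) {
    if (seg$values[k]) next
    a <- seg_starts[k]; b <- seg_ends[k]
    idx <- a:b
    keep <- idx[!noncons[idx]]
    if (!length(keep)) next
    a2 <- min(keep); b2 <- max(keep)
    if (b2 - a2 + 1L >= min_block) good[a2:b2] <- TRUE
  }
  cq$good <- good
  cq
}

#' Column quality for one protein alignment
#'
#' Convenience wrapper: [column_stats()] followed by [good_blocks()].
#'
#' @inheritParams column_stats
#' @inheritParams good_blocks
#' @return Data.frame as in [good_blocks()].
#' @export
column_quality <- function(x, min_block = 10, max_nonconserved_stretch = 8) {
  good_blocks(column_stats(x), min_block, max_nonconserved_stretch)
}

write_quality_tsv <- function(cq, path) {
  out <- data.frame(column_1based = cq$column,
                    gap_fraction = cq$gap_fraction,
                    class = cq$class,
                    good = as.integer(cq$good))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
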