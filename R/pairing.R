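# Protein pair enumeration and per-pair input preparation: shared-species
# trimming, all-gap column removal with an index map back to original
# coordinates, tree pruning, and the minimum-shared-species threshold.

#' Enumerate all unique unordered protein pairs
#'
#' @param proteins Character vector of unique protein ids (>= 2).
#' @return Data.frame with columns `a`, `b` (lexicographically `a < b`) and
#'   `pair_id` (`"a__b"`), sorted by `pair_id`; independent of input order.
#' @export
enumerate_pairs <- function(proteins) {
  if (anyDuplicated(proteins))
    stop_coev("coev_duplicate_label", "duplicate protein ids")
  if (length(proteins) < 2L)
    stop_coev("coev_shape", "need at least 2 proteins")
  p <- sort(proteins)
  cmb <- utils::combn(p, 2)
  out <- data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  out$pair_id <- paste(out$a, out$b, sep = "__")
  out[order(out$pair_id), , drop = FALSE]
}

# Remove all-gap columns, returning the msa and the 1-based original-column
# index map of retained columns.
drop_allgap_columns <- function(x) {
  allgap <- colSums(x$seq != "-") == 0L
  keep <- which(!allgap)
  x$seq <- x$seq[, keep, drop = FALSE]
  list(msa = x, col_map = keep)
}

#' Build the trimmed input for one protein pair
#'
#' Both alignments are restricted to the species found in both (rows sorted
#' by species label so pair indexing is identical between the two), columns
#' that become all-gap are removed (recorded in a strictly increasing index
#' map to original 1-based columns), and trees, when given, are pruned to
#' the shared species. Pairs sharing fewer than `min_shared` species are
#' rejected (a value, not an error).
#'
#' @param msa_a,msa_b `coev_msa` objects for the two proteins.
#' @param tree_a,tree_b Optional `ape::phylo` trees covering the species.
#' @param min_shared Minimum number of shared species (default 20).
#' @return An object of class `coev_pair_input` (fields `pair_id`, `msa_a`,
#'   `msa_b`, `col_map_a`, `col_map_b`, `tree_a`, `tree_b`,
#'   `shared_species`), or of class `coev_pair_rejection` with a `reason`.
#' @export
build_pair_input <- function(msa_a, msa_b, tree_a = NULL, tree_b = NULL,
                             min_shared = 20) {
  stopifnot(inherits(msa_a, "coev_msa"), inherits(msa_b, "coev_msa"))
  if (msa_a$protein_id > msa_b$protein_id) {
    tmp <- msa_a; msa_a <- msa_b; msa_b <- tmp
    tmp <- tree_a; tree_a <- tree_b; tree_b <- tmp
  }
  pair_id <- paste(msa_a$protein_id, msa_b$protein_id, sep = "__")
  shared <- sort(intersect(msa_a$species, msa_b$species))
  if (length(shared) < min_shared) {
    return(structure(list(pair_id = pair_id, n_shared = length(shared),
                          reason = sprintf("shared<%d", min_shared)),
                     class = "coev_pair_rejection"))
  }
  a <- drop_allgap_columns(msa_subset(msa_a, shared))
  b <- drop_allgap_columns(msa_subset(msa_b, shared))
  if (!is.null(tree_a)) tree_a <- prune_tree(tree_a, shared)
  if (!is.null(tree_b)) tree_b <- prune_tree(tree_b, shared)
  structure(list(pair_id = pair_id,
                 msa_a = a$msa, msa_b = b$msa,
                 col_map_a = a$col_map, col_map_b = b$col_map,
                 tree_a = tree_a, tree_b = tree_b,
                 shared_species = shared),
            class = "coev_pair_input")
}

#' @export
print.coev_pair_input <- function(x, ...) {
  cat(sprintf("<coev_pair_input> %s: %d shared species, %d x %d columns\n",
              x$pair_id, length(x$shared_species),
              ncol(x$msa_a$seq), ncol(x$msa_b$seq)))
  invisible(x)
}

#' @export
print.coev_pair_rejection <- function(x, ...) {
  cat(sprintf("<coev_pair_rejection> %s: %s (n_shared = %d)\n",
              x$pair_id, x$reason, x$n_shared))
  invisible(x)
}
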