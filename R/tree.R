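# Phylogenetic trees (ape::phylo) and distance matrices.
#
# Trees are plain ape "phylo" objects so that the whole ape toolbox applies;
# this file adds the operations the screen needs: Poisson-corrected protein
# distances, neighbour-joining with a negative-branch convention,
# minimum-height rooting, patristic distances and metric-preserving pruning.

#' Parse a Newick tree
#'
#' @param path Path to a single-tree Newick file.
#' @param text Newick string (alternative to `path`).
#' @return An `ape::phylo` tree; missing branch lengths default to 0.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop_coev("coev_parse", "Newick parse error: %s",
                                  conditionMessage(e)))
  if (is.null(tr))
    stop_coev("coev_parse", "Newick parse error: no tree found")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop_coev("coev_parse", "expected a single tree, found %d", length(tr))
    tr <- tr[[1]]
  }
  if (anyDuplicated(tr$tip.label))
    stop_coev("coev_duplicate_label", "duplicate leaf labels: %s",
              paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0))
    stop_coev("coev_parse", "negative branch length in input tree")
  tr
}

#' Serialize a tree as Newick
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths (default 10).
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Poisson-corrected protein distance matrix
#'
#' Pairwise p-distances over columns where neither sequence has a gap or
#' 'X', corrected as d = -ln(1 - p). Proportions at or above `p_cap` are
#' capped (with a warning) to keep the correction finite.
#'
#' @param x A `coev_msa` with at least 2 rows.
#' @param p_cap Cap applied to the mismatch proportion before correction.
#' @return A symmetric numeric matrix with species dimnames, zero diagonal.
#' @export
protein_distance_matrix <- function(x, p_cap = 0.95) {
  stopifnot(inherits(x, "coev_msa"))
  n <- nrow(x$seq)
  if (n < 2L) stop_coev("coev_shape", "need at least 2 sequences")
  ok <- x$seq != "-" & x$seq != "X"
  d <- matrix(0, n, n, dimnames = list(x$species, x$species))
  capped <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop_coev("coev_incomparable_pair",
                  "no comparable columns between '%s' and '%s'",
                  x$species[i], x$species[j])
      p <- sum(x$seq[i, comp] != x$seq[j, comp]) / nc
      if (p >= p_cap) { p <- p_cap; capped <- TRUE }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  if (capped)
    warning("mismatch proportion capped at ", p_cap, " for at least one pair")
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]). Negative branch-length
#' estimates are clamped to zero with the deficit transferred to the longest
#' sibling branch, so path lengths through the parent are preserved where
#' possible.
#'
#' @param dist Symmetric distance matrix with labels (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) stop_coev("coev_too_few_taxa", "neighbour joining needs >= 3 taxa")
  if (is.null(rownames(dist))) stop_coev("coev_shape", "distance matrix must be labelled")
  tr <- ape::nj(stats::as.dist(dist))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sibs <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
    if (length(sibs)) {
      s <- sibs[which.max(tr$edge.length[sibs])]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + deficit)
    }
  }
  tr
}

# For each edge (u = edge[i,1], v = edge[i,2]) of an unrooted tree, the leaves
# on the v side, as a logical matrix [edges x tips].
edge_tip_sides <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- matrix(FALSE, nt + tree$Nnode, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    u <- po$edge[k, 1]; v <- po$edge[k, 2]
    below[u, ] <- below[u, ] | below[v, ]
  }
  below[tree$edge[, 2], , drop = FALSE]
}

#' Root a tree at the point of minimum height
#'
#' Places the root at the point (on an edge) minimizing the maximum
#' root-to-leaf path length. For each edge the optimum is solved in closed
#' form; ties between edges are broken by the smallest edge index in ape's
#' edge ordering.
#'
#' @param tree An `ape::phylo` tree with >= 2 leaves (a rooted input is
#'   unrooted first when it has more than 2 leaves).
#' @return A rooted `ape::phylo` tree of the same leaf set.
#' @export
root_min_height <- function(tree) {
  nt <- length(tree$tip.label)
  if (nt < 2L) stop_coev("coev_too_few_taxa", "need >= 2 leaves to root")
  if (nt == 2L) {
    tot <- sum(tree$edge.length)
    txt <- sprintf("(%s:%.12g,%s:%.12g);", tree$tip.label[1], tot / 2,
                   tree$tip.label[2], tot / 2)
    return(ape::read.tree(text = txt))
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  D <- ape::dist.nodes(tree)
  sides <- edge_tip_sides(tree)
  best <- NULL
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]; len <- tree$edge.length[k]
    tips_v <- which(sides[k, ])
    tips_u <- which(!sides[k, ])
    h_down <- max(D[v, tips_v])
    h_up <- max(D[u, tips_u])
    # root at distance x from u on this edge
    x <- min(max((h_down + len - h_up) / 2, 0), len)
    h <- max(h_up + x, h_down + len - x)
    if (is.null(best) || h < best$h - 1e-12) {
      best <- list(h = h, edge = k, v = v, x = x, len = len)
    }
  }
  if (best$x <= 1e-12) best$x <- min(1e-12, best$len)  # avoid degenerate split at u
  rooted <- phytools::reroot(tree, best$v, position = best$x)
  rooted
}

#' Prune a tree to a subset of leaves
#'
#' Unary nodes created by pruning are contracted with branch lengths summed,
#' so patristic distances among kept leaves are unchanged.
#'
#' @param tree An `ape::phylo` tree.
#' @param keep Character vector of leaf labels to keep (>= 2, all present).
#' @return The pruned tree.
#' @export
prune_tree <- function(tree, keep) {
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop_coev("coev_unknown_label", "labels not in tree: %s",
              paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop_coev("coev_too_few_taxa", "keep at least 2 leaves")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of leaves.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Symmetric numeric matrix ordered by `tree$tip.label`.
#' @export
patristic_distances <- function(tree) {
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}
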