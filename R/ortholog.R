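# Orthologue curation: pick one sequence per species by global-alignment
# similarity to the reference, then screen out overly divergent sequences.

#' Global pairwise alignment statistics
#'
#' Needleman-Wunsch global alignment with affine gap costs (a gap of length
#' k costs `gap_open + k * gap_extend`), computed with
#' [Biostrings::pairwiseAlignment()]. Identity is counted over aligned
#' (both-residue) positions; the gap percentage over the full alignment
#' length. The denominator for identity can be switched to the alignment
#' length.
#'
#' @param query,reference Ungapped amino-acid strings.
#' @param matrix Scoring matrix name (see [substitution_matrix()]).
#' @param gap_open,gap_extend Gap opening / extension costs (positive).
#' @param identity_denom `"aligned"` (default) or `"alignment_length"`.
#' @return List with `score`, `identity_pct`, `gap_pct`, `alignment_length`,
#'   and the two aligned strings `query_aln`, `reference_aln`.
#' @export
global_align <- function(query, reference, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 1,
                         identity_denom = c("aligned", "alignment_length")) {
  identity_denom <- match.arg(identity_denom)
  for (s in c(query, reference)) {
    if (nchar(s) == 0L) stop_coev("coev_empty_input", "empty sequence")
    if (grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), toupper(s)))
      stop_coev("coev_alphabet", "illegal character in sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    toupper(query), toupper(reference), type = "global",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  qa <- as.character(Biostrings::alignedPattern(aln))
  ra <- as.character(Biostrings::alignedSubject(aln))
  qv <- strsplit(qa, "")[[1]]
  rv <- strsplit(ra, "")[[1]]
  len <- length(qv)
  both <- qv != "-" & rv != "-"
  n_aligned <- sum(both)
  n_ident <- sum(qv[both] == rv[both])
  denom <- if (identity_denom == "aligned") n_aligned else len
  list(score = Biostrings::score(aln),
       identity_pct = 100 * n_ident / denom,
       gap_pct = 100 * sum(!both) / len,
       alignment_length = len,
       query_aln = qa, reference_aln = ra)
}

#' Select the best orthologue candidate per species
#'
#' Every candidate is globally aligned to the reference sequence; per
#' species the highest-scoring candidate is chosen (score ties broken by
#' lexicographically smallest candidate id). Chosen candidates failing the
#' identity or gap filter are dropped and logged; species left without a
#' surviving candidate are reported as missing.
#'
#' @param hs Homolog set: a list with `protein_id`, `reference` (ungapped
#'   string) and `candidates`, a data.frame with columns `species`,
#'   `candidate_id`, `sequence`.
#' @param min_identity Minimum alignment identity percentage (default 35).
#' @param max_gaps Maximum gap percentage (default 25).
#' @param ... Passed to [global_align()].
#' @return List with data.frames `selected` (species, candidate_id,
#'   sequence, score, identity_pct, gap_pct), `rejected` (protein, species,
#'   candidate, reason, identity, gaps) and character vector `missing`.
#' @export
select_best_hit <- function(hs, min_identity = 35, max_gaps = 25, ...) {
  stopifnot(is.character(hs$reference), nrow(hs$candidates) >= 0)
  cand <- hs$candidates
  sel <- list(); rej <- list()
  for (sp in unique(cand$species)) {
    rows <- cand[cand$species == sp, , drop = FALSE]
    stats <- lapply(rows$sequence, global_align, reference = hs$reference, ...)
    score <- vapply(stats, `[[`, 0, "score")
    ord <- order(-score, rows$candidate_id)
    best <- ord[1]
    st <- stats[[best]]
    reason <- NULL
    if (st$identity_pct < min_identity)
      reason <- sprintf("identity<%g", min_identity)
    else if (st$gap_pct > max_gaps)
      reason <- sprintf("gaps>%g", max_gaps)
    if (is.null(reason)) {
      sel[[sp]] <- data.frame(species = sp, candidate_id = rows$candidate_id[best],
                              sequence = rows$sequence[best], score = st$score,
                              identity_pct = st$identity_pct, gap_pct = st$gap_pct,
                              stringsAsFactors = FALSE)
    } else {
      rej[[sp]] <- data.frame(protein = hs$protein_id %||% NA_character_,
                              species = sp, candidate = rows$candidate_id[best],
                              reason = reason, identity = st$identity_pct,
                              gaps = st$gap_pct, stringsAsFactors = FALSE)
    }
  }
  selected <- if (length(sel)) do.call(rbind, unname(sel)) else
    data.frame(species = character(), candidate_id = character(),
               sequence = character(), score = numeric(),
               identity_pct = numeric(), gap_pct = numeric())
  rejected <- if (length(rej)) do.call(rbind, unname(rej)) else
    data.frame(protein = character(), species = character(),
               candidate = character(), reason = character(),
               identity = numeric(), gaps = numeric())
  missing <- setdiff(unique(cand$species),
                     c(selected$species, rejected$species))
  list(selected = selected[order(selected$species), , drop = FALSE],
       rejected = rejected, missing = missing)
}

#' Screen out overly divergent sequences
#'
#' Each sequence is scored by its mean pairwise identity to all other
#' sequences, rescaled to `[0, 1]` by the per-set maximum; sequences whose
#' rescaled score falls below `cutoff * median(rescaled scores)` are
#' removed. This is a deliberately simple divergence screen (it is not an
#' alignment-confidence score); the default cutoff of 0.95 matches the
#' screening stringency used for orthologue sets in this pipeline.
#'
#' @param sequences Named character vector (species -> ungapped or aligned
#'   sequence). With fewer than 4 sequences the screen is skipped with a
#'   warning.
#' @param cutoff Relative cutoff in `[0, 1]` (default 0.95).
#' @param ... Passed to [global_align()] when sequences are unaligned.
#' @return List with `retained` (named character vector), `removed`
#'   (data.frame species, score) and `scores` (rescaled scores).
#' @export
divergence_screen <- function(sequences, cutoff = 0.95, ...) {
  n <- length(sequences)
  if (n < 4L) {
    warning("fewer than 4 sequences; divergence screen skipped")
    return(list(retained = sequences,
                removed = data.frame(species = character(), score = numeric()),
                scores = stats::setNames(rep(NA_real_, n), names(sequences))))
  }
  aligned <- length(unique(nchar(sequences))) == 1L
  idmat <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (aligned) {
      a <- strsplit(sequences[[i]], "")[[1]]
      b <- strsplit(sequences[[j]], "")[[1]]
      keep <- !(a == "-" & b == "-")
      idmat[i, j] <- idmat[j, i] <- 100 * sum(a[keep] == b[keep]) / sum(keep)
    } else {
      idmat[i, j] <- idmat[j, i] <-
        global_align(sequences[[i]], sequences[[j]], ...)$identity_pct
    }
  }
  raw <- rowMeans(idmat, na.rm = TRUE)
  scores <- raw / max(raw)
  names(scores) <- names(sequences)
  thr <- cutoff * stats::median(scores)
  drop <- scores < thr
  list(retained = sequences[!drop],
       removed = data.frame(species = names(sequences)[drop],
                            score = unname(scores[drop])),
       scores = scores)
}
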