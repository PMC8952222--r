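# Multiple sequence alignments keyed by species.
#
# An alignment is stored as a character matrix (rows = species, columns =
# alignment positions, single upper-case characters). Only the 20 amino
# acids, 'X' and '-' are allowed; '.' and '*' on input are folded to '-',
# other ambiguity codes to 'X'.

#' Construct a species-keyed multiple sequence alignment
#'
#' @param protein_id Identifier of the protein the alignment belongs to.
#' @param species Character vector of unique species labels.
#' @param sequences Character vector of aligned sequences (equal lengths),
#'   parallel to `species`.
#' @return An object of class `coev_msa`: a list with elements `protein_id`,
#'   `species`, and `seq` (character matrix of single residues with species
#'   rownames).
#' @export
msa <- function(protein_id, species, sequences) {
  if (length(species) == 0L)
    stop_coev("coev_empty_input", "alignment for '%s' has no sequences", protein_id)
  if (length(species) != length(sequences))
    stop_coev("coev_shape", "species and sequences differ in length")
  if (anyDuplicated(species))
    stop_coev("coev_duplicate_label", "duplicate species label in '%s': %s",
              protein_id, paste(unique(species[duplicated(species)]), collapse = ", "))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop_coev("coev_shape",
              "ragged alignment for '%s': sequence lengths %s",
              protein_id, paste(sort(unique(lens)), collapse = ", "))
  if (lens[1] < 1L)
    stop_coev("coev_empty_input", "alignment for '%s' has zero columns", protein_id)
  m <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
              nrow = length(species), byrow = TRUE)
  m[m == "." | m == "*"] <- "-"
  bad <- !(m %in% c(AA20, MSA_EXTRA))
  if (any(bad)) {
    m[bad] <- "X"
  }
  rownames(m) <- species
  structure(list(protein_id = protein_id, species = species, seq = m),
            class = "coev_msa")
}

msa_from_matrix <- function(protein_id, m) {
  msa(protein_id, rownames(m), apply(m, 1, paste, collapse = ""))
}

#' @export
print.coev_msa <- function(x, ...) {
  cat(sprintf("<coev_msa> %s: %d sequences x %d columns\n",
              x$protein_id, nrow(x$seq), ncol(x$seq)))
  invisible(x)
}

#' Number of alignment columns
#' @param x A `coev_msa`.
#' @return Integer column count.
#' @export
msa_length <- function(x) ncol(x$seq)

#' Read an aligned FASTA file
#'
#' The species label is the first whitespace-delimited token of each header
#' (overridable with a regular expression whose first capture group is the
#' label). All sequences must have identical length.
#'
#' @param path FASTA file path.
#' @param protein_id Protein identifier to attach; defaults to the file name
#'   without extension.
#' @param label_regex Optional regex with one capture group applied to the
#'   full header to extract the species label.
#' @return A [msa()] object; row order follows file order.
#' @export
read_msa <- function(path, protein_id = NULL,
                     label_regex = NULL) {
  protein_id <- protein_id %||% sub("\\.[^.]*$", "", basename(path))
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop_coev("coev_parse", "cannot read FASTA '%s': %s",
                                                 path, conditionMessage(e)))
  if (length(recs) == 0L)
    stop_coev("coev_empty_input", "FASTA '%s' contains no records", path)
  headers <- names(recs)
  labels <- if (is.null(label_regex)) {
    sub("\\s.*$", "", headers)
  } else {
    m <- regmatches(headers, regexec(label_regex, headers))
    vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_, "")
  }
  if (anyNA(labels) || any(labels == ""))
    stop_coev("coev_parse", "could not extract species labels from '%s'", path)
  msa(protein_id, labels, as.character(recs))
}

#' Write an alignment as FASTA
#'
#' Standard FASTA with 60-character line wrap, LF endings; byte-deterministic
#' for a given alignment.
#'
#' @param x A `coev_msa`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "coev_msa"))
  seqs <- apply(x$seq, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- x$species
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Restrict an alignment to a species subset (keeping the given order).
msa_subset <- function(x, keep) {
  missing <- setdiff(keep, x$species)
  if (length(missing))
    stop_coev("coev_unknown_label", "species not in alignment '%s': %s",
              x$protein_id, paste(missing, collapse = ", "))
  m <- x$seq[keep, , drop = FALSE]
  structure(list(protein_id = x$protein_id, species = keep, seq = m),
            class = "coev_msa")
}
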