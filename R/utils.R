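# Shared internal helpers: alphabet, scoring matrices, seed derivation.

# The 20 canonical amino acids, in the row order used throughout the package.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Characters tolerated in alignment rows besides the 20 residues.
MSA_EXTRA <- c("X", "-")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Amino-acid substitution scoring matrix
#'
#' Returns one of the BLOSUM log-odds matrices shipped with Biostrings,
#' restricted to the 20 canonical amino acids.
#'
#' @param name Matrix name: `"BLOSUM62"` (default), `"BLOSUM45"` or
#'   `"BLOSUM80"`.
#' @return A symmetric 20 x 20 numeric matrix with amino-acid dimnames.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  name <- match.arg(name, c("BLOSUM62", "BLOSUM45", "BLOSUM80"))
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  storage.mode(m) <- "double"
  m[AA20, AA20]
}

# Expand a scoring matrix so that 'X' and '-' score against everything.
# Used only for theta lookups where such pairs are masked anyway.
expand_matrix <- function(m, fill = 0) {
  labs <- c(rownames(m), MSA_EXTRA)
  out <- matrix(fill, length(labs), length(labs), dimnames = list(labs, labs))
  out[rownames(m), colnames(m)] <- m
  out
}

#' Derive a deterministic RNG seed from a base seed and string labels
#'
#' Protein pairs are scanned independently (possibly in parallel); each pair
#' draws its Monte-Carlo streams from a seed derived from the global seed and
#' the pair identity, so results do not depend on worker count or scheduling.
#'
#' @param seed Integer base seed.
#' @param ... Character or numeric labels mixed into the hash.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), paste, "", collapse = "|"), collapse = "|")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Run fun() with its own RNG stream without disturbing the caller's stream.
with_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

stop_coev <- function(class, msg, ...) {
  stop(structure(class = c(class, "coev_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
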