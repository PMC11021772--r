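#' @keywords internal
"_PACKAGE"

# Canonical amino-acid alphabet used throughout (alphabetical one-letter codes).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PHOSPHO_RESIDUES <- c("S", "T", "Y")

# Fixed compartment vocabulary; order encodes the prioritization used for
# ranking and tie-breaking (plasma membrane first, then cytosol, ER, nucleus).
COMPARTMENTS <- c("plasma membrane", "cytosol", "endoplasmic reticulum",
                  "nucleus", "mitochondrion", "plastid", "extracellular",
                  "other")

#' Split peptide strings into residue character matrices
#'
#' @param x character vector of equal-length peptide strings.
#' @return character matrix, one row per peptide.
#' @keywords internal
peptide_matrix <- function(x) {
  n <- unique(nchar(x))
  if (length(n) != 1L)
    stop("peptides must have equal length, got lengths: ",
         paste(sort(unique(nchar(x))), collapse = ", "))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}

#' Encode peptides as integer indices into the amino-acid alphabet
#'
#' @inheritParams peptide_matrix
#' @return integer matrix (1..20), one row per peptide.
#' @keywords internal
peptide_int_matrix <- function(x) {
  m <- peptide_matrix(x)
  idx <- match(m, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- sort(unique(m[is.na(idx)]))
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  }
  matrix(idx, nrow = nrow(m), ncol = ncol(m))
}

# assert that every string is a valid peptide over the 20-letter alphabet
assert_peptides <- function(x, what = "peptide") {
  if (length(x) == 0L) return(invisible(x))
  if (!is.character(x) || anyNA(x) || any(!nzchar(x)))
    stop(what, " sequences must be non-empty strings")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), x)
  if (any(bad))
    stop(what, " contains non-amino-acid symbols: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  invisible(x)
}

# numerically stable log(sum(exp(...))) for a list of equal-length vectors,
# reduced element-wise; -Inf handled exactly
logsumexp_rows <- function(...) {
  mats <- list(...)
  m <- do.call(pmax, mats)
  out <- m
  fin <- is.finite(m)
  if (any(fin)) {
    acc <- 0
    for (a in mats) acc <- acc + ifelse(fin, exp(a - ifelse(fin, m, 0)), 0)
    out[fin] <- m[fin] + log(acc[fin])
  }
  out
}

#' Residue background frequencies of a sequence set
#'
#' Tallies residue usage over a character vector of sequences and returns a
#' named frequency vector over the 20-letter alphabet. Used as the default
#' null model for profile-HMM scoring and motif enrichment.
#'
#' @param sequences character vector of amino-acid strings.
#' @param pseudocount added to every residue count before normalizing
#'   (default 1; keeps all frequencies strictly positive).
#' @return named numeric vector of length 20 summing to 1.
#' @export
residue_frequencies <- function(sequences, pseudocount = 1) {
  assert_peptides(sequences, "sequence")
  counts <- stats::setNames(rep(pseudocount, 20L), AA_ALPHABET)
  if (length(sequences)) {
    tab <- table(factor(unlist(strsplit(sequences, "", fixed = TRUE),
                               use.names = FALSE), levels = AA_ALPHABET))
    counts <- counts + as.numeric(tab)
  }
  counts / sum(counts)
}
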