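# Library design: centered 20-mer windows, flank filtering, similarity
# deduplication, control sampling and pooling arithmetic.

# Window geometry: 20 residues with the phosphosite at position 10 (1-based),
# i.e. 9 upstream and 10 downstream flanking residues.
WINDOW_LENGTH <- 20L
DEFAULT_SITE_OFFSET <- 10L

#' Extract a centered phosphosite window from a protein sequence
#'
#' Cuts a fixed-length amino-acid window around a phosphorylatable residue so
#' that the site sits at a fixed offset (by default position 10 of 20, giving
#' 9 upstream and 10 downstream residues). Sites too close to either protein
#' terminus are rejected rather than padded: padding characters would corrupt
#' downstream model training.
#'
#' @param protein_sequence amino-acid string.
#' @param site_position 1-based position of the phosphosite in the protein;
#'   the residue there must be S, T or Y.
#' @param window_length window size (default 20).
#' @param site_offset 1-based position of the site within the window
#'   (default 10).
#' @return list with `window` (string), `site_offset`, `start` and `end`
#'   (1-based coordinates of the window in the protein), or an error.
#' @export
extract_window <- function(protein_sequence, site_position,
                           window_length = WINDOW_LENGTH,
                           site_offset = DEFAULT_SITE_OFFSET) {
  assert_peptides(protein_sequence, "protein")
  stopifnot(length(protein_sequence) == 1L, length(site_position) == 1L)
  len <- nchar(protein_sequence)
  if (site_position < 1L || site_position > len)
    stop("site_position ", site_position, " out of bounds for protein of length ", len)
  res <- substr(protein_sequence, site_position, site_position)
  if (!res %in% PHOSPHO_RESIDUES)
    stop("residue at site_position is '", res, "', not a phosphorylatable S/T/Y")
  upstream <- site_offset - 1L
  downstream <- window_length - site_offset
  if (site_position - 1L < upstream)
    stop("rejected: only ", site_position - 1L, " upstream residues, need ", upstream)
  if (len - site_position < downstream)
    stop("rejected: only ", len - site_position, " downstream residues, need ", downstream)
  start <- site_position - upstream
  end <- site_position + downstream
  list(window = substr(protein_sequence, start, end),
       site_offset = as.integer(site_offset),
       start = as.integer(start), end = as.integer(end))
}

#' Keep peptides whose phosphosite has enough flanking residues
#'
#' A seed phosphopeptide is retained only when its phosphosite is at least
#' `min_flank` residues away from either peptide end.
#'
#' @param peptide_sequence peptide string(s).
#' @param site_index 1-based phosphosite position(s) within the peptide.
#' @param min_flank minimum number of residues on each side (default 5).
#' @return logical vector.
#' @export
filter_site_distance <- function(peptide_sequence, site_index, min_flank = 5L) {
  assert_peptides(peptide_sequence, "peptide")
  len <- nchar(peptide_sequence)
  stopifnot(all(site_index >= 1L), all(site_index <= len))
  (site_index >= min_flank + 1L) & (len - site_index >= min_flank)
}

# identity substitution matrix over the Biostrings alignment alphabet
identity_submat <- function() {
  letters <- rownames(blosum62_matrix())
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Pairwise sequence similarity as identity fraction of a global alignment
#'
#' Similarity is the number of identical aligned positions in an optimal
#' global (Needleman-Wunsch) alignment — match +1, mismatch 0, affine gaps —
#' normalized by the length of the longer sequence. The measure is symmetric,
#' 1 for identical sequences and 0 for sequences sharing no residues.
#'
#' @param a,b peptide strings; `b` may be a vector, in which case `a` is
#'   compared against every element.
#' @return numeric vector of similarities in \[0, 1\].
#' @export
pairwise_similarity <- function(a, b) {
  stopifnot(length(a) == 1L)
  assert_peptides(a); assert_peptides(b)
  aln <- Biostrings::pairwiseAlignment(
    rep(a, length(b)), b, type = "global",
    substitutionMatrix = identity_submat(),
    gapOpening = 2, gapExtension = 0.5)
  Biostrings::nmatch(aln) / pmax(nchar(a), nchar(b))
}

#' Remove near-duplicate peptides by greedy similarity screening
#'
#' Peptides are visited in a deterministic order and each one is dropped iff
#' its similarity to an already-retained peptide is strictly greater than
#' `threshold`; the retained set therefore has all pairwise similarities
#' less than or equal to the threshold.
#'
#' Order matters for greedy screening: by default peptides flagged as
#' experimentally observed are visited before predicted ones (so experimental
#' representatives are kept), with lexicographic order within a priority tier.
#'
#' @param peptides character vector.
#' @param threshold similarity above which a peptide is considered redundant
#'   (default 0.6, strict).
#' @param priority optional numeric vector (lower = visited earlier); defaults
#'   to all-equal so order is purely lexicographic.
#' @return list with `retained` (character vector, in visit order) and
#'   `retained_index` (positions in the input).
#' @export
deduplicate <- function(peptides, threshold = 0.6, priority = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  assert_peptides(peptides)
  if (length(peptides) == 0L)
    return(list(retained = character(0), retained_index = integer(0)))
  if (is.null(priority)) priority <- rep(0, length(peptides))
  stopifnot(length(priority) == length(peptides))
  ord <- order(priority, peptides)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        all(pairwise_similarity(peptides[i], peptides[keep]) <= threshold)) {
      keep <- c(keep, i)
    }
  }
  list(retained = peptides[keep], retained_index = keep)
}

#' Merge seed phosphopeptide pools from multiple screens
#'
#' Concatenates per-screen seed tables (e.g. peptides interacting with two
#' paralogous kinases) into one pool, preserving the origin label of each row.
#'
#' @param ... data frames with columns `accession`, `peptide`, `site_index`,
#'   `residue`, `origin`.
#' @return one combined data frame.
#' @export
merge_seed_pools <- function(...) {
  pools <- list(...)
  cols <- c("accession", "peptide", "site_index", "residue", "origin")
  for (p in pools) {
    if (!all(cols %in% names(p)))
      stop("seed pool missing column(s): ",
           paste(setdiff(cols, names(p)), collapse = ", "))
  }
  out <- do.call(rbind, lapply(pools, function(p) p[, cols, drop = FALSE]))
  rownames(out) <- NULL
  bad <- substr(out$peptide, out$site_index, out$site_index) != out$residue
  if (any(bad))
    stop("seed rows where the annotated residue does not match the peptide: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  out
}

#' Assemble the final peptide library from predictor hits and controls
#'
#' Concatenates HMM hits, machine-learning hits and experimentally observed
#' control windows into the final library with unique integer ids. Windows
#' appearing in more than one source are kept once with source priority
#' hmm > ml > experimental_control, so source attribution is stable.
#'
#' @param hmm_hits,ml_hits,controls data frames with columns `accession` and
#'   `window` (20-mer with the site at the fixed offset), or character vectors
#'   of windows (accessions then default to `"unknown"`).
#' @param site_offset phosphosite offset within each window (default 10).
#' @return data frame with columns `library_id`, `accession`, `window`,
#'   `site_offset`, `source`.
#' @export
assemble_library <- function(hmm_hits, ml_hits, controls,
                             site_offset = DEFAULT_SITE_OFFSET) {
  as_part <- function(x, source) {
    if (is.character(x)) x <- data.frame(accession = rep("unknown", length(x)),
                                         window = x)
    if (nrow(x) == 0L)
      return(data.frame(accession = character(0), window = character(0),
                        source = character(0)))
    data.frame(accession = as.character(x$accession),
               window = as.character(x$window),
               source = source)
  }
  parts <- rbind(as_part(hmm_hits, "hmm"), as_part(ml_hits, "ml"),
                 as_part(controls, "experimental_control"))
  if (nrow(parts) == 0L)
    return(data.frame(library_id = integer(0), accession = character(0),
                      window = character(0), site_offset = integer(0),
                      source = character(0)))
  assert_peptides(parts$window, "window")
  bad <- nchar(parts$window) != WINDOW_LENGTH |
    !substr(parts$window, site_offset, site_offset) %in% PHOSPHO_RESIDUES
  if (any(bad))
    stop("malformed window(s) at input row(s): ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  # cross-source exact-duplicate removal with source priority hmm > ml > control
  parts <- parts[!duplicated(parts$window), , drop = FALSE]
  data.frame(library_id = seq_len(nrow(parts)),
             accession = parts$accession,
             window = parts$window,
             site_offset = rep(as.integer(site_offset), nrow(parts)),
             source = parts$source)
}

#' Sample positive-control peptides from the seed pool
#'
#' Uniform sampling without replacement, reproducible for a fixed seed.
#'
#' @param seed_peptides character vector (or data frame with a `window` or
#'   `peptide` column).
#' @param n number of controls to draw (default 57).
#' @param random_seed integer seed.
#' @return subset of `seed_peptides`, in draw order.
#' @export
sample_controls <- function(seed_peptides, n = 57L, random_seed = 1L) {
  pool <- if (is.data.frame(seed_peptides)) {
    col <- intersect(c("window", "peptide"), names(seed_peptides))[1]
    if (is.na(col)) stop("data frame needs a 'window' or 'peptide' column")
    seed_peptides[[col]]
  } else seed_peptides
  if (n > length(pool))
    stop("cannot sample ", n, " controls from ", length(pool), " peptides")
  idx <- withr_seed(random_seed, sample.int(length(pool), n))
  if (is.data.frame(seed_peptides)) seed_peptides[idx, , drop = FALSE]
  else pool[idx]
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-peptide concentration in an equal-volume peptide pool
#'
#' When `n_peptides` stocks of equal concentration are pooled in equal
#' aliquot volumes, each peptide is diluted `n_peptides`-fold: a 5 mM stock
#' pooled 225-way gives 22.2 uM per peptide.
#'
#' @param stock_concentration concentration of each individual stock (any
#'   unit; the result is in the same unit).
#' @param n_peptides number of peptides pooled.
#' @return per-peptide concentration.
#' @export
pool_per_peptide_concentration <- function(stock_concentration, n_peptides) {
  stopifnot(stock_concentration > 0)
  if (n_peptides <= 0) stop("n_peptides must be positive")
  stock_concentration / n_peptides
}
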