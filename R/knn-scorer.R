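# BLOSUM62 k-nearest-neighbour phosphosite scorer: the similarity-voting
# core of classical phosphosite predictors, trained on known-site windows
# (positives) versus non-site S/T/Y windows (negatives).

#' Build a k-nearest-neighbour phosphosite scorer
#'
#' References are equal-length site-centered windows. Query similarity to a
#' reference is the sum of position-wise BLOSUM62 substitution scores; the
#' prediction score of a query is the fraction of its `k` most similar
#' references that are positives (known sites), a value in \[0, 1\].
#'
#' @param positive_windows windows centered on known phosphosites.
#' @param negative_windows windows centered on S/T/Y residues not known to be
#'   phosphorylated.
#' @param k neighbourhood size; defaults to `min(15, 3 * floor(sqrt(n_refs)))`.
#' @return object of class `knn_scorer`.
#' @export
build_knn_scorer <- function(positive_windows, negative_windows, k = NULL) {
  assert_peptides(positive_windows, "positive window")
  assert_peptides(negative_windows, "negative window")
  if (length(positive_windows) == 0L || length(negative_windows) == 0L)
    stop("need at least one positive and one negative reference window")
  n_ref <- length(positive_windows) + length(negative_windows)
  if (is.null(k)) k <- min(15L, 3L * floor(sqrt(n_ref)))
  k <- as.integer(k)
  if (k < 1L || k > n_ref)
    stop("k must be between 1 and the reference count (", n_ref, ")")
  # deterministic reference order (positives first, lexicographic within
  # label) so distance ties always break the same way
  refs <- data.frame(
    window = c(sort(positive_windows), sort(negative_windows)),
    positive = rep(c(TRUE, FALSE),
                   c(length(positive_windows), length(negative_windows))))
  L <- unique(nchar(refs$window))
  if (length(L) != 1L) stop("reference windows must share one length")
  structure(list(references = refs, k = k, length = L,
                 ref_mat = peptide_matrix(refs$window)),
            class = "knn_scorer")
}

#' @export
print.knn_scorer <- function(x, ...) {
  cat("KNN phosphosite scorer:", sum(x$references$positive), "positive /",
      sum(!x$references$positive), "negative references, k =", x$k, "\n")
  invisible(x)
}

# query-by-reference BLOSUM62 similarity matrix (rows: queries)
knn_similarity_matrix <- function(scorer, windows) {
  B <- blosum62_matrix()
  q <- peptide_matrix(windows)
  r <- scorer$ref_mat
  if (ncol(q) != ncol(r)) stop("query length must match reference length")
  S <- matrix(0, nrow(q), nrow(r))
  for (p in seq_len(ncol(q))) S <- S + B[q[, p], r[, p], drop = FALSE]
  unname(S)
}

#' KNN phosphosite prediction score
#'
#' @param scorer a `knn_scorer`.
#' @param windows character vector of query windows (same length as the
#'   references).
#' @return numeric vector: fraction of the k nearest references that are
#'   positive, in \[0, 1\]. Ties in similarity are broken by reference rank
#'   in the scorer's deterministic order.
#' @export
knn_score <- function(scorer, windows) {
  stopifnot(inherits(scorer, "knn_scorer"))
  if (length(windows) == 0L) return(numeric(0))
  assert_peptides(windows, "query window")
  S <- knn_similarity_matrix(scorer, windows)
  pos <- scorer$references$positive
  k <- scorer$k
  vapply(seq_len(nrow(S)), function(i) {
    ord <- order(-S[i, ], seq_along(pos))  # similarity desc, then ref rank
    mean(pos[ord[seq_len(k)]])
  }, numeric(1))
}

#' Scan a proteome for candidate phosphosite windows
#'
#' Slides over every S/T/Y residue that has full flanking context (9 upstream
#' and 10 downstream residues by default), extracts the centered window, and
#' scores it once with either a profile HMM (log-odds bits plus calibrated
#' E-value; hits satisfy `evalue < threshold`) or a KNN scorer (hits satisfy
#' `score > threshold`). Hits are sorted by significance, then coordinates.
#'
#' @param proteome named character vector of protein sequences (names are
#'   accessions), or an `AAStringSet`.
#' @param model a `profile_hmm` or `knn_scorer`.
#' @param threshold E-value cutoff for the HMM (default 0.001) or score
#'   cutoff for KNN (default 0.8).
#' @param calibration an `evalue_calibration` (required for HMM scanning;
#'   built automatically over the scanned window count when omitted).
#' @param site_offset site position within the window (default 10).
#' @param random_seed seed used only when a calibration must be built.
#' @return data frame with columns `accession`, `position`, `window`,
#'   `score`, `evalue` (NA for KNN), `predictor`.
#' @export
scan_proteome <- function(proteome, model, threshold = NULL,
                          calibration = NULL,
                          site_offset = DEFAULT_SITE_OFFSET,
                          random_seed = 1L) {
  if (methods::is(proteome, "AAStringSet"))
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  empty <- data.frame(accession = character(0), position = integer(0),
                      window = character(0), score = numeric(0),
                      evalue = numeric(0), predictor = character(0))
  if (length(proteome) == 0L) return(empty)
  if (is.null(names(proteome)))
    names(proteome) <- paste0("protein_", seq_along(proteome))
  is_hmm <- inherits(model, "profile_hmm")
  if (!is_hmm && !inherits(model, "knn_scorer"))
    stop("model must be a profile_hmm or knn_scorer")
  if (is.null(threshold)) threshold <- if (is_hmm) 0.001 else 0.8
  wlen <- if (is_hmm) model$length else model$length
  upstream <- site_offset - 1L
  downstream <- wlen - site_offset

  hits <- lapply(names(proteome), function(acc) {
    seqc <- proteome[[acc]]
    chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
    sites <- which(chars %in% PHOSPHO_RESIDUES)
    sites <- sites[sites - 1L >= upstream &
                   nchar(seqc) - sites >= downstream]
    if (length(sites) == 0L) return(NULL)
    windows <- substring(seqc, sites - upstream, sites + downstream)
    data.frame(accession = acc, position = sites, window = windows)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)

  if (is_hmm) {
    hits$score <- forward_log_odds(model, hits$window)
    if (is.null(calibration))
      calibration <- calibrate_evalues(model, random_seed = random_seed,
                                       search_space_size = nrow(hits))
    hits$evalue <- evalue(calibration, hits$score)
    hits$predictor <- "hmm"
    hits <- hits[hits$evalue < threshold, , drop = FALSE]
    hits <- hits[order(hits$evalue, hits$accession, hits$position), ,
                 drop = FALSE]
  } else {
    hits$score <- knn_score(model, hits$window)
    hits$evalue <- NA_real_
    hits$predictor <- "ml"
    hits <- hits[hits$score > threshold, , drop = FALSE]
    hits <- hits[order(-hits$score, hits$accession, hits$position), ,
                 drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}
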