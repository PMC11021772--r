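# Redundancy clustering of candidate windows and consensus-motif detection
# by position-specific binomial enrichment on center-aligned windows.

#' Greedy identity clustering of equal-length windows
#'
#' Windows are visited in input order; each window joins the first existing
#' representative with fractional identity (matching positions / window
#' length) at or above the threshold, otherwise it founds a new cluster.
#' Every member is therefore at least `identity_threshold` identical to its
#' representative. For 20-mers the default 0.90 means 18 or more matching
#' positions.
#'
#' @param windows character vector of equal-length windows.
#' @param identity_threshold fractional identity for joining a cluster
#'   (default 0.90, inclusive).
#' @return list with `representatives` (character vector), `cluster`
#'   (integer vector assigning each input window to a representative) and
#'   `representative_index` (positions of representatives in the input).
#' @export
cluster_redundant_peptides <- function(windows, identity_threshold = 0.90) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(windows) == 0L)
    return(list(representatives = character(0), cluster = integer(0),
                representative_index = integer(0)))
  assert_peptides(windows)
  m <- peptide_matrix(windows)
  L <- ncol(m)
  rep_idx <- integer(0)
  cluster <- integer(length(windows))
  for (i in seq_along(windows)) {
    assigned <- FALSE
    for (ci in seq_along(rep_idx)) {
      ident <- sum(m[i, ] == m[rep_idx[ci], ]) / L
      if (ident >= identity_threshold) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      cluster[i] <- length(rep_idx)
    }
  }
  list(representatives = windows[rep_idx], cluster = cluster,
       representative_index = rep_idx)
}

#' Position-specific consensus motif by binomial enrichment
#'
#' For every window offset (relative to the phosphosite at `site_offset`)
#' and every residue, tests whether the observed residue count among the
#' center-aligned representatives exceeds the background expectation with a
#' one-sided exact binomial test. Significant cells (raw `p < alpha`) define
#' candidate motif positions; the reported motif is restricted to the
#' contiguous offset window of width at most `max_window` with the strongest
#' combined significance. The consensus takes the most enriched residue per
#' significant offset, and member ids are the windows matching the full
#' consensus. Bonferroni-adjusted p-values are reported alongside the raw
#' ones.
#'
#' @param representatives character vector of equal-length center-aligned
#'   windows (at least 5).
#' @param background named residue frequency vector summing to 1 (e.g. from
#'   [residue_frequencies()] over the whole library or the proteome).
#' @param alpha raw p-value cutoff (default 0.05, strict).
#' @param max_window maximum motif width in offsets (default 5).
#' @param site_offset phosphosite position within the window (default 10).
#' @param ids optional identifiers parallel to `representatives` used for
#'   `member_ids` (defaults to indices).
#' @return object of class `motif_result`: `cells` (per offset/residue
#'   counts and p-values), `positions` (significant offsets inside the
#'   motif window), `consensus` (data frame offset/residue), `consensus_string`,
#'   `member_ids`, `n`.
#' @export
find_positional_motif <- function(representatives, background, alpha = 0.05,
                                  max_window = 5L,
                                  site_offset = DEFAULT_SITE_OFFSET,
                                  ids = NULL) {
  n <- length(representatives)
  if (n < 5L) stop("need at least 5 representatives for motif detection")
  background <- validate_background(background)
  if (is.null(ids)) ids <- seq_len(n)
  m <- peptide_int_matrix(representatives)
  L <- ncol(m)
  offsets <- seq_len(L) - site_offset
  cells <- expand.grid(column = seq_len(L), residue = AA_ALPHABET,
                       stringsAsFactors = FALSE)
  cells$offset <- cells$column - site_offset
  cells$count <- mapply(function(col, res) {
    sum(m[, col] == match(res, AA_ALPHABET))
  }, cells$column, cells$residue)
  p0 <- as.numeric(background[cells$residue])
  # one-sided upper-tail exact binomial p-value: P(X >= count)
  cells$p_value <- stats::pbinom(cells$count - 1L, n, p0, lower.tail = FALSE)
  cells$p_adjusted <- pmin(1, cells$p_value * nrow(cells))
  sig <- cells[cells$p_value < alpha & cells$count > 0, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(structure(list(cells = cells, positions = integer(0),
                          consensus = data.frame(offset = integer(0),
                                                 residue = character(0)),
                          consensus_string = strrep(".", L),
                          member_ids = ids[integer(0)], n = n,
                          alpha = alpha, max_window = max_window),
                     class = "motif_result"))
  }
  # strongest contiguous offset window of width <= max_window: maximize the
  # summed -log10(p) of the best significant cell per offset
  per_offset <- vapply(offsets, function(o) {
    p <- sig$p_value[sig$offset == o]
    if (length(p) == 0L) 0 else max(-log10(pmax(p, 1e-300)))
  }, numeric(1))
  width <- min(max_window, L)
  starts <- seq_len(L - width + 1L)
  window_scores <- vapply(starts, function(s) sum(per_offset[s:(s + width - 1L)]),
                          numeric(1))
  best <- starts[which.max(window_scores)]
  window_offsets <- offsets[best:(best + width - 1L)]
  positions <- sort(intersect(unique(sig$offset), window_offsets))
  consensus <- do.call(rbind, lapply(positions, function(o) {
    d <- sig[sig$offset == o, , drop = FALSE]
    d <- d[order(d$p_value, d$residue), , drop = FALSE]
    data.frame(offset = o, residue = d$residue[1], p_value = d$p_value[1],
               p_adjusted = d$p_adjusted[1])
  }))
  cons_chars <- rep(".", L)
  for (r in seq_len(nrow(consensus)))
    cons_chars[consensus$offset[r] + site_offset] <- consensus$residue[r]
  # members must match every consensus position
  member_mask <- rep(TRUE, n)
  for (r in seq_len(nrow(consensus))) {
    col <- consensus$offset[r] + site_offset
    member_mask <- member_mask &
      m[, col] == match(consensus$residue[r], AA_ALPHABET)
  }
  structure(list(cells = cells, positions = positions,
                 consensus = consensus,
                 consensus_string = paste(cons_chars, collapse = ""),
                 member_ids = ids[member_mask], n = n,
                 alpha = alpha, max_window = max_window),
            class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat("Positional motif over", x$n, "windows: ", x$consensus_string, "\n")
  if (nrow(x$consensus))
    cat("  significant offsets:",
        paste(sprintf("%+d:%s", x$consensus$offset, x$consensus$residue),
              collapse = " "), "\n")
  cat("  members:", length(x$member_ids), "\n")
  invisible(x)
}

#' Position-frequency matrix of a window set
#'
#' @param windows equal-length windows.
#' @param site_offset phosphosite position (default 10); column names are
#'   offsets relative to it.
#' @return 20 x L matrix of residue frequencies per column.
#' @export
position_frequency_matrix <- function(windows,
                                      site_offset = DEFAULT_SITE_OFFSET) {
  m <- peptide_int_matrix(windows)
  L <- ncol(m)
  pfm <- vapply(seq_len(L), function(col) {
    tabulate(m[, col], nbins = 20L) / nrow(m)
  }, numeric(20))
  rownames(pfm) <- AA_ALPHABET
  colnames(pfm) <- sprintf("%+d", seq_len(L) - site_offset)
  pfm
}
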