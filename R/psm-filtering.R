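# PSM-table ingestion and the negative-control-derived filtration rule:
# thresholds are chosen so that no phosphopeptide identified in any negative
# control (kinase-dead with or without ATP, wild type without ATP) survives,
# and the same rule is then applied to the test condition (wild type + ATP).

PSM_COLUMNS <- c("sample_id", "enzyme_state", "atp_state", "library_id",
                 "sequence", "is_phospho", "site_positions", "xcorr",
                 "site_probability")

#' Read a PSM table
#'
#' Reads a tab-separated peptide-spectrum-match table with columns
#' `sample_id enzyme_state atp_state library_id sequence is_phospho
#' site_positions xcorr site_probability`. `site_positions` is a
#' comma-separated list of in-peptide indices (empty for unmodified PSMs);
#' `site_probability` is the best site-localization probability and may be
#' empty/NA for unmodified PSMs. Malformed rows are dropped and reported in
#' the `rejected` attribute with line numbers and reasons.
#'
#' @param path TSV file path.
#' @return data frame of validated PSM records; attribute `rejected` holds a
#'   data frame (`line`, `reason`) of dropped rows.
#' @export
read_psm_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(PSM_COLUMNS, names(raw))
  if (length(missing))
    stop("PSM table missing column(s): ", paste(missing, collapse = ", "))
  raw <- raw[, PSM_COLUMNS, drop = FALSE]
  validate_psm_records(raw, line_offset = 1L)
}

# shared validation for file input and in-memory tables
validate_psm_records <- function(raw, line_offset = 0L) {
  n <- nrow(raw)
  reasons <- character(n)
  lid <- suppressWarnings(as.integer(raw$library_id))
  xcorr <- suppressWarnings(as.numeric(raw$xcorr))
  prob <- suppressWarnings(as.numeric(raw$site_probability))
  prob[!nzchar(trimws(ifelse(is.na(raw$site_probability), "",
                             raw$site_probability)))] <- NA_real_
  phospho <- tolower(trimws(raw$is_phospho)) %in% c("true", "t", "1", "yes")
  sites <- lapply(raw$site_positions, function(s) {
    s <- trimws(s)
    if (is.na(s) || !nzchar(s)) return(integer(0))
    suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
  })
  bad_site <- vapply(sites, anyNA, logical(1))
  set_reason <- function(cond, msg) {
    new <- cond & !nzchar(reasons)
    reasons[new] <<- msg
  }
  set_reason(is.na(lid), "library_id is not an integer")
  set_reason(is.na(xcorr) | xcorr < 0, "xcorr missing or negative")
  set_reason(bad_site, "unparseable site_positions")
  set_reason(phospho & lengths(sites) == 0L,
             "phospho PSM without site positions")
  set_reason(!phospho & lengths(sites) > 0L,
             "unmodified PSM with site positions")
  set_reason(phospho & (is.na(prob) | prob < 0 | prob > 1),
             "site_probability missing or outside [0,1]")
  ok <- !nzchar(reasons)
  out <- data.frame(sample_id = raw$sample_id[ok],
                    enzyme_state = raw$enzyme_state[ok],
                    atp_state = raw$atp_state[ok],
                    library_id = lid[ok],
                    sequence = raw$sequence[ok],
                    is_phospho = phospho[ok],
                    site_positions = I(sites[ok]),
                    xcorr = xcorr[ok],
                    site_probability = prob[ok])
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(
    line = which(!ok) + line_offset, reason = reasons[!ok])
  out
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: serializes `site_positions` as a
#' comma-separated list and NA probabilities as empty fields.
#'
#' @param records PSM data frame.
#' @param path output TSV path.
#' @export
write_psm_table <- function(records, path) {
  out <- records
  out$site_positions <- vapply(records$site_positions, paste,
                               character(1), collapse = ",")
  out$is_phospho <- ifelse(records$is_phospho, "TRUE", "FALSE")
  out$site_probability <- ifelse(is.na(records$site_probability), "",
                                 format(records$site_probability,
                                        trim = TRUE, scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filtration criteria for valid phosphopeptide identification
#'
#' @param min_psm_count minimum number of supporting phospho-PSMs.
#' @param min_xcorr strict Xcorr lower bound (a PSM supports a call only with
#'   `xcorr > min_xcorr`).
#' @param min_site_probability minimum best site-localization probability.
#' @return object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_psm_count = 2L, min_xcorr = 2.04,
                            min_site_probability = 0.75) {
  stopifnot(min_psm_count >= 1, min_xcorr >= 0,
            min_site_probability >= 0, min_site_probability <= 1)
  structure(list(min_psm_count = as.integer(min_psm_count),
                 min_xcorr = as.numeric(min_xcorr),
                 min_site_probability = as.numeric(min_site_probability)),
            class = "filter_criteria")
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat("Phosphopeptide filtration criteria:\n",
      " PSM count >=", x$min_psm_count, "\n",
      " Xcorr >", x$min_xcorr, "(strict)\n",
      " site probability >=", x$min_site_probability, "\n")
  invisible(x)
}

# one row per (phospho PSM, site): explode multi-site PSMs so each listed
# site gets its own observation
explode_phospho_sites <- function(records) {
  ph <- records[records$is_phospho, , drop = FALSE]
  if (nrow(ph) == 0L)
    return(data.frame(sample_id = character(0), library_id = integer(0),
                      site = integer(0), xcorr = numeric(0),
                      site_probability = numeric(0)))
  reps <- lengths(ph$site_positions)
  data.frame(sample_id = rep(ph$sample_id, reps),
             library_id = rep(ph$library_id, reps),
             site = unlist(ph$site_positions, use.names = FALSE),
             xcorr = rep(ph$xcorr, reps),
             site_probability = rep(ph$site_probability, reps))
}

#' Derive filtration thresholds from negative-control PSMs
#'
#' Every phosphopeptide identification in a negative control is by design a
#' false positive, so the thresholds are set just above the worst offender:
#' `min_xcorr` is the maximum Xcorr over all negative phospho-PSMs (applied
#' strictly, so that exact value fails), and `min_psm_count` is one more than
#' the largest per-peptide phospho-PSM count seen in any single negative
#' sample. Re-applying the derived criteria to the negatives therefore passes
#' zero phosphopeptides.
#'
#' @param negative_controls PSM records from negative-control samples only
#'   (kinase-dead with/without ATP and wild type without ATP).
#' @param min_site_probability localization threshold to carry into the
#'   criteria (not derived from the negatives; default 0.75).
#' @return a [filter_criteria()] object.
#' @export
derive_filter_thresholds <- function(negative_controls,
                                     min_site_probability = 0.75) {
  if (is.null(negative_controls) || nrow(negative_controls) == 0L)
    stop("no negative-control records supplied")
  ph <- explode_phospho_sites(negative_controls)
  if (nrow(ph) == 0L)
    return(filter_criteria(1L, 0, min_site_probability))
  per_sample <- stats::aggregate(
    xcorr ~ sample_id + library_id + site, data = ph, FUN = length)
  filter_criteria(min_psm_count = max(per_sample$xcorr) + 1L,
                  min_xcorr = max(ph$xcorr),
                  min_site_probability = min_site_probability)
}

#' Apply filtration criteria to PSM records
#'
#' A (peptide, site) phosphopeptide passes iff (1) its supporting phospho-PSM
#' count is at least `min_psm_count`, (2) at least one supporting PSM has
#' `xcorr` strictly greater than `min_xcorr`, and (3) its best
#' site-localization probability is at least `min_site_probability`.
#'
#' @param records PSM records (typically the wild-type +ATP condition).
#' @param criteria a [filter_criteria()] object.
#' @return data frame of passing phosphopeptides with columns `library_id`,
#'   `site`, `psm_count`, `max_xcorr`, `best_site_probability`.
#' @export
apply_filters <- function(records, criteria) {
  stopifnot(inherits(criteria, "filter_criteria"))
  ph <- explode_phospho_sites(records)
  if (nrow(ph) == 0L)
    return(data.frame(library_id = integer(0), site = integer(0),
                      psm_count = integer(0), max_xcorr = numeric(0),
                      best_site_probability = numeric(0)))
  key <- paste(ph$library_id, ph$site, sep = "/")
  agg <- do.call(rbind, lapply(split(ph, key), function(d) {
    data.frame(library_id = d$library_id[1], site = d$site[1],
               psm_count = nrow(d), max_xcorr = max(d$xcorr),
               best_site_probability = max(d$site_probability))
  }))
  pass <- agg$psm_count >= criteria$min_psm_count &
    agg$max_xcorr > criteria$min_xcorr &
    agg$best_site_probability >= criteria$min_site_probability
  out <- agg[pass, , drop = FALSE]
  out <- out[order(out$library_id, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag peptides whose phosphorylated form appears in every sample
#'
#' A peptide detected in phosphorylated form across all samples — including
#' every negative control — cannot be a genuine kinase-dependent signal (the
#' usual culprit is a serine-rich sequence the search engine cannot
#' confidently localize). Such peptides are excluded from all downstream
#' analyses.
#'
#' @param per_sample_phospho named list: for each sample, the vector of
#'   library_ids with at least one phospho-PSM.
#' @return integer vector of excluded library_ids.
#' @export
flag_ubiquitous_outliers <- function(per_sample_phospho) {
  if (length(per_sample_phospho) < 2L)
    stop("need at least two samples to flag ubiquitous outliers")
  common <- Reduce(intersect, lapply(per_sample_phospho, unique))
  sort(as.integer(common))
}

#' Per-sample phosphopeptide detection sets from PSM records
#'
#' @param records PSM records across all samples.
#' @param samples sample ids the screen design contains; samples without any
#'   PSM still contribute an (empty) detection set. Defaults to the samples
#'   observed in `records`.
#' @return named list mapping sample_id to the library_ids with at least one
#'   phospho-PSM in that sample.
#' @export
per_sample_phospho_sets <- function(records, samples = NULL) {
  ph <- records[records$is_phospho, , drop = FALSE]
  ids <- split(ph$library_id, ph$sample_id)
  all_samples <- union(samples, unique(records$sample_id))
  out <- stats::setNames(vector("list", length(all_samples)), all_samples)
  for (s in all_samples) {
    v <- ids[[s]]
    out[[s]] <- if (is.null(v)) integer(0) else sort(unique(v))
  }
  out
}
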