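# Spectral-count stoichiometry and evidence-based candidate prioritization.

#' Phosphorylation stoichiometry from spectral counts
#'
#' For each surviving (peptide, site), stoichiometry is
#' `100 * phosphopeptide spectrum count / total peptide spectrum count`,
#' where the denominator counts every PSM of the peptide sequence in the
#' condition — phosphorylated (any site) plus unmodified — so a peptide never
#' seen unmodified scores 100%.
#'
#' @param records PSM records for one condition (typically wild type +ATP).
#' @param survivors data frame with columns `library_id`, `site` (the output
#'   of [apply_filters()]).
#' @return data frame with columns `library_id`, `site`,
#'   `phospho_psm_count`, `total_psm_count`, `stoichiometry` (percent),
#'   `n_sites_on_peptide`.
#' @export
compute_stoichiometry <- function(records, survivors) {
  if (nrow(survivors) == 0L)
    return(data.frame(library_id = integer(0), site = integer(0),
                      phospho_psm_count = integer(0),
                      total_psm_count = integer(0),
                      stoichiometry = numeric(0),
                      n_sites_on_peptide = integer(0)))
  missing <- setdiff(survivors$library_id, records$library_id)
  if (length(missing))
    stop("survivors not present in the PSM records: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ph <- explode_phospho_sites(records)
  total_by_peptide <- table(factor(records$library_id))
  sites_per_peptide <- stats::aggregate(site ~ library_id, data = survivors,
                                        FUN = length)
  out <- survivors[, c("library_id", "site"), drop = FALSE]
  out$phospho_psm_count <- mapply(function(id, s) {
    sum(ph$library_id == id & ph$site == s)
  }, out$library_id, out$site)
  out$total_psm_count <- as.integer(total_by_peptide[as.character(out$library_id)])
  if (any(out$phospho_psm_count > out$total_psm_count))
    stop("phospho-PSM count exceeds total PSM count; inconsistent records")
  out$stoichiometry <- 100 * out$phospho_psm_count / out$total_psm_count
  out$n_sites_on_peptide <- sites_per_peptide$site[
    match(out$library_id, sites_per_peptide$library_id)]
  out <- out[order(out$library_id, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# numeric priority of a compartment label; unknown labels rank last
localization_priority <- function(compartment) {
  p <- match(compartment, COMPARTMENTS)
  p[is.na(p)] <- length(COMPARTMENTS) + 1L
  p
}

#' Rank substrate candidates by the screening evidence hierarchy
#'
#' Candidates are ordered lexicographically: stoichiometry (descending),
#' phospho-PSM count (descending), subcellular-localization priority
#' (plasma membrane > cytosol > endoplasmic reticulum > nucleus > other
#' compartments), consensus-motif membership, and finally ascending
#' library_id so the order is total and reproducible. Missing annotations
#' rank lowest for their key and are flagged with a warning.
#'
#' @param stoich output of [compute_stoichiometry()].
#' @param library peptide library data frame (`library_id`, `accession`,
#'   `source`).
#' @param localization optional data frame `accession`, `compartment`.
#' @param motif_members optional vector of library_ids inside the consensus
#'   motif.
#' @param db_status optional data frame `library_id`, `status` with values
#'   `none`/`one`/`both` (reported, not used in the sort).
#' @return data frame of class `candidate_report` with ranks 1..n.
#' @export
rank_candidates <- function(stoich, library, localization = NULL,
                            motif_members = integer(0), db_status = NULL) {
  out <- stoich
  out$protein_accession <- library$accession[
    match(out$library_id, library$library_id)]
  out$source <- library$source[match(out$library_id, library$library_id)]
  if (is.null(localization)) {
    out$localization <- NA_character_
  } else {
    out$localization <- localization$compartment[
      match(out$protein_accession, localization$accession)]
  }
  if (anyNA(out$localization) && !is.null(localization))
    warning(sum(is.na(out$localization)),
            " candidate(s) without localization evidence; ranked last for that key")
  out$in_consensus_motif <- out$library_id %in% motif_members
  out$known_in_databases <- if (is.null(db_status)) NA_character_ else
    db_status$status[match(out$library_id, db_status$library_id)]
  ord <- order(-out$stoichiometry, -out$phospho_psm_count,
               localization_priority(out$localization),
               !out$in_consensus_motif, out$library_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  cols <- c("rank", "library_id", "protein_accession", "site",
            "stoichiometry", "phospho_psm_count", "total_psm_count",
            "localization", "in_consensus_motif", "known_in_databases",
            "source")
  structure(out[, cols, drop = FALSE], class = c("candidate_report",
                                                 "data.frame"))
}
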