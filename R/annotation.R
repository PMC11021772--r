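# Candidate annotation: GO class abundance, weighted subcellular
# localization consensus, and phosphosite-database cross-reference.

#' GO class abundance among candidate proteins
#'
#' Computes, per namespace (biological process, molecular function, cellular
#' component), the percentage of annotation assignments falling in each GO
#' class among the candidate proteins; only classes strictly above
#' `min_percent` are retained. The denominator is the number of annotation
#' assignments (not proteins), so percentages within a namespace sum to 100
#' before trimming. Candidates absent from the mapping count as a single
#' "unannotated" assignment.
#'
#' @param protein_to_terms data frame `accession`, `namespace`, `term`.
#' @param candidates character vector of candidate protein accessions.
#' @param min_percent retention threshold in percent (default 1, strict).
#' @return data frame `namespace`, `term`, `count`, `percent`.
#' @export
summarize_go_abundance <- function(protein_to_terms, candidates,
                                   min_percent = 1.0) {
  if (length(candidates) == 0L) stop("empty candidate set")
  candidates <- unique(candidates)
  ann <- protein_to_terms[protein_to_terms$accession %in% candidates, ,
                          drop = FALSE]
  missing <- setdiff(candidates, ann$accession)
  if (length(missing)) {
    ann <- rbind(ann,
                 data.frame(accession = missing, namespace = "unannotated",
                            term = "unannotated"))
  }
  out <- do.call(rbind, lapply(split(ann, ann$namespace), function(d) {
    tab <- table(d$term)
    data.frame(namespace = d$namespace[1], term = names(tab),
               count = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(d))
  }))
  out <- out[out$percent > min_percent, , drop = FALSE]
  out <- out[order(out$namespace, -out$percent, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted subcellular-localization consensus for one protein
#'
#' Scores each compartment as `5 * n_experimental + 1 * n_predicted`
#' (experimentally determined localizations weigh five times more than in
#' silico predictions) and picks the highest-scoring compartment. Ties are
#' resolved by the fixed compartment priority order (plasma membrane,
#' cytosol, endoplasmic reticulum, nucleus, ...) and flagged.
#'
#' @param evidence data frame `accession`, `compartment`, `evidence_type`
#'   (`experimental` or `predicted`).
#' @param protein accession to score.
#' @param experimental_weight weight of one experimental observation
#'   relative to one prediction (default 5).
#' @return list with `compartment`, `score`, `tie` (logical) and
#'   `score_table` (per-compartment scores); compartment `"unknown"` when no
#'   evidence exists.
#' @export
score_subcellular_localization <- function(evidence, protein,
                                           experimental_weight = 5) {
  rows <- evidence[evidence$accession == protein, , drop = FALSE]
  if (nrow(rows) == 0L)
    return(list(compartment = "unknown", score = 0, tie = FALSE,
                score_table = data.frame(compartment = character(0),
                                         score = numeric(0))))
  bad <- !rows$evidence_type %in% c("experimental", "predicted")
  if (any(bad)) stop("unknown evidence_type: ",
                     paste(unique(rows$evidence_type[bad]), collapse = ", "))
  w <- ifelse(rows$evidence_type == "experimental", experimental_weight, 1)
  score_table <- stats::aggregate(w, by = list(compartment = rows$compartment),
                                  FUN = sum)
  names(score_table)[2] <- "score"
  score_table <- score_table[
    order(-score_table$score, localization_priority(score_table$compartment)), ,
    drop = FALSE]
  rownames(score_table) <- NULL
  tie <- sum(score_table$score == score_table$score[1]) > 1L
  list(compartment = score_table$compartment[1],
       score = score_table$score[1], tie = tie, score_table = score_table)
}

#' Localization calls for a set of proteins
#'
#' Vectorized wrapper over [score_subcellular_localization()].
#'
#' @inheritParams score_subcellular_localization
#' @param proteins accessions to score.
#' @return data frame `accession`, `compartment`, `score`, `tie`.
#' @export
call_localizations <- function(evidence, proteins, experimental_weight = 5) {
  rows <- lapply(unique(proteins), function(p) {
    r <- score_subcellular_localization(evidence, p, experimental_weight)
    data.frame(accession = p, compartment = r$compartment, score = r$score,
               tie = r$tie)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-reference candidate phosphopeptides against phosphosite databases
#'
#' A candidate window is `confirmed` in a database iff the full window occurs
#' verbatim (100% identity, full coverage — equivalent to an exact substring
#' match) in one of that database's protein sequences AND the database lists
#' a phosphosite at the aligned position; `sequence-only` iff the window
#' occurs but no phosphosite aligns with the candidate site; otherwise
#' `novel`.
#'
#' @param candidates data frame `library_id`, `window`, `site_offset`.
#' @param databases named list; each element is a data frame with columns
#'   `accession`, `sequence`, `site_position` (1-based in the protein;
#'   NA rows contribute sequence only).
#' @return list with `status` (data frame: `library_id`, one column per
#'   database with values confirmed/sequence-only/novel, and a combined
#'   `status` in none/one/both for two-database input) and `summary`
#'   (counts: total, known_in_either, known_in_both, novel).
#' @export
crossref_phospho_databases <- function(candidates, databases) {
  stopifnot(length(databases) >= 1L, !is.null(names(databases)))
  per_db <- vapply(names(databases), function(dbname) {
    db <- databases[[dbname]]
    vapply(seq_len(nrow(candidates)), function(i) {
      win <- candidates$window[i]
      off <- candidates$site_offset[i]
      best <- "novel"
      for (j in seq_len(nrow(db))) {
        starts <- gregexpr(win, db$sequence[j], fixed = TRUE)[[1]]
        if (starts[1] == -1L) next
        best <- if (best == "novel") "sequence-only" else best
        hit_sites <- db$site_position[!is.na(db$site_position) &
                                        db$accession == db$accession[j] &
                                        db$sequence == db$sequence[j]]
        for (s in starts) {
          if ((s + off - 1L) %in% hit_sites) best <- "confirmed"
        }
      }
      best
    }, character(1))
  }, character(nrow(candidates)))
  per_db <- matrix(per_db, nrow = nrow(candidates),
                   dimnames = list(NULL, names(databases)))
  n_confirmed <- rowSums(per_db == "confirmed")
  status <- data.frame(library_id = candidates$library_id)
  for (dbname in names(databases)) status[[dbname]] <- per_db[, dbname]
  status$status <- c("none", "one", "both")[pmin(n_confirmed, 2) + 1L]
  summary <- data.frame(total = nrow(candidates),
                        known_in_either = sum(n_confirmed >= 1),
                        known_in_both = sum(n_confirmed >= 2),
                        sequence_only_somewhere =
                          sum(n_confirmed == 0 &
                                rowSums(per_db == "sequence-only") > 0),
                        novel = sum(n_confirmed == 0))
  list(status = status, summary = summary)
}
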