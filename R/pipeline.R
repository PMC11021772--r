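# End-to-end orchestration of the screening stages over a synthetic or
# user-supplied screen, with a run manifest for reproducibility accounting.

#' Run the full screening pipeline on a synthetic 2x2 screen
#'
#' Executes the stages in dependency order: generate (or accept) the screen,
#' flag ubiquitous-outlier peptides and drop them from all analyses, derive
#' filtration thresholds from the three negative controls, apply them to the
#' wild-type +ATP condition, compute spectral-count stoichiometry, cluster
#' the surviving windows and search for a positional consensus motif, rank
#' candidates, and attribute them to their library sources. A fixed config
#' (including its seed) reproduces identical outputs.
#'
#' @param config a [synthetic_screen_config()].
#' @param screen optional precomputed list with elements `library`, `truth`
#'   and `records` (PSM data frame); when omitted the synthetic generator
#'   supplies them.
#' @param annotations optional list with elements `go` (accession/namespace/
#'   term), `localization` (accession/compartment/evidence_type) and
#'   `databases` (named list of phosphosite tables).
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSVs and their digests recorded in the manifest.
#' @return list of class `kic_run`: `library`, `truth`, `criteria`,
#'   `outlier_ids`, `survivors`, `stoichiometry`, `motif`, `report`,
#'   `source_attribution`, `manifest`.
#' @export
run_screen_pipeline <- function(config, screen = NULL, annotations = NULL,
                                out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  design_samples <- NULL
  if (is.null(screen)) {
    gen <- generate_proteome_and_seeds(config)
    records <- simulate_psm_tables(config, gen$library, gen$truth)
    screen <- list(library = gen$library, truth = gen$truth,
                   records = records, proteome = gen$proteome)
    design_samples <- SAMPLE_DESIGN$sample_id
  }
  library <- screen$library
  records <- screen$records

  # stage 1: ubiquitous outliers are excluded from all analyses up front,
  # so they cannot distort the negative-control thresholds
  outlier_ids <- flag_ubiquitous_outliers(
    per_sample_phospho_sets(records, samples = design_samples))
  records <- records[!records$library_id %in% outlier_ids, , drop = FALSE]

  # stage 2: thresholds from the negatives (dead +/-ATP, wild type -ATP)
  negatives <- records[records$enzyme_state == "dead" |
                         records$atp_state == "minus", , drop = FALSE]
  # negatives that ran but identified nothing are a vacuous background,
  # not a missing input
  criteria <- if (nrow(negatives) == 0L) filter_criteria(1L, 0, 0.75)
              else derive_filter_thresholds(negatives)

  # stage 3: the test condition
  test <- records[records$enzyme_state == "wildtype" &
                    records$atp_state == "plus", , drop = FALSE]
  survivors <- apply_filters(test, criteria)
  stoich <- compute_stoichiometry(test, survivors)

  # stage 4: motif on the surviving windows (clustered at 90% identity)
  surv_windows <- library$window[match(survivors$library_id,
                                       library$library_id)]
  motif <- NULL
  motif_members <- integer(0)
  if (length(surv_windows) >= 5L) {
    cl <- cluster_redundant_peptides(surv_windows)
    bg <- residue_frequencies(library$window)
    motif <- find_positional_motif(
      cl$representatives, bg,
      ids = survivors$library_id[cl$representative_index])
    # membership extends from representatives to all clustered survivors
    rep_member <- cl$cluster %in%
      which(survivors$library_id[cl$representative_index] %in%
              motif$member_ids)
    motif_members <- survivors$library_id[rep_member]
  }

  # stage 5: annotation (optional inputs) and ranking
  loc_calls <- NULL
  db_status <- NULL
  go_summary <- NULL
  accs <- unique(library$accession[match(survivors$library_id,
                                         library$library_id)])
  if (!is.null(annotations$localization))
    loc_calls <- call_localizations(annotations$localization, accs)
  if (!is.null(annotations$databases) && nrow(survivors) > 0L) {
    cand <- data.frame(library_id = survivors$library_id,
                       window = surv_windows,
                       site_offset = DEFAULT_SITE_OFFSET)
    xref <- crossref_phospho_databases(cand, annotations$databases)
    db_status <- xref$status[, c("library_id", "status")]
  }
  if (!is.null(annotations$go) && length(accs) > 0L)
    go_summary <- summarize_go_abundance(annotations$go, accs)
  loc_for_rank <- if (is.null(loc_calls)) NULL else
    data.frame(accession = loc_calls$accession,
               compartment = loc_calls$compartment)
  report <- rank_candidates(stoich, library, localization = loc_for_rank,
                            motif_members = motif_members,
                            db_status = db_status)
  attribution <- attribute_sources(report, library)

  manifest <- build_manifest(config, library, records, survivors, report,
                             motif_members, outlier_ids)
  run <- list(library = library, truth = screen$truth, criteria = criteria,
              outlier_ids = outlier_ids, survivors = survivors,
              stoichiometry = stoich, motif = motif,
              go_summary = go_summary, localization = loc_calls,
              db_status = db_status, report = report,
              source_attribution = attribution, manifest = manifest)
  class(run) <- "kic_run"
  if (!is.null(out_dir)) run$manifest <- write_run_outputs(run, out_dir)
  run
}

build_manifest <- function(config, library, records, survivors, report,
                           motif_members, outlier_ids) {
  if (nrow(survivors) > nrow(library))
    stop("manifest inconsistency: more survivors than library members")
  list(config = unclass(config),
       random_seed = config$random_seed,
       version = as.character(utils::packageVersion("kicscreen")),
       counts = c(library_size = nrow(library),
                  psm_records = nrow(records),
                  outliers_excluded = length(outlier_ids),
                  survivors = nrow(survivors),
                  candidates = nrow(report),
                  motif_members = length(motif_members)),
       file_digests = character(0))
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(library = file.path(out_dir, "library.tsv"),
             survivors = file.path(out_dir, "survivors.tsv"),
             report = file.path(out_dir, "candidate_report.tsv"),
             attribution = file.path(out_dir, "source_attribution.tsv"))
  write_library_tsv(run$library, paths["library"])
  utils::write.table(run$survivors, paths["survivors"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(run$report), paths["report"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$source_attribution, paths["attribution"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- run$manifest
  manifest$file_digests <- tools::md5sum(paths)
  manifest
}

#' Attribute candidates to their library sources
#'
#' Per-source candidate counts and hit rates
#' (`100 * candidates from source / library members from source`), the
#' bookkeeping behind source-distribution summaries of a screen.
#'
#' @param candidates data frame with a `library_id` column (one row per
#'   candidate phosphopeptide; peptides with several sites count once).
#' @param library library data frame with `library_id` and `source`.
#' @return data frame `source`, `library_members`, `candidates`,
#'   `hit_rate_percent`.
#' @export
attribute_sources <- function(candidates, library) {
  if (!all(candidates$library_id %in% library$library_id))
    stop("candidates must be a subset of the library")
  cand_ids <- unique(candidates$library_id)
  src_levels <- unique(library$source)
  lib_by_src <- table(factor(library$source, levels = src_levels))
  cand_src <- library$source[match(cand_ids, library$library_id)]
  cand_by_src <- table(factor(cand_src, levels = src_levels))
  data.frame(source = src_levels,
             library_members = as.integer(lib_by_src),
             candidates = as.integer(cand_by_src),
             hit_rate_percent = 100 * as.integer(cand_by_src) /
               pmax(as.integer(lib_by_src), 1L))
}

#' @export
print.kic_run <- function(x, ...) {
  cat("KiC screen run\n")
  cat("  library peptides:   ", x$manifest$counts[["library_size"]], "\n")
  cat("  outliers excluded:  ", x$manifest$counts[["outliers_excluded"]], "\n")
  cat("  derived criteria:    PSM >=", x$criteria$min_psm_count,
      ", Xcorr >", signif(x$criteria$min_xcorr, 4), "\n")
  cat("  surviving sites:    ", x$manifest$counts[["survivors"]], "\n")
  cat("  motif members:      ", x$manifest$counts[["motif_members"]], "\n")
  invisible(x)
}
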