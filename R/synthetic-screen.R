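# Synthetic 2x2 kinase screen: a toy proteome with planted phosphosites, a
# peptide library, and simulated PSM tables for the four conditions
# (wild type +/-ATP, kinase-dead +/-ATP) with known ground truth.

#' Configuration of a synthetic kinase-client screen
#'
#' The defaults emulate the screen geometry this pipeline targets: a
#' 225-peptide library of centered 20-mers, 46 genuine substrates with
#' strong, repeatedly sampled phospho-PSMs, and a sparse background of
#' spurious single-spectrum identifications in every sample at low Xcorr —
#' exactly the background that count- and Xcorr-based filtration criteria
#' are derived to remove.
#'
#' @param random_seed integer seed; all outputs are byte-identical for a
#'   fixed seed.
#' @param n_proteins number of synthetic proteins.
#' @param protein_length_range min/max protein length (residues).
#' @param n_library_peptides library size (default 225).
#' @param n_true_substrates number of planted substrates (default 46).
#' @param planted_motif optional list(`offsets`, `residues`, `n_sites`):
#'   residues written at the given offsets (relative to the phosphosite) in
#'   the first `n_sites` library windows.
#' @param signal_psm_rate Poisson mean of extra phospho-PSMs per true
#'   substrate (counts are `1 + Poisson(rate)`; default 4).
#' @param signal_xcorr mean/sd of true-substrate Xcorr (default 3.0, 0.4;
#'   truncated below at 0).
#' @param noise_rate per-peptide, per-sample probability of one spurious
#'   phospho-PSM (default 0.02).
#' @param noise_xcorr mean/sd of spurious Xcorr (default 1.7, 0.25).
#' @param planted_stoichiometry target phospho fraction per true substrate
#'   (default 0.75); unmodified PSM counts are chosen to match it.
#' @param include_ubiquitous_outlier plant one peptide whose phosphorylated
#'   form appears in all four samples (default FALSE).
#' @param aa_composition residue sampling weights (default uniform).
#' @return list of class `synthetic_screen_config`.
#' @export
synthetic_screen_config <- function(random_seed = 1L,
                                    n_proteins = 120L,
                                    protein_length_range = c(80L, 300L),
                                    n_library_peptides = 225L,
                                    n_true_substrates = 46L,
                                    planted_motif = NULL,
                                    signal_psm_rate = 4,
                                    signal_xcorr = c(3.0, 0.4),
                                    noise_rate = 0.02,
                                    noise_xcorr = c(1.7, 0.25),
                                    planted_stoichiometry = 0.75,
                                    include_ubiquitous_outlier = FALSE,
                                    aa_composition = NULL) {
  stopifnot(n_true_substrates <= n_library_peptides,
            noise_rate >= 0, noise_rate <= 1,
            planted_stoichiometry > 0, planted_stoichiometry <= 1,
            signal_psm_rate >= 0,
            length(protein_length_range) == 2L,
            protein_length_range[1] >= WINDOW_LENGTH,
            signal_xcorr[2] > 0, noise_xcorr[2] > 0)
  if (is.null(aa_composition))
    aa_composition <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  structure(list(random_seed = as.integer(random_seed),
                 n_proteins = as.integer(n_proteins),
                 protein_length_range = as.integer(protein_length_range),
                 n_library_peptides = as.integer(n_library_peptides),
                 n_true_substrates = as.integer(n_true_substrates),
                 planted_motif = planted_motif,
                 signal_psm_rate = signal_psm_rate,
                 signal_xcorr = signal_xcorr,
                 noise_rate = noise_rate,
                 noise_xcorr = noise_xcorr,
                 planted_stoichiometry = planted_stoichiometry,
                 include_ubiquitous_outlier = include_ubiquitous_outlier,
                 aa_composition = validate_background(aa_composition)),
            class = "synthetic_screen_config")
}

# normal truncated below at zero, via inverse-CDF so a fixed seed gives a
# fixed draw count
rtnorm_pos <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

SAMPLE_DESIGN <- data.frame(
  sample_id = c("WT_plusATP", "WT_minusATP", "dead_plusATP", "dead_minusATP"),
  enzyme_state = c("wildtype", "wildtype", "dead", "dead"),
  atp_state = c("plus", "minus", "plus", "minus"))

#' Generate a synthetic proteome, seed peptides, library and ground truth
#'
#' Proteins are i.i.d. residues at the configured composition. Library
#' windows are extracted around randomly placed S/T/Y sites with full
#' flanking context; when a motif is planted its residues are written into
#' the flanks of the first `n_sites` windows (and into the source protein,
#' so a string scan recovers them). Sources are assigned with the
#' 81:87:57 hmm/ml/experimental-control mix of the screen design.
#'
#' @param config a [synthetic_screen_config()].
#' @return list with `proteome` (named character vector), `seeds` (seed
#'   phosphopeptide data frame), `library` (library data frame) and `truth`
#'   (list: `true_substrate_ids`, `planted_site`, `planted_stoichiometry`,
#'   `outlier_id` or NA).
#' @export
generate_proteome_and_seeds <- function(config) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  motif <- config$planted_motif
  if (!is.null(motif)) {
    stopifnot(length(motif$offsets) == length(motif$residues))
    if (any(motif$offsets < -(DEFAULT_SITE_OFFSET - 1L)) ||
        any(motif$offsets > WINDOW_LENGTH - DEFAULT_SITE_OFFSET))
      stop("planted motif wider than the window flanks")
  }
  withr_seed(config$random_seed, {
    rng <- config$protein_length_range
    lens <- rng[1] + sample.int(rng[2] - rng[1] + 1L, config$n_proteins,
                                replace = TRUE) - 1L
    comp <- as.numeric(config$aa_composition)
    proteome <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = comp),
            collapse = "")
    }, character(1))
    names(proteome) <- sprintf("SYN%04d", seq_along(proteome))

    upstream <- DEFAULT_SITE_OFFSET - 1L
    downstream <- WINDOW_LENGTH - DEFAULT_SITE_OFFSET
    # place sites with full flanks; windows of distinct sites never overlap,
    # so planted residues cannot clobber another site's S/T/Y
    slots <- do.call(rbind, lapply(seq_along(proteome), function(i) {
      data.frame(protein = i,
                 position = seq(upstream + 1L, lens[i] - downstream))
    }))
    slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
    taken <- vector("list", length(proteome))
    sel <- integer(0)
    for (r in seq_len(nrow(slots))) {
      if (length(sel) == config$n_library_peptides) break
      p <- slots$protein[r]; pos <- slots$position[r]
      if (!any(abs(taken[[p]] - pos) < WINDOW_LENGTH)) {
        taken[[p]] <- c(taken[[p]], pos)
        sel <- c(sel, r)
      }
    }
    if (length(sel) < config$n_library_peptides)
      stop("proteome too small for the requested library size")
    pick <- slots[sel, , drop = FALSE]
    site_res <- sample(PHOSPHO_RESIDUES, nrow(pick), replace = TRUE)
    for (r in seq_len(nrow(pick))) {
      p <- pick$protein[r]; pos <- pick$position[r]
      s <- proteome[[p]]
      substr(s, pos, pos) <- site_res[r]
      if (!is.null(motif) && r <= motif$n_sites) {
        for (k in seq_along(motif$offsets)) {
          at <- pos + motif$offsets[k]
          substr(s, at, at) <- motif$residues[k]
        }
      }
      proteome[[p]] <- s
    }
    windows <- vapply(seq_len(nrow(pick)), function(r) {
      extract_window(proteome[[pick$protein[r]]], pick$position[r])$window
    }, character(1))

    n <- config$n_library_peptides
    src_mix <- c(hmm = 81, ml = 87, experimental_control = 57)
    counts <- round(src_mix / sum(src_mix) * n)
    counts[1] <- counts[1] + (n - sum(counts))
    source <- sample(rep(names(src_mix), times = counts))
    lib <- data.frame(library_id = seq_len(n),
                      accession = names(proteome)[pick$protein],
                      window = windows,
                      site_offset = DEFAULT_SITE_OFFSET,
                      source = source,
                      protein_position = pick$position)
    seeds <- data.frame(accession = lib$accession,
                        peptide = lib$window,
                        site_index = DEFAULT_SITE_OFFSET,
                        residue = substr(lib$window, DEFAULT_SITE_OFFSET,
                                         DEFAULT_SITE_OFFSET),
                        origin = "synthetic")

    true_ids <- sort(sample(lib$library_id, config$n_true_substrates))
    outlier_id <- NA_integer_
    if (config$include_ubiquitous_outlier) {
      pool <- setdiff(lib$library_id, true_ids)
      if (length(pool) == 0L) stop("no peptide left to serve as outlier")
      outlier_id <- sample(pool, 1L)
    }
    list(proteome = proteome, seeds = seeds, library = lib,
         truth = list(true_substrate_ids = true_ids,
                      planted_site = DEFAULT_SITE_OFFSET,
                      planted_stoichiometry = config$planted_stoichiometry,
                      outlier_id = outlier_id))
  })
}

#' Simulate the four PSM tables of a 2x2 kinase screen
#'
#' Wild type +ATP carries the signal: every true substrate receives
#' `1 + Poisson(signal_psm_rate)` phospho-PSMs (truncated-normal Xcorr,
#' site probability Uniform(0.9, 1)) plus enough unmodified PSMs that the
#' empirical phospho fraction matches the planted stoichiometry. Every
#' sample — including the three negative controls — gains spurious
#' single-spectrum phospho-PSMs per peptide with probability `noise_rate`
#' at low Xcorr and loosely localized sites. An optional ubiquitous outlier
#' peptide appears phosphorylated in all four samples at filter-passing
#' quality.
#'
#' @param config a [synthetic_screen_config()].
#' @param library library data frame from [generate_proteome_and_seeds()].
#' @param truth ground-truth list from the same call.
#' @return data frame of PSM records across the four samples (see
#'   [read_psm_table()] for the schema).
#' @export
simulate_psm_tables <- function(config, library, truth) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  if (!all(truth$true_substrate_ids %in% library$library_id))
    stop("ground truth inconsistent with the library")
  site <- truth$planted_site
  withr_seed(config$random_seed + 1L, {
    rows <- list()
    add <- function(sample_row, lid, n_phospho, xcorr, prob,
                    n_unmod = 0L, unmod_xcorr = NULL) {
      win <- library$window[library$library_id == lid]
      if (n_phospho > 0L)
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_id = sample_row$sample_id,
          enzyme_state = sample_row$enzyme_state,
          atp_state = sample_row$atp_state,
          library_id = lid, sequence = win, is_phospho = TRUE,
          site_positions = I(rep(list(site), n_phospho)),
          xcorr = xcorr, site_probability = prob)
      if (n_unmod > 0L)
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_id = sample_row$sample_id,
          enzyme_state = sample_row$enzyme_state,
          atp_state = sample_row$atp_state,
          library_id = lid, sequence = win, is_phospho = FALSE,
          site_positions = I(rep(list(integer(0)), n_unmod)),
          xcorr = unmod_xcorr, site_probability = NA_real_)
    }
    wt_plus <- SAMPLE_DESIGN[1, ]
    s <- config$planted_stoichiometry
    for (lid in truth$true_substrate_ids) {
      k <- 1L + stats::rpois(1L, config$signal_psm_rate)
      n_unmod <- as.integer(round(k * (1 - s) / s))
      add(wt_plus, lid,
          n_phospho = k,
          xcorr = rtnorm_pos(k, config$signal_xcorr[1], config$signal_xcorr[2]),
          prob = stats::runif(k, 0.9, 1),
          n_unmod = n_unmod,
          unmod_xcorr = if (n_unmod > 0L)
            rtnorm_pos(n_unmod, config$signal_xcorr[1], config$signal_xcorr[2]))
    }
    for (si in seq_len(nrow(SAMPLE_DESIGN))) {
      srow <- SAMPLE_DESIGN[si, ]
      hit <- stats::runif(nrow(library)) < config$noise_rate
      for (lid in library$library_id[hit]) {
        add(srow, lid, n_phospho = 1L,
            xcorr = rtnorm_pos(1L, config$noise_xcorr[1], config$noise_xcorr[2]),
            prob = stats::runif(1L, 0.3, 0.95))
      }
    }
    if (!is.na(truth$outlier_id)) {
      for (si in seq_len(nrow(SAMPLE_DESIGN))) {
        add(SAMPLE_DESIGN[si, ], truth$outlier_id, n_phospho = 2L,
            xcorr = rtnorm_pos(2L, 2.6, 0.2),
            prob = stats::runif(2L, 0.8, 1))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
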