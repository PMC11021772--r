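# The synthetic 2x2 screen generator: determinism, planted structure, and
# the statistical properties the downstream filters rely on.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_screen_config(random_seed = 5, n_proteins = 30,
                                 n_library_peptides = 40,
                                 n_true_substrates = 8)
  a <- generate_proteome_and_seeds(cfg)
  b <- generate_proteome_and_seeds(cfg)
  expect_identical(a, b)
  pa <- simulate_psm_tables(cfg, a$library, a$truth)
  pb <- simulate_psm_tables(cfg, b$library, b$truth)
  expect_identical(pa, pb)
  # and writing the proteome gives identical files
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a$proteome, f1); write_fasta(b$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_proteome_fasta(f1), a$proteome)
})

test_that("library windows are valid and anchored in the proteome", {
  cfg <- synthetic_screen_config(random_seed = 2, n_proteins = 40,
                                 n_library_peptides = 60,
                                 n_true_substrates = 10)
  gen <- generate_proteome_and_seeds(cfg)
  lib <- gen$library
  expect_identical(nrow(lib), 60L)
  expect_true(all(nchar(lib$window) == 20))
  expect_true(all(substr(lib$window, 10, 10) %in% c("S", "T", "Y")))
  # windows round-trip to their source proteins at the recorded positions
  for (r in sample(nrow(lib), 10)) {
    prot <- gen$proteome[[lib$accession[r]]]
    w <- extract_window(prot, lib$protein_position[r])
    expect_identical(w$window, lib$window[r])
  }
  expect_true(all(gen$truth$true_substrate_ids %in% lib$library_id))
})

test_that("a planted motif appears exactly where requested", {
  motif <- list(offsets = c(-3L, 2L), residues = c("D", "P"), n_sites = 10L)
  cfg <- synthetic_screen_config(random_seed = 9, n_proteins = 50,
                                 n_library_peptides = 30,
                                 n_true_substrates = 5,
                                 planted_motif = motif)
  gen <- generate_proteome_and_seeds(cfg)
  first10 <- gen$library$window[1:10]
  expect_true(all(substr(first10, 7, 7) == "D"))
  expect_true(all(substr(first10, 12, 12) == "P"))
  # string scan of the proteome finds at least the 10 planted co-occurrences
  planted <- vapply(1:10, function(i) {
    grepl(gen$library$window[i], gen$proteome[[gen$library$accession[i]]],
          fixed = TRUE)
  }, logical(1))
  expect_true(all(planted))
  # a motif wider than the flanks is impossible geometry
  expect_error(synthetic_screen_config(
    planted_motif = list(offsets = -15L, residues = "D", n_sites = 1L),
    n_proteins = 10) |> generate_proteome_and_seeds(), "wider")

  # fixed-length proteins come out at that length
  cfg50 <- synthetic_screen_config(random_seed = 1, n_proteins = 10,
                                   protein_length_range = c(50, 50),
                                   n_library_peptides = 10,
                                   n_true_substrates = 2)
  expect_true(all(nchar(generate_proteome_and_seeds(cfg50)$proteome) == 50))
})

test_that("zero noise leaves the negatives free of phospho-PSMs", {
  cfg <- synthetic_screen_config(random_seed = 3, n_proteins = 40,
                                 n_library_peptides = 50,
                                 n_true_substrates = 10, noise_rate = 0)
  gen <- generate_proteome_and_seeds(cfg)
  psm <- simulate_psm_tables(cfg, gen$library, gen$truth)
  negs <- psm[psm$enzyme_state == "dead" | psm$atp_state == "minus", ]
  expect_identical(sum(negs$is_phospho), 0L)
})

test_that("full stoichiometry substrates come out at exactly 100 percent", {
  cfg <- synthetic_screen_config(random_seed = 11, n_proteins = 40,
                                 n_library_peptides = 50,
                                 n_true_substrates = 12,
                                 planted_stoichiometry = 1.0)
  run <- run_screen_pipeline(cfg)
  recovered <- run$stoichiometry[
    run$stoichiometry$library_id %in% run$truth$true_substrate_ids, ]
  expect_true(nrow(recovered) > 0)
  expect_true(all(recovered$stoichiometry == 100))
})

test_that("the planted ubiquitous outlier is flagged, and only it", {
  cfg <- synthetic_screen_config(random_seed = 13, n_proteins = 40,
                                 n_library_peptides = 50,
                                 n_true_substrates = 10, noise_rate = 0,
                                 include_ubiquitous_outlier = TRUE)
  gen <- generate_proteome_and_seeds(cfg)
  psm <- simulate_psm_tables(cfg, gen$library, gen$truth)
  flagged <- flag_ubiquitous_outliers(per_sample_phospho_sets(psm))
  expect_identical(flagged, gen$truth$outlier_id)
})

test_that("empirical stoichiometry tracks the planted value at high signal", {
  errs <- c()
  for (seed in 1:5) {
    cfg <- synthetic_screen_config(random_seed = seed, n_proteins = 60,
                                   n_library_peptides = 80,
                                   n_true_substrates = 20,
                                   signal_psm_rate = 8,
                                   planted_stoichiometry = 0.6)
    run <- run_screen_pipeline(cfg)
    rec <- run$stoichiometry[
      run$stoichiometry$library_id %in% run$truth$true_substrate_ids, ]
    errs <- c(errs, abs(rec$stoichiometry - 60))
  }
  expect_lt(mean(errs), 10)
  expect_lt(stats::quantile(errs, 0.9), 10 + 1e-9)
})
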