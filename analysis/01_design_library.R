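#!/usr/bin/env Rscript
# Stage 1 — design a centered 20-mer peptide library from seed phosphopeptides.
#
# A synthetic proteome carries a conserved substrate family: 120 of its
# phosphosites share 8 fixed flanking residues, enough context for profile
# scanning yet diverse enough (~0.45 pairwise identity) to survive the >0.6
# similarity deduplication. Those sites seed the design. The stages mirror
# a real library build: flank filtering, >0.6 similarity deduplication,
# profile-HMM and KNN proteome scans, random positive-control sampling,
# and final assembly with source bookkeeping.

suppressPackageStartupMessages(library(kicscreen))
dir.create("results", showWarnings = FALSE)
set.seed(42)

cfg <- synthetic_screen_config(
  random_seed = 42, n_proteins = 150,
  planted_motif = list(
    offsets = c(-7L, -5L, -4L, -3L, -1L, 2L, 4L, 6L),
    residues = c("R", "K", "A", "D", "F", "P", "L", "G"),
    n_sites = 120L))
gen <- generate_proteome_and_seeds(cfg)
write_fasta(gen$proteome, "results/proteome.fasta")
cat("proteome:", length(gen$proteome), "proteins\n")

## seed pool: flank filter, then similarity deduplication at the 0.6 rule
seeds <- gen$seeds
keep <- filter_site_distance(seeds$peptide, seeds$site_index)
cat("seeds with full flanks:", sum(keep), "of", nrow(seeds), "\n")
seeds <- seeds[keep, ]
dedup <- deduplicate(seeds$peptide, threshold = 0.6)
seeds <- seeds[dedup$retained_index, ]
cat("after >0.6 similarity dedup:", nrow(seeds), "seed peptides\n")

## predictor 1: profile HMM over the seed windows, scanned at E < 0.001
model <- train_profile_hmm(seeds$peptide,
                           background = residue_frequencies(gen$proteome))
# tail-censored Gumbel fit: decoy scores of a windowed global model are
# normal-ish in the bulk, so the extreme tail (which E-values extrapolate)
# is fitted from the top quarter of the decoys
cal <- calibrate_evalues(model, n_decoys = 2000, random_seed = 43,
                         search_space_size = 5000, tail_fraction = 0.25)
hmm_hits <- scan_proteome(gen$proteome, model, threshold = 0.001,
                          calibration = cal)
cat("HMM hits at E < 0.001:", nrow(hmm_hits), "\n")

## predictor 2: KNN similarity scorer (negatives: non-seed S/T/Y windows)
all_sty <- scan_proteome(gen$proteome, model, threshold = Inf,
                         calibration = cal)
seed_keys <- paste(gen$library$accession, gen$library$protein_position)
neg_pool <- all_sty[!paste(all_sty$accession, all_sty$position) %in%
                      seed_keys, ]
negatives <- sample(neg_pool$window, min(300, nrow(neg_pool)))
knn <- build_knn_scorer(seeds$peptide, negatives)
ml_hits <- scan_proteome(gen$proteome, knn, threshold = 0.8)
cat("KNN hits at score > 0.8:", nrow(ml_hits), "\n")

## positive controls and assembly
controls <- sample_controls(seeds, n = min(57L, nrow(seeds)),
                            random_seed = 44)
lib <- assemble_library(hmm_hits[, c("accession", "window")],
                        ml_hits[, c("accession", "window")],
                        data.frame(accession = controls$accession,
                                   window = controls$peptide))
write_library_tsv(lib, "results/designed_library.tsv")
write_fasta(setNames(lib$window, paste0("pep", lib$library_id)),
            "results/designed_library.fasta")
cat("assembled library:", nrow(lib), "peptides (",
    paste(names(table(lib$source)), table(lib$source), collapse = ", "),
    ")\n")
cat("per-peptide concentration from a 5 mM stock:",
    round(1000 * pool_per_peptide_concentration(5, nrow(lib)), 1), "uM\n")
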