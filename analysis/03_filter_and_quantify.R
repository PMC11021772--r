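#!/usr/bin/env Rscript
# Stage 3 — derive filtration thresholds from the negative controls, call
# substrates in the wild-type +ATP condition, and quantify phosphorylation
# stoichiometry from spectral counts.

suppressPackageStartupMessages(library(kicscreen))

samples <- c("WT_plusATP", "WT_minusATP", "dead_plusATP", "dead_minusATP")
psm <- do.call(rbind, lapply(samples, function(s)
  read_psm_table(file.path("results", paste0("psm_", s, ".tsv")))))
lib <- read_library_tsv("results/screen_library.tsv")

## peptides phospho-detected in every sample are outliers: excluded first
outliers <- flag_ubiquitous_outliers(per_sample_phospho_sets(psm, samples))
cat("ubiquitous outlier peptide(s) excluded:",
    if (length(outliers)) paste(outliers, collapse = ", ") else "none", "\n")
psm <- psm[!psm$library_id %in% outliers, ]

## thresholds from the three negative controls
negatives <- psm[psm$enzyme_state == "dead" | psm$atp_state == "minus", ]
criteria <- derive_filter_thresholds(negatives)
print(criteria)
stopifnot(nrow(apply_filters(negatives, criteria)) == 0)
cat("sanity: criteria pass zero negative-control phosphopeptides\n")

## the test condition
test <- psm[psm$enzyme_state == "wildtype" & psm$atp_state == "plus", ]
survivors <- apply_filters(test, criteria)
stoich <- compute_stoichiometry(test, survivors)
write.table(stoich, "results/stoichiometry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("surviving phosphopeptide sites:", nrow(survivors), "\n")
cat("stoichiometry: ", sum(stoich$stoichiometry == 100),
    "sites at 100%,", sum(stoich$stoichiometry >= 50), "at >= 50%\n")

truth <- read.delim("results/ground_truth.tsv")
called <- unique(survivors$library_id)
cat(sprintf("recovery vs ground truth: precision %.3f, recall %.3f\n",
            mean(called %in% truth$true_substrate_id),
            mean(truth$true_substrate_id %in% called)))
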