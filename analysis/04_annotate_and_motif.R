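#!/usr/bin/env Rscript
# Stage 4 — annotate the surviving candidates (synthetic GO terms, weighted
# subcellular localization, phosphosite-database cross-reference) and search
# for a consensus motif after 90%-identity redundancy clustering.

suppressPackageStartupMessages(library(kicscreen))
set.seed(99)

lib <- read_library_tsv("results/screen_library.tsv")
stoich <- read.delim("results/stoichiometry.tsv")
surv_windows <- lib$window[match(stoich$library_id, lib$library_id)]
accs <- unique(lib$accession[match(stoich$library_id, lib$library_id)])

## synthetic annotation sources (stand-ins for GO/SUBA/P3DB/PhosPhAt exports,
## generated alongside the screen for a self-contained walkthrough)
compartments <- c("plasma membrane", "cytosol", "endoplasmic reticulum",
                  "nucleus", "mitochondrion")
loc <- data.frame(accession = rep(accs, each = 2),
                  compartment = sample(compartments, 2 * length(accs),
                                       replace = TRUE),
                  evidence_type = sample(c("experimental", "predicted"),
                                         2 * length(accs), replace = TRUE,
                                         prob = c(0.3, 0.7)))
go <- data.frame(accession = accs,
                 namespace = "molecular function",
                 term = sample(c("kinase activity", "ATP binding",
                                 "protein binding", "other"),
                               length(accs), replace = TRUE))
# one database knows a third of the candidate windows at the right site
known <- sample(seq_along(surv_windows), ceiling(length(surv_windows) / 3))
dbA <- data.frame(accession = paste0("DBA", known),
                  sequence = surv_windows[known], site_position = 10L)
databases <- list(
  p3db_like = dbA,
  phosphat_like = dbA[seq_len(floor(nrow(dbA) / 2)), ])

loc_calls <- call_localizations(loc, accs)
write.table(loc_calls, "results/localization_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("localization winners:\n")
print(table(loc_calls$compartment))

go_sum <- summarize_go_abundance(go, accs)
write.table(go_sum, "results/go_abundance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("GO classes above 1% abundance:", nrow(go_sum), "\n")

cand <- data.frame(library_id = stoich$library_id, window = surv_windows,
                   site_offset = 10L)
xref <- crossref_phospho_databases(cand, databases)
write.table(xref$status, "results/db_crossref.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("database cross-reference:\n")
print(xref$summary)

## motif: cluster at 90% identity, then positional binomial enrichment
cl <- cluster_redundant_peptides(surv_windows)
cat("redundancy clustering:", length(cl$representatives),
    "representatives from", length(surv_windows), "windows\n")
motif <- find_positional_motif(cl$representatives,
                               residue_frequencies(lib$window),
                               ids = stoich$library_id[cl$representative_index])
print(motif)
# this screen's substrates carry no planted flank motif, so any consensus
# beyond the centered phosphoacceptor reflects raw-p chance enrichment --
# the expected outcome under the <0.05 per-cell rule without correction
write.table(motif$cells[motif$cells$p_value < motif$alpha, ],
            "results/motif_cells.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
pfm <- position_frequency_matrix(cl$representatives)
write.table(round(pfm, 4), "results/motif_pfm.tsv", sep = "\t", quote = FALSE)
writeLines(paste(motif$member_ids, collapse = "\t"),
           "results/motif_members.tsv")
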