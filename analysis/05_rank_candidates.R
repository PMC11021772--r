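#!/usr/bin/env Rscript
# Stage 5 — rank candidates by the evidence hierarchy (stoichiometry, PSM
# count, subcellular localization priority, motif membership) and attribute
# them to their library sources.

suppressPackageStartupMessages(library(kicscreen))

lib <- read_library_tsv("results/screen_library.tsv")
stoich <- read.delim("results/stoichiometry.tsv")
loc_calls <- read.delim("results/localization_calls.tsv")
db_status_full <- read.delim("results/db_crossref.tsv")
motif_members <- as.integer(strsplit(readLines("results/motif_members.tsv"),
                                     "\t")[[1]])

report <- rank_candidates(
  stoich, lib,
  localization = data.frame(accession = loc_calls$accession,
                            compartment = loc_calls$compartment),
  motif_members = motif_members,
  db_status = data.frame(library_id = db_status_full$library_id,
                         status = db_status_full$status))
write.table(as.data.frame(report), "results/candidate_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("top candidates:\n")
print(head(as.data.frame(report)[, c("rank", "library_id", "stoichiometry",
                                     "phospho_psm_count", "localization",
                                     "in_consensus_motif", "source")], 8))

att <- attribute_sources(report, lib)
write.table(att, "results/source_attribution.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\ncandidates by library source:\n")
print(att)
stopifnot(sum(att$candidates) == length(unique(report$library_id)))
cat("\nreport written to results/candidate_report.tsv\n")
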