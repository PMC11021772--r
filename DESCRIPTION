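Package: kicscreen
Title: Kinase-Client Peptide Library Design and Substrate Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for kinase-client (KiC) assay screens against synthetic
    phosphopeptide libraries. Designs a centered 20-mer peptide library from
    prior phosphopeptides with two in-silico candidate generators (a linear
    profile hidden Markov model with Gumbel E-value calibration, and a
    BLOSUM62 k-nearest-neighbour phosphosite scorer), then calls substrates
    from peptide-spectrum-match tables using negative-control-derived
    filtration thresholds, quantifies phosphorylation stoichiometry from
    spectral counts, annotates candidates (GO class abundance, weighted
    subcellular localization, phosphosite-database cross-reference), detects
    consensus motifs by position-specific binomial enrichment, and ranks
    candidates. A synthetic 2x2 screen generator (active and kinase-dead
    enzyme, with and without ATP) with planted substrates makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
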