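---
title: "Kinase-client screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase-client screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kicscreen` implements the computational side of a kinase-client (KiC)
screen: a purified kinase is incubated with a pooled synthetic peptide
library, phosphorylation is read out by LC-MS/MS, and substrates are called
from peptide-spectrum-match (PSM) tables. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic screen generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## Library design

Candidate substrate peptides are fixed-length windows around a
phosphorylatable residue. Every window is 20 residues long with the
phosphosite at position 10, i.e. 9 upstream and 10 downstream flanking
residues. A 20-mer has no exact center, so the offset is a convention; we
fix it at 10 (configurable through `site_offset` arguments) and apply it
consistently in extraction, scanning, and motif offsets. Sites closer than
the required flank to a protein terminus are rejected rather than padded:
padding symbols would contaminate the position-specific models trained on
these windows.

Seed peptides from prior screens pass two filters before training:

* **Flank filter** (`filter_site_distance`): the phosphosite must lie at
  least 5 residues from either peptide end (`min_flank = 5`), so that a
  meaningful context window exists.
* **Similarity deduplication** (`deduplicate`): peptides with pairwise
  similarity strictly above 0.6 are collapsed. Similarity is defined as the
  identical-position fraction of an optimal global alignment (match +1,
  mismatch 0, affine gaps: opening 2, extension 0.5), normalized by the
  longer sequence. The choice is deliberate: it needs no substitution
  matrix, is symmetric, equals 1 only for identical sequences, and is
  reproducible from the definition alone. The greedy pass visits peptides
  in a deterministic order — experimentally observed peptides before
  predicted ones (via the `priority` argument), lexicographic within a
  tier — so experimentally supported representatives are the ones kept.

The final library concatenates profile-HMM hits, machine-learning hits and
randomly sampled positive controls, removing cross-source exact duplicates
with priority hmm > ml > control so that per-source attribution of later
screen results is stable. Pooling arithmetic is the trivial equal-volume
dilution: each peptide's concentration is the stock concentration divided
by the number of peptides pooled (5 mM pooled 225-way gives 22.2 uM).

## The two in-silico candidate generators

### Linear profile HMM

`train_profile_hmm` builds a classic match/insert/delete profile of length
20 from the center-aligned seed windows. Match emissions use additive
smoothing, `P_j(a) = (count_j(a) + c) / (n + 20c)` with pseudocount
`c = 1` by default. Because the training stack is gapless, only
match-to-match transitions are observed; a transition pseudocount (default
1) keeps insert/delete paths reachable but rare, and insert states emit the
background distribution. `forward_log_odds` scores a window as
`log2(P(window | model) / P(window | background))` using the full forward
sum over all state paths — not just the Viterbi path — and is verified in
the test suite against exhaustive path enumeration on small models. The
background defaults to the residue frequencies of the scanned proteome
(falling back to uniform 1/20), because scanning statistics should reflect
the searched database.

### E-value calibration

The screening rule keeps hits with E-value below 0.001. E-values require a
null score distribution; we estimate it by scoring decoy windows (residue
draws from the background, or shuffles of supplied windows) and fitting a
Gumbel distribution by maximum likelihood — the standard family for maxima
and local-alignment-type scores, and fully reproducible. Then
`E(s) = N * (1 - GumbelCDF(s))` for a search space of `N` windows.

One practical caveat is documented here deliberately: the forward score of
a fixed-length global model is a sum of ~20 per-position terms, so decoy
scores are close to normal in the bulk. A Gumbel fitted to the whole sample
then has a heavier-than-true upper tail and the resulting E-values are
conservative (planted signals of moderate strength may not reach E < 0.001
even when cleanly separated). `fit_gumbel(tail_fraction = f)` therefore
offers censored maximum likelihood on the top fraction `f` of the decoys —
left-censoring the rest at the cut point — which is consistent when the
null really is Gumbel and extrapolates the extreme tail far more faithfully
when it is not. The default remains the plain full-sample MLE; the analysis
scripts use `tail_fraction = 0.25` and say so.

### KNN similarity scorer

The deep-network phosphosite predictor used alongside the HMM in the
original screen cannot be retrained without its corpus. In its place —
and documented loudly as a stand-in — `build_knn_scorer` implements the
k-nearest-neighbour similarity feature at the core of classical phosphosite
predictors: similarity between two windows is the sum of position-wise
BLOSUM62 scores, and the prediction score of a query is the fraction of its
`k` nearest reference windows that are known sites (positives), giving a
score in [0, 1] on which the original 0.8 cutoff is retained. Negatives are
S/T/Y windows from the same proteins not known to be phosphorylated. No
published value of `k` exists for this setting; the default
`k = min(15, 3 * floor(sqrt(n_references)))` scales with reference count
and is configurable. Distance ties are broken by reference rank in a fixed
sorted order (positives first, lexicographic within label) so scores are
order-invariant and reproducible.

`scan_proteome` applies either model to every S/T/Y residue with full
flanks, scoring each window exactly once, and sorts hits by significance
then coordinates.

## PSM filtration from negative controls

The screen's 2x2 design (wild-type / kinase-dead enzyme, with / without
ATP) gives three negative controls in which every phosphopeptide
identification is by construction a false positive. `derive_filter_thresholds`
turns that into filtration criteria:

* `min_xcorr` = the maximum Xcorr over all negative phospho-PSMs, applied
  strictly (`xcorr > min_xcorr`), so the worst negative offender itself
  fails;
* `min_psm_count` = one more than the largest per-peptide phospho-PSM
  count in any single negative sample;
* `min_site_probability` (default 0.75) is *not* derived: the original
  rule was a site-localization tool flag with no printed cutoff, so a
  conventional localization threshold is used and exposed as a parameter.

Re-applying derived criteria to the negatives passes zero phosphopeptides
by construction; the test suite asserts this over 100 simulated screens. A
peptide whose phosphorylated form appears in *every* sample (negatives
included) cannot be kinase-dependent signal — serine-rich sequences that
defeat site localization are the usual culprit — and is excluded from all
analyses. The pipeline flags and removes such ubiquitous outliers *before*
deriving thresholds: an outlier present in negatives at passing quality
would otherwise inflate `min_xcorr`/`min_psm_count` and cost sensitivity.
Multiply phosphorylated PSMs contribute one observation to each listed
site, so per-site bookkeeping survives into quantification.

## Stoichiometry and ranking

For each surviving (peptide, site), stoichiometry is
`100 * phospho PSM count / total PSM count`, with the denominator counting
all PSMs of that peptide sequence — phosphorylated at any site plus
unmodified — within the test condition (wild type + ATP) only; negatives
define background, not abundance. A peptide never observed unmodified
scores exactly 100%.

Candidates are ranked lexicographically: stoichiometry, then phospho-PSM
count, then subcellular-localization priority (plasma membrane > cytosol >
endoplasmic reticulum > nucleus > other compartments — the order expected
for substrates of a plasma-membrane receptor kinase), then consensus-motif
membership, with ascending library id as the final tiebreak so the order is
total and runs are reproducible. A weighted sum was rejected because the
evidence is hierarchical and no defensible weights exist; database-known
status is reported but deliberately excluded from the sort key, since both
novel and database-confirmed candidates are of interest for different
reasons.

## Annotation

GO class abundance is reported per namespace as the percentage of
annotation *assignments* (not proteins) in each class, so percentages sum
to 100 within a namespace before the strict >1% display cutoff; proteins
without annotation enter as an explicit "unannotated" class. Subcellular
localization follows the weighted-consensus convention of curated plant
localization databases: each compartment scores
`5 * experimental observations + 1 * predictions`, the highest score wins,
and ties resolve by the same fixed compartment priority with a flag.
Database cross-reference replaces a BLASTP search at 100% identity and full
coverage with exact substring matching — mathematically equivalent at that
operating point and dependency-free. A candidate window is *confirmed* in a
database only when the window occurs verbatim and the database lists a
phosphosite at the aligned position; verbatim occurrence without the
aligned site is reported separately as *sequence-only* rather than merged,
because the two readings support different claims of novelty.

## Motif detection

Candidate windows are first redundancy-reduced by greedy clustering at 90%
identity (18 of 20 matching positions, inclusive), visiting windows in
input order; every member is at least 90% identical to its representative.
Because all windows are center-aligned on the phosphosite by construction,
de novo alignment-searching motif discovery (expectation-maximization over
offsets) is unnecessary machinery: position-specific enrichment is the
standard approach in this regime and replaces the EM tool used originally.
For every offset and residue, a one-sided exact binomial test compares the
observed count among representatives to the background frequency (default:
residue frequencies over the whole library; configurable to proteome
frequencies). Cells with raw p < 0.05 are significant — the original
rule — and Bonferroni-adjusted values are reported alongside. The reported
motif is confined to the contiguous offset window of width at most 5 with
the strongest combined significance (sum over offsets of the best
significant cell's -log10 p); the consensus takes the most enriched residue
per significant offset, and members are the windows matching the full
consensus.

Exact one-sided binomial tests are discrete: at a nominal level of 0.05 the
attained per-cell false-positive rate is the largest achievable tail
probability below 0.05 (for example 0.0195 at n = 12 representatives and a
background frequency of 1/20), never 0.05 itself. The test suite therefore
checks type-I *control* — the observed rate matches the closed-form
attained level and never exceeds the nominal alpha — rather than equality
with alpha, which no exact test can deliver.

## The synthetic screen generator

`synthetic_screen_config` fixes the simulated study conditions. Defaults:
225 library peptides, 46 true substrates, signal phospho-PSM counts
`1 + Poisson(4)` with Xcorr ~ Normal(3.0, 0.4) truncated at zero and site
probability Uniform(0.9, 1); spurious identifications arrive independently
per peptide and sample with probability 0.02 as single PSMs with Xcorr ~
Normal(1.7, 0.25) and loosely localized sites (probability Uniform(0.3,
0.95)). The noise model is deliberately matched to what the filtration
criteria remove: low-scoring singletons. It makes the criteria *necessary*
(noise is present in every sample) and *sufficient* (signal is separable),
which is exactly the property the negative-control design exploits.
Remaining defaults are our own choices where nothing was prescribed: 120
proteins of 80-300 residues with i.i.d. uniform composition (large enough
to host the library with non-overlapping windows, small enough for
second-scale tests), planted per-substrate stoichiometry 0.75 (a strong
but not saturated substrate, so both the numerator and denominator of the
statistic are exercised), and truncated-normal Xcorr rather than a
decoy-score model because only the ordering relative to the thresholds
matters downstream.

Unmodified PSM counts are chosen as `round(k * (1 - s) / s)` for `k`
phospho-PSMs and planted stoichiometry `s`, so the empirical phospho
fraction converges to `s` as counts grow; at `signal_psm_rate = 8` the
per-substrate recovery error is within a few percentage points. Site
windows of distinct library peptides never overlap in the synthetic
proteome, so planted motif residues cannot corrupt another site's context.

What the generator does *not* emulate: spectrum-level structure (m/z
peaks, charge states, retention time), peptide-specific detectability and
ionization efficiency, search-engine score correlations between samples,
shared-sequence ambiguity between library members, and biological
correlation between substrates. Passing the recovery tests therefore
demonstrates that the pipeline's logic is correct under its stated noise
model, not that real screens achieve these precision/recall figures.

## Problem sizes and numerical choices

The test and acceptance workloads use the default screen design (225
peptides, 46 substrates) with 20-100 seeded replicates per property, toy
models of up to 3 positions for exact path-enumeration checks, and decoy
samples of 500-10,000 for calibration checks; these sizes give stable
statistics at desk scale. Forward scores are computed in log space with a
numerically stable log-sum-exp; emission and transition rows are validated
to sum to 1 within 1e-9; degenerate inputs (constant decoy scores, empty
training sets, empty candidate sets, zero-length flanks) raise immediate
errors rather than propagating NaNs. All randomness flows through explicit
seeds, and a fixed configuration reproduces byte-identical outputs,
including on-disk TSVs.

## Known limitations

* The profile HMM scores fixed windows globally; it does not implement
  local/glocal alignment modes or multi-domain scoring, so its E-values are
  not comparable to those of general-purpose homology search tools.
* The KNN scorer is a transparent stand-in for a deep-network predictor;
  its 0-1 score shares the cutoff convention but not the learned feature
  space of the original.
* Upstream search-engine FDR control is accepted as given in the PSM
  tables and never recomputed.
* With raw per-cell p-values (the original rule), a motif search over 400
  cells expects ~8 chance-significant cells under the null; the Bonferroni
  column is provided for users who want family-wise control.
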