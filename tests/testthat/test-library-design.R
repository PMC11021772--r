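# Library design: window extraction, flank filtering, similarity
# deduplication, control sampling, pooling arithmetic.

test_that("extract_window centers the phosphosite and rejects short flanks", {
  # a 20-aa protein with the site at position 10 is its own window
  prot20 <- paste0(strrep("A", 9), "S", strrep("G", 10))
  w <- extract_window(prot20, 10)
  expect_identical(w$window, prot20)
  expect_identical(w$site_offset, 10L)

  # 40-aa protein, site at 20 -> residues 11..30 (manual index arithmetic)
  set.seed(11)
  prot40 <- paste(sample(c("A", "G", "L", "V"), 40, replace = TRUE),
                  collapse = "")
  substr(prot40, 20, 20) <- "T"
  w <- extract_window(prot40, 20)
  expect_identical(w$window, substr(prot40, 11, 30))
  expect_identical(substr(w$window, 10, 10), "T")
  expect_identical(c(w$start, w$end), c(11L, 30L))
  # round-trip: the window occurs in the protein at the recorded coordinates
  expect_identical(regexpr(w$window, prot40, fixed = TRUE)[1], 11L)

  # only 4 upstream residues -> rejection, not padding
  prot30 <- paste0("AAAA", "S", strrep("G", 25))
  expect_error(extract_window(prot30, 5), "upstream")
  # non-S/T/Y site and out-of-range index
  expect_error(extract_window(prot40, 11), "S/T/Y")
  expect_error(extract_window(prot20, 99), "bounds")
})

test_that("filter_site_distance keeps sites at least five residues from ends", {
  expect_true(filter_site_distance("ALKVQSGHKDLM", 6))    # 5 before, 6 after
  expect_false(filter_site_distance("ALSKVQGHKD", 3))     # 2 before
  expect_true(filter_site_distance("ALKVQSGHKDL", 6))     # exactly 5 each side
  expect_false(filter_site_distance("ALKVQSGHKD", 6))     # only 4 after
})

test_that("pairwise_similarity is the identity fraction of a global alignment", {
  a <- "ASDFGHKLQWERTYPCVNML"
  expect_equal(pairwise_similarity(a, a), 1.0)
  # 20-mers differing at 8 positions, no indels -> 12/20 = 0.60
  b <- a
  for (i in c(1, 3, 5, 7, 9, 11, 13, 15))
    substr(b, i, i) <- if (substr(a, i, i) == "G") "W" else "G"
  expect_equal(pairwise_similarity(a, b), 0.60)
  # disjoint alphabets share nothing
  expect_equal(pairwise_similarity(strrep("A", 10), strrep("G", 10)), 0.0)
  # symmetry, and normalization by the longer sequence
  x <- "ACDEFGHIKL"; y <- "ACDEFGHIKLMNP"
  expect_equal(pairwise_similarity(x, y), pairwise_similarity(y, x))
  expect_equal(pairwise_similarity(x, y), 10 / 13)
  expect_error(pairwise_similarity("", x))
})

test_that("deduplicate keeps strict-threshold survivors in greedy order", {
  # identical peptides collapse to one
  expect_length(deduplicate(c("ACDEFGHIKL", "ACDEFGHIKL"))$retained, 1L)

  # pair at exactly 0.60 similarity: both retained (strict >)
  a <- "ASDFGHKLQWERTYPCVNML"
  b <- a
  for (i in c(1, 3, 5, 7, 9, 11, 13, 15))
    substr(b, i, i) <- if (substr(a, i, i) == "G") "W" else "G"
  expect_equal(pairwise_similarity(a, b), 0.60)
  expect_length(deduplicate(c(a, b))$retained, 2L)

  # greedy trace: A~B 0.8 drops B, A~C and B~C low keep C
  A <- "AAAAAAAAAACCCCCCCCCC"
  B <- "AAAAAAAAAACCCCCCDDDD"   # 16/20 = 0.8 to A
  C <- "WWWWWWWWWWYYYYYYYYYY"   # 0 to both
  expect_equal(pairwise_similarity(A, B), 0.8)
  got <- deduplicate(c(A, B, C), priority = c(1, 2, 3))
  expect_setequal(got$retained, c(A, C))

  # property: retained set has max pairwise similarity <= threshold,
  # against a brute-force all-pairs oracle
  set.seed(42)
  base <- random_windows(8, 12)
  variants <- unlist(lapply(base, function(w) {
    v <- w; substr(v, 2, 2) <- "A"; c(w, v)
  }))
  kept <- deduplicate(variants, threshold = 0.6)$retained
  expect_lte(oracle_max_pairwise_similarity(kept), 0.6)
})

test_that("assemble_library concatenates sources with priority and validation", {
  set.seed(5)
  mk <- function(n) vapply(seq_len(n), function(i) {
    w <- random_windows(1, 20)
    substr(w, 10, 10) <- sample(c("S", "T", "Y"), 1)
    w
  }, character(1))
  hmm <- mk(81); ml <- mk(87); ctrl <- mk(57)
  lib <- assemble_library(hmm, ml, ctrl)
  expect_identical(nrow(lib), 225L)
  expect_identical(lib$library_id, 1:225)
  expect_identical(as.vector(table(lib$source)[c("hmm", "ml",
                                                 "experimental_control")]),
                   c(81L, 87L, 57L))
  # every window is a valid 20-mer with S/T/Y at the fixed offset
  expect_true(all(nchar(lib$window) == 20))
  expect_true(all(substr(lib$window, 10, 10) %in% c("S", "T", "Y")))

  # empty inputs -> empty library
  expect_identical(nrow(assemble_library(character(0), character(0),
                                         character(0))), 0L)

  # a window in both hmm and ml counts once, attributed to hmm
  shared <- hmm[1]
  lib2 <- assemble_library(c(shared), c(shared, ml[1]), character(0))
  expect_identical(nrow(lib2), 2L)
  expect_identical(lib2$source[lib2$window == shared], "hmm")

  # malformed windows are rejected with offender positions
  expect_error(assemble_library(substr(hmm[1], 1, 19), character(0),
                                character(0)), "malformed")
})

test_that("sample_controls is a reproducible uniform subsample", {
  pool <- random_windows(10, 20)
  expect_setequal(sample_controls(pool, 10, random_seed = 3), pool)
  expect_identical(sample_controls(pool, 5, random_seed = 7),
                   sample_controls(pool, 5, random_seed = 7))
  expect_error(sample_controls(pool, 11, random_seed = 1), "cannot sample")

  # inclusion frequency of 5-from-10 over many resamples is ~0.5
  hits <- numeric(10)
  for (s in 1:1000) {
    drawn <- sample_controls(pool, 5, random_seed = s)
    hits <- hits + pool %in% drawn
  }
  expect_true(all(abs(hits / 1000 - 0.5) < 0.05))
})

test_that("merge_seed_pools combines screens and validates site residues", {
  p1 <- data.frame(accession = "P1", peptide = "ALKVQSGHKDLM",
                   site_index = 6L, residue = "S", origin = "P2K1")
  p2 <- data.frame(accession = "P2", peptide = "GGGGGTGGGGG",
                   site_index = 6L, residue = "T", origin = "P2K2")
  merged <- merge_seed_pools(p1, p2)
  expect_identical(nrow(merged), 2L)
  expect_setequal(merged$origin, c("P2K1", "P2K2"))
  p_bad <- p1; p_bad$residue <- "Y"
  expect_error(merge_seed_pools(p_bad), "does not match")
})

test_that("pool dilution follows equal-volume arithmetic", {
  # 5 mM stock pooled 225-way -> 22.2 uM per peptide
  expect_equal(round(1000 * pool_per_peptide_concentration(5, 225), 1), 22.2)
  expect_equal(pool_per_peptide_concentration(3.7, 1), 3.7)
  expect_equal(pool_per_peptide_concentration(5, 100), 0.05)
  # scale invariance: doubling the stock doubles the output
  expect_equal(pool_per_peptide_concentration(10, 225),
               2 * pool_per_peptide_concentration(5, 225))
  expect_error(pool_per_peptide_concentration(5, 0), "positive")
})
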