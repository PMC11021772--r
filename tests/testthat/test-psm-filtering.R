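# PSM ingestion, negative-control threshold derivation, the three-part
# filtration rule, and ubiquitous-outlier flagging.

test_that("PSM tables round-trip through write/read with validation", {
  rec <- rbind(
    psm_rows("WT_plusATP", "wildtype", "plus", 1:5, TRUE,
             xcorr = c(2.5, 2.6, 3.0, 1.9, 2.2), site_probability = 0.99),
    psm_rows("WT_plusATP", "wildtype", "plus", 1:5, FALSE,
             xcorr = c(1.5, 1.6, 2.0, 0.9, 1.2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(rec, path)
  back <- read_psm_table(path)
  expect_identical(nrow(back), 10L)
  expect_equal(back$xcorr, rec$xcorr)
  expect_identical(back$library_id, rec$library_id)
  expect_identical(unclass(back$site_positions), unclass(rec$site_positions))
  expect_identical(nrow(attr(back, "rejected")), 0L)

  # header-only file -> empty table
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("sample_id", "enzyme_state", "atp_state", "library_id",
                     "sequence", "is_phospho", "site_positions", "xcorr",
                     "site_probability"), collapse = "\t"), empty)
  expect_identical(nrow(read_psm_table(empty)), 0L)

  # a phospho row without site positions violates the invariant
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("sample_id", "enzyme_state", "atp_state", "library_id",
                       "sequence", "is_phospho", "site_positions", "xcorr",
                       "site_probability"), collapse = "\t"),
               "s1\twildtype\tplus\t1\tAAAS\tTRUE\t\t2.5\t0.9",
               "s1\twildtype\tplus\t2\tAAAS\tTRUE\t4\t2.5\t1.7"), bad)
  got <- read_psm_table(bad)
  expect_identical(nrow(got), 0L)
  rej <- attr(got, "rejected")
  expect_identical(nrow(rej), 2L)
  expect_match(rej$reason[1], "without site positions")
  expect_match(rej$reason[2], "outside \\[0,1\\]")

  # a missing column is a schema error
  noxc <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tenzyme_state", noxc)
  expect_error(read_psm_table(noxc), "missing column")
})

test_that("thresholds derived from negatives reproduce the screen criteria", {
  # worst negative phospho-PSM: Xcorr 2.04 seen once -> (PSM >= 2, Xcorr > 2.04)
  negs <- rbind(
    psm_rows("dead_plusATP", "dead", "plus", 1:3, TRUE,
             xcorr = c(2.04, 1.7, 1.2), site_probability = 0.9),
    psm_rows("WT_minusATP", "wildtype", "minus", 4, TRUE,
             xcorr = 1.5, site_probability = 0.85),
    psm_rows("dead_minusATP", "dead", "minus", 5, FALSE, xcorr = 1.0))
  crit <- derive_filter_thresholds(negs)
  expect_identical(crit$min_psm_count, 2L)
  expect_equal(crit$min_xcorr, 2.04)

  # vacuous background: no phospho-PSMs at all
  clean <- psm_rows("dead_plusATP", "dead", "plus", 1:4, FALSE, xcorr = 1)
  crit0 <- derive_filter_thresholds(clean)
  expect_identical(crit0$min_psm_count, 1L)
  expect_equal(crit0$min_xcorr, 0)
  expect_error(derive_filter_thresholds(clean[0, ]), "no negative")
})

test_that("derived criteria always exclude the negatives that defined them", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:40, 1)
    negs <- psm_rows("dead_plusATP", "dead", "plus",
                     library_id = sample(1:20, n, replace = TRUE),
                     is_phospho = stats::runif(n) < 0.7,
                     xcorr = stats::rexp(n, 1 / 2),
                     site_probability = stats::runif(n))
    negs$site_probability[!negs$is_phospho] <- NA_real_
    crit <- derive_filter_thresholds(negs, min_site_probability = 0)
    expect_identical(nrow(apply_filters(negs, crit)), 0L)
  }
})

test_that("the three-part rule is enforced part by part", {
  crit <- filter_criteria(2L, 2.04, 0.75)
  one <- psm_rows("WT_plusATP", "wildtype", "plus", 1, TRUE,
                  xcorr = 3.0, site_probability = 0.99)
  expect_identical(nrow(apply_filters(one, crit)), 0L)  # count 1 < 2

  two <- psm_rows("WT_plusATP", "wildtype", "plus", c(1, 1), TRUE,
                  xcorr = c(2.5, 2.6), site_probability = 0.99)
  expect_identical(nrow(apply_filters(two, crit)), 1L)

  # Xcorr exactly at the bound fails: the bound is strict
  border <- psm_rows("WT_plusATP", "wildtype", "plus", c(1, 1), TRUE,
                     xcorr = c(2.04, 2.04), site_probability = 0.99)
  expect_identical(nrow(apply_filters(border, crit)), 0L)

  # poorly localized sites fail on the probability criterion
  fuzzy <- psm_rows("WT_plusATP", "wildtype", "plus", c(1, 1), TRUE,
                    xcorr = c(2.5, 2.6), site_probability = 0.5)
  expect_identical(nrow(apply_filters(fuzzy, crit)), 0L)

  # monotone: raising any threshold never adds survivors
  set.seed(8)
  n <- 60
  recs <- psm_rows("WT_plusATP", "wildtype", "plus",
                   library_id = sample(1:15, n, replace = TRUE),
                   is_phospho = TRUE,
                   xcorr = stats::rexp(n, 1 / 2.5),
                   site_probability = stats::runif(n))
  base <- apply_filters(recs, crit)
  for (stricter in list(filter_criteria(3, 2.04, 0.75),
                        filter_criteria(2, 2.5, 0.75),
                        filter_criteria(2, 2.04, 0.9))) {
    sub <- apply_filters(recs, stricter)
    expect_true(all(paste(sub$library_id, sub$site) %in%
                      paste(base$library_id, base$site)))
  }
  # row order never matters
  shuf <- recs[sample(nrow(recs)), ]
  expect_identical(apply_filters(shuf, crit), base)
})

test_that("multi-site PSMs contribute one observation per listed site", {
  rec <- data.frame(sample_id = "WT_plusATP", enzyme_state = "wildtype",
                    atp_state = "plus", library_id = 7L,
                    sequence = paste0(strrep("A", 9), "ST",
                                      strrep("A", 9)),
                    is_phospho = TRUE,
                    site_positions = I(list(c(10L, 11L), c(10L, 11L))),
                    xcorr = c(2.8, 2.9), site_probability = c(0.95, 0.97))
  got <- apply_filters(rec, filter_criteria(2, 2.04, 0.75))
  expect_identical(got$site, c(10L, 11L))
  expect_identical(got$psm_count, c(2L, 2L))
})

test_that("only peptides phospho-detected in every sample are flagged", {
  sets <- list(WT_plusATP = c(1L, 2L, 3L), WT_minusATP = c(1L, 3L),
               dead_plusATP = c(1L, 3L), dead_minusATP = c(1L, 9L))
  expect_identical(flag_ubiquitous_outliers(sets), 1L)   # 3 misses one sample
  sets$dead_minusATP <- c(9L)
  expect_identical(flag_ubiquitous_outliers(sets), integer(0))
  expect_error(flag_ubiquitous_outliers(sets[1]), "two samples")
})
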