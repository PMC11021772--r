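# Profile HMM: training counts, forward recursion vs exhaustive path
# enumeration, maximum-likelihood property, Gumbel E-value calibration.

test_that("training emissions follow the smoothed count formula", {
  # single window, zero pseudocount: probability 1 at each observed residue
  m <- train_profile_hmm("ACDY", pseudocount = 0)
  for (j in 1:4) {
    res <- substr("ACDY", j, j)
    expect_equal(unname(m$match_emissions[j, res]), 1.0)
  }
  # two windows, pseudocount 1, both A at a position -> (2+1)/(2+20)
  m2 <- train_profile_hmm(c("AC", "AG"), pseudocount = 1)
  expect_equal(unname(m2$match_emissions[1, "A"]), 3 / 22)
  expect_equal(unname(m2$match_emissions[2, "C"]), 2 / 22)
  expect_error(train_profile_hmm(character(0)), "empty")
  expect_error(train_profile_hmm(c("AC", "ACD")), "equal length")
})

test_that("emission and transition rows stay normalized for random inputs", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(2:30, 1)
    L <- sample(3:12, 1)
    m <- train_profile_hmm(random_windows(n, L),
                           pseudocount = stats::runif(1, 0, 2))
    expect_equal(rowSums(m$match_emissions), rep(1, L), tolerance = 1e-9)
    tr <- m$transitions
    for (j in seq_len(L + 1)) {
      expect_equal(tr$MM[j] + tr$MI[j] + tr$MD[j], 1, tolerance = 1e-9)
      expect_equal(tr$IM[j] + tr$II[j], 1, tolerance = 1e-9)
      expect_equal(tr$DM[j] + tr$DD[j], 1, tolerance = 1e-9)
    }
    # gapless training keeps match-to-match dominant
    expect_true(all(tr$MM > tr$MI & tr$MM > tr$MD))
  }
  # a uniform random training set of 1000 windows is close to uniform 1/20
  big <- train_profile_hmm(random_windows(1000, 6), pseudocount = 1)
  expect_true(all(abs(big$match_emissions - 1 / 20) < 0.05))
})

test_that("forward log-odds equals exhaustive path enumeration on toy models", {
  set.seed(7)
  for (L in 2:3) {
    for (n in 2:3) {
      train <- random_windows(3, L, alphabet = c("A", "C"))
      m <- train_profile_hmm(train, pseudocount = 0.5)
      for (rep in 1:3) {
        w <- random_windows(1, n, alphabet = c("A", "C", "G"))
        expect_equal(forward_log_odds(m, w), oracle_forward_bits(m, w),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("a background-equal model scores zero bits everywhere", {
  bg <- stats::setNames(rep(1 / 20, 20), AA20)
  m <- train_profile_hmm(random_windows(5, 4), pseudocount = 1)
  m$match_emissions[] <- 1 / 20     # flatten to the background
  # match emissions equal background and indel paths carry the remaining
  # probability mass; with emissions == background the log-odds reduces to
  # log2 of the total path probability mass, which must not depend on the
  # window residues
  set.seed(1)
  scores <- forward_log_odds(m, random_windows(20, 4))
  expect_equal(diff(range(scores)), 0, tolerance = 1e-9)
  # with indel paths switched off the score is exactly zero bits
  m$transitions$MM[] <- 1
  m$transitions$MI[] <- 0
  m$transitions$MD[] <- 0
  expect_equal(max(abs(forward_log_odds(m, random_windows(20, 4)))), 0,
               tolerance = 1e-9)
})

test_that("a window is its own maximum-likelihood match", {
  set.seed(13)
  w <- random_windows(1, 8)
  m <- train_profile_hmm(w, pseudocount = 0)
  own <- forward_log_odds(m, w)
  others <- forward_log_odds(m, random_windows(50, 8))
  expect_true(all(own >= others))
})

test_that("Gumbel MLE recovers known parameters and E-values are monotone", {
  set.seed(2024)
  x <- rgumbel(10000, location = 0, scale = 1)
  fit <- fit_gumbel(x)
  expect_lt(abs(fit$location), 0.1)
  expect_lt(abs(fit$scale - 1), 0.1)
  expect_error(fit_gumbel(rep(1, 100)), "degenerate")

  # censored tail fitting stays consistent on genuinely Gumbel data
  tf <- fit_gumbel(x, tail_fraction = 0.3)
  expect_lt(abs(tf$location), 0.1)
  expect_lt(abs(tf$scale - 1), 0.1)
  # ... and tracks the upper tail, not the bulk, under misspecification:
  # for a normal sample the censored fit assigns less mass far out than
  # the full-sample fit, whose Gumbel tail is too heavy
  z <- stats::rnorm(10000)
  full <- fit_gumbel(z)
  tail <- fit_gumbel(z, tail_fraction = 0.2)
  far <- 6
  expect_lt(pgumbel(far, tail$location, tail$scale, lower.tail = FALSE),
            pgumbel(far, full$location, full$scale, lower.tail = FALSE))

  m <- train_profile_hmm(random_windows(30, 6), pseudocount = 1)
  cal <- calibrate_evalues(m, n_decoys = 500, random_seed = 5,
                           search_space_size = 1e4)
  s <- seq(-10, 20, length.out = 50)
  expect_true(all(diff(evalue(cal, s)) <= 0))

  # E at the sample median ~ half the search space (CDF-median identity,
  # checked where the null really is Gumbel)
  gfit <- fit_gumbel(x)
  cal_g <- structure(list(gumbel_location = gfit$location,
                          gumbel_scale = gfit$scale,
                          decoy_count = length(x),
                          search_space_size = 1e4),
                     class = "evalue_calibration")
  e_med <- evalue(cal_g, stats::median(x))
  expect_lt(abs(e_med - 5e3) / 5e3, 0.10)
})

test_that("trained windows score better than their shuffles", {
  set.seed(31)
  # a conserved motif family: one consensus with light mutation
  consensus <- random_windows(1, 12)
  fam <- vapply(1:40, function(i) {
    w <- consensus
    for (pos in sample(12, 2)) substr(w, pos, pos) <- sample(AA20, 1)
    w
  }, character(1))
  m <- train_profile_hmm(fam, pseudocount = 0.3)
  shuffled <- vapply(fam, function(w) {
    paste(sample(strsplit(w, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  cal <- calibrate_evalues(m, n_decoys = 300, random_seed = 9,
                           search_space_size = 1000)
  expect_lt(stats::median(evalue(cal, forward_log_odds(m, fam))),
            stats::median(evalue(cal, forward_log_odds(m, shuffled))))
})
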