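# Linear profile hidden Markov model over phosphosite windows: training from
# a gapless center-aligned stack of 20-mers, forward-algorithm log-odds
# scoring against a residue background, and E-value calibration by fitting a
# Gumbel distribution to shuffled-decoy scores.

#' Train a linear profile HMM from center-aligned windows
#'
#' Builds a match/insert/delete profile of the same length as the (gapless,
#' equal-length) training windows. Match emissions use additive smoothing:
#' at position j, `P(a) = (count_j(a) + pseudocount) / (n + 20 * pseudocount)`.
#' Insert states emit the background distribution. Because the training
#' alignment is gapless, only match-to-match transitions are observed;
#' the transition pseudocount keeps insert/delete paths reachable but rare.
#'
#' @param windows character vector of equal-length amino-acid windows.
#' @param pseudocount emission pseudocount (default 1).
#' @param background named length-20 residue distribution; defaults to
#'   uniform 1/20.
#' @param transition_pseudocount pseudocount per outgoing transition
#'   (default 1).
#' @return object of class `profile_hmm`.
#' @export
train_profile_hmm <- function(windows, pseudocount = 1,
                              background = NULL,
                              transition_pseudocount = 1) {
  if (length(windows) == 0L) stop("empty training set")
  stopifnot(pseudocount >= 0, transition_pseudocount > 0)
  assert_peptides(windows, "training window")
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("training windows must have equal length")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  }
  background <- validate_background(background)
  mat <- peptide_int_matrix(windows)
  n <- nrow(mat)
  emis <- matrix(pseudocount, nrow = L, ncol = 20L,
                 dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(L)) {
    tab <- tabulate(mat[, j], nbins = 20L)
    emis[j, ] <- emis[j, ] + tab
  }
  emis <- emis / rowSums(emis)
  if (pseudocount == 0 && any(rowSums(emis) == 0))
    stop("zero pseudocount with an empty emission row")
  # transitions: training alignment is gapless, so n observed M->M at every
  # junction; smooth with the transition pseudocount
  tp <- transition_pseudocount
  mm <- (n + tp) / (n + 3 * tp)
  mi <- tp / (n + 3 * tp)
  md <- tp / (n + 3 * tp)
  trans <- list(
    MM = rep(mm, L + 1L), MI = rep(mi, L + 1L), MD = rep(md, L + 1L),
    IM = rep(0.9, L + 1L), II = rep(0.1, L + 1L),
    DM = rep(0.9, L + 1L), DD = rep(0.1, L + 1L))
  # final junction (j = L): no delete target, renormalize M_L and D_L exits
  trans$MM[L + 1L] <- (n + tp) / (n + 2 * tp)  # M_L -> End
  trans$MI[L + 1L] <- tp / (n + 2 * tp)
  trans$MD[L + 1L] <- 0
  trans$DM[L + 1L] <- 1                        # D_L -> End
  trans$DD[L + 1L] <- 0
  structure(list(length = L,
                 match_emissions = emis,
                 insert_emissions = background,
                 transitions = trans,
                 background = background,
                 n_train = n),
            class = "profile_hmm")
}

validate_background <- function(background) {
  if (is.null(names(background)) || !all(AA_ALPHABET %in% names(background)))
    stop("background must be named by the 20 amino acids")
  background <- background[AA_ALPHABET]
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  background
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM: length", x$length, "trained on", x$n_train, "window(s)\n")
  cat("  match emission range:",
      signif(range(x$match_emissions), 3), "\n")
  invisible(x)
}

#' Forward-algorithm log-odds score of windows against a profile HMM
#'
#' Computes `log2( P(window | model) / P(window | background) )` where the
#' numerator is the full forward sum over all match/insert/delete state paths
#' and the denominator is the i.i.d. background likelihood. Vectorized over
#' windows (all must share one length).
#'
#' @param model a `profile_hmm`.
#' @param windows character vector of amino-acid windows.
#' @return numeric vector of scores in bits.
#' @export
forward_log_odds <- function(model, windows) {
  stopifnot(inherits(model, "profile_hmm"))
  if (length(windows) == 0L) return(numeric(0))
  assert_peptides(windows, "window")
  x <- peptide_int_matrix(windows)
  W <- nrow(x); n <- ncol(x); L <- model$length
  lem <- log(model$match_emissions)          # L x 20
  lei <- log(as.numeric(model$insert_emissions[AA_ALPHABET]))  # 20
  tr <- lapply(model$transitions, log)
  neg <- rep(-Inf, W)

  # fM[[j]], fI[[j]], fD[[j]]: log forward prob vectors over windows for the
  # current number of emitted symbols i; j = 0..L (j = 0 is the begin state,
  # with I_0 the N-terminal insert and no D_0)
  fM <- vector("list", L + 1L); fI <- vector("list", L + 1L)
  fD <- vector("list", L + 1L)
  # i = 0: nothing emitted
  fM[[1L]] <- rep(0, W)                       # begin
  fI[[1L]] <- neg
  fD[[1L]] <- neg
  for (j in seq_len(L)) {
    fM[[j + 1L]] <- neg
    fI[[j + 1L]] <- neg
    # silent delete chain reachable before any emission
    fD[[j + 1L]] <- logsumexp_rows(fM[[j]] + tr$MD[j], fD[[j]] + tr$DD[j])
  }
  for (i in seq_len(n)) {
    sym <- x[, i]
    nM <- vector("list", L + 1L); nI <- vector("list", L + 1L)
    nD <- vector("list", L + 1L)
    nM[[1L]] <- neg                            # begin cannot re-enter
    nI[[1L]] <- lei[sym] + logsumexp_rows(fM[[1L]] + tr$MI[1L],
                                          fI[[1L]] + tr$II[1L])
    nD[[1L]] <- neg
    for (j in seq_len(L)) {
      nM[[j + 1L]] <- lem[j, sym] +
        logsumexp_rows(fM[[j]] + tr$MM[j],
                       fI[[j]] + tr$IM[j],
                       fD[[j]] + tr$DM[j])
      nI[[j + 1L]] <- lei[sym] +
        logsumexp_rows(fM[[j + 1L]] + tr$MI[j + 1L],
                       fI[[j + 1L]] + tr$II[j + 1L])
      nD[[j + 1L]] <- logsumexp_rows(nM[[j]] + tr$MD[j],
                                     nD[[j]] + tr$DD[j])
    }
    fM <- nM; fI <- nI; fD <- nD
  }
  loglik <- logsumexp_rows(fM[[L + 1L]] + tr$MM[L + 1L],
                           fI[[L + 1L]] + tr$IM[L + 1L],
                           fD[[L + 1L]] + tr$DM[L + 1L])
  lbg <- log(as.numeric(model$background[AA_ALPHABET]))
  bg <- rowSums(matrix(lbg[x], nrow = W))
  unname((loglik - bg) / log(2))
}

# --- Gumbel (type-I extreme value) helpers -------------------------------

#' Gumbel distribution density, CDF and sampling
#'
#' Standard location-scale Gumbel (maximum) distribution used to model the
#' null distribution of profile-HMM log-odds scores.
#'
#' @param x,q,n usual distribution-function arguments.
#' @param location,scale Gumbel parameters (`scale > 0`).
#' @param log,lower.tail as in base distribution functions.
#' @name gumbel
#' @export
dgumbel <- function(x, location = 0, scale = 1, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - location) / scale
  ld <- -log(scale) - z - exp(-z)
  if (log) ld else exp(ld)
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, location = 0, scale = 1, lower.tail = TRUE) {
  stopifnot(scale > 0)
  p <- exp(-exp(-(q - location) / scale))
  if (lower.tail) p else -expm1(-exp(-(q - location) / scale))
}

#' @rdname gumbel
#' @export
rgumbel <- function(n, location = 0, scale = 1) {
  stopifnot(scale > 0)
  location - scale * log(-log(stats::runif(n)))
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location and scale by direct likelihood maximization (Nelder-Mead on
#' `(location, log scale)`, moment estimates as start). With
#' `tail_fraction < 1` only the top fraction of the sample enters the
#' density term and the rest is treated as left-censored at the cut point
#' (proper censored MLE). Tail fitting leaves estimates consistent when the
#' sample really is Gumbel, while making the extreme upper tail — the only
#' region E-values depend on — robust to misspecification of the bulk.
#'
#' @param x numeric sample.
#' @param tail_fraction fraction of the largest observations fitted exactly
#'   (default 1: plain MLE on the full sample).
#' @return list with `location` and `scale`.
#' @export
fit_gumbel <- function(x, tail_fraction = 1) {
  if (length(x) < 10L) stop("need at least 10 observations")
  if (stats::sd(x) < 1e-12) stop("degenerate (constant) sample")
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  beta0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0
  if (tail_fraction >= 1) {
    nll <- function(p) -sum(dgumbel(x, p[1], exp(p[2]), log = TRUE))
  } else {
    cut <- stats::quantile(x, 1 - tail_fraction, names = FALSE)
    xt <- x[x > cut]
    n_cens <- length(x) - length(xt)
    if (length(xt) < 10L) stop("tail_fraction leaves fewer than 10 points")
    nll <- function(p) {
      -sum(dgumbel(xt, p[1], exp(p[2]), log = TRUE)) -
        n_cens * log(pgumbel(cut, p[1], exp(p[2])))
    }
  }
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  list(location = fit$par[1], scale = exp(fit$par[2]))
}

#' Calibrate E-values for a profile HMM by shuffled-decoy scoring
#'
#' Scores `n_decoys` residue-shuffled versions of windows drawn from the
#' background distribution, fits a Gumbel null to the resulting log-odds
#' scores, and returns a calibration object mapping a score `s` to
#' `E(s) = search_space_size * (1 - GumbelCDF(s))`, the expected number of
#' equal-or-better scores in a search of that many windows under the null.
#'
#' @param model a `profile_hmm`.
#' @param n_decoys number of decoy windows (default 10000, minimum 100).
#' @param random_seed integer seed for decoy generation.
#' @param search_space_size number of windows in the target search space.
#' @param decoy_windows optional explicit decoy windows; when supplied they
#'   are residue-shuffled and used instead of background draws.
#' @param keep_scores keep the decoy score sample in the result (default
#'   FALSE).
#' @param tail_fraction passed to [fit_gumbel()]; values below 1 fit only
#'   the decoy upper tail (censored MLE), which extrapolates the extreme
#'   tail more faithfully when decoy scores are not exactly Gumbel.
#' @return object of class `evalue_calibration` with `gumbel_location`,
#'   `gumbel_scale`, `decoy_count`, `search_space_size` (and
#'   `decoy_scores` when requested).
#' @export
calibrate_evalues <- function(model, n_decoys = 10000L, random_seed = 1L,
                              search_space_size, decoy_windows = NULL,
                              keep_scores = FALSE, tail_fraction = 1) {
  stopifnot(inherits(model, "profile_hmm"), search_space_size > 0)
  if (n_decoys < 100L) stop("need at least 100 decoys")
  L <- model$length
  decoys <- withr_seed(random_seed, {
    if (is.null(decoy_windows)) {
      p <- as.numeric(model$background[AA_ALPHABET])
      m <- matrix(sample(AA_ALPHABET, n_decoys * L, replace = TRUE, prob = p),
                  nrow = n_decoys)
      apply(m, 1L, paste, collapse = "")
    } else {
      src <- sample(decoy_windows, n_decoys, replace = TRUE)
      vapply(src, function(w) {
        paste(sample(strsplit(w, "", fixed = TRUE)[[1]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
  })
  scores <- forward_log_odds(model, decoys)
  if (stats::sd(scores) < 1e-12) stop("degenerate decoy score distribution")
  fit <- fit_gumbel(scores, tail_fraction = tail_fraction)
  structure(list(gumbel_location = fit$location,
                 gumbel_scale = fit$scale,
                 decoy_count = as.integer(n_decoys),
                 search_space_size = as.numeric(search_space_size),
                 decoy_scores = if (keep_scores) scores else NULL),
            class = "evalue_calibration")
}

#' E-value of a score under a calibration
#'
#' @param calibration an `evalue_calibration`.
#' @param score numeric vector of log-odds scores.
#' @return expected number of equal-or-better null scores (non-increasing
#'   in `score`).
#' @export
evalue <- function(calibration, score) {
  stopifnot(inherits(calibration, "evalue_calibration"))
  calibration$search_space_size *
    pgumbel(score, calibration$gumbel_location, calibration$gumbel_scale,
            lower.tail = FALSE)
}
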