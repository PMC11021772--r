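# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the forward algorithm is checked against a
# depth-first enumeration of every state path, binomial tails against a
# direct density sum, and similarity/identity rules against hand counting.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# total probability of a window under a profile HMM by exhaustive
# enumeration of all match/insert/delete state paths (tiny models only)
oracle_forward_lik <- function(model, window) {
  L <- model$length
  sym <- match(strsplit(window, "", fixed = TRUE)[[1]], AA20)
  n <- length(sym)
  tr <- model$transitions
  emM <- model$match_emissions
  emI <- as.numeric(model$insert_emissions[colnames(model$match_emissions)])
  env <- new.env()
  env$total <- 0
  go <- function(state, j, i, p) {
    if (p <= 0) return()
    jj <- j + 1L
    if (state == "M") {
      if (j == L) {
        if (i == n) env$total <- env$total + p * tr$MM[L + 1L]
        if (i < n) go("I", L, i + 1L, p * tr$MI[L + 1L] * emI[sym[i + 1L]])
        return()
      }
      if (i < n) go("M", j + 1L, i + 1L, p * tr$MM[jj] * emM[j + 1L, sym[i + 1L]])
      if (i < n) go("I", j, i + 1L, p * tr$MI[jj] * emI[sym[i + 1L]])
      go("D", j + 1L, i, p * tr$MD[jj])
    } else if (state == "I") {
      if (j == L) {
        if (i == n) env$total <- env$total + p * tr$IM[L + 1L]
        if (i < n) go("I", L, i + 1L, p * tr$II[L + 1L] * emI[sym[i + 1L]])
        return()
      }
      if (i < n) go("M", j + 1L, i + 1L, p * tr$IM[jj] * emM[j + 1L, sym[i + 1L]])
      if (i < n) go("I", j, i + 1L, p * tr$II[jj] * emI[sym[i + 1L]])
    } else {
      if (j == L) {
        if (i == n) env$total <- env$total + p * tr$DM[L + 1L]
        return()
      }
      if (i < n) go("M", j + 1L, i + 1L, p * tr$DM[jj] * emM[j + 1L, sym[i + 1L]])
      go("D", j + 1L, i, p * tr$DD[jj])
    }
  }
  go("M", 0L, 0L, 1)
  env$total
}

oracle_forward_bits <- function(model, window) {
  bg <- as.numeric(model$background[strsplit(window, "", fixed = TRUE)[[1]]])
  unname(log2(oracle_forward_lik(model, window) / prod(bg)))
}

# one-sided upper binomial tail by direct density summation
oracle_binom_tail <- function(count, n, p0) {
  if (count <= 0) return(1)
  sum(stats::dbinom(count:n, n, p0))
}

# attained level of the exact one-sided binomial test at nominal alpha:
# the largest achievable tail probability strictly below alpha
oracle_attained_level <- function(n, p0, alpha) {
  tails <- vapply(0:(n + 1), function(c) oracle_binom_tail(c, n, p0),
                  numeric(1))
  ok <- tails[tails < alpha]
  if (length(ok) == 0) 0 else max(ok)
}

# brute-force all-pairs maximum similarity of a retained set
oracle_max_pairwise_similarity <- function(peptides) {
  if (length(peptides) < 2L) return(0)
  best <- 0
  for (i in seq_along(peptides)[-length(peptides)]) {
    s <- pairwise_similarity(peptides[i],
                             peptides[(i + 1):length(peptides)])
    best <- max(best, max(s))
  }
  best
}

# random window helper
random_windows <- function(n, len = 20L, alphabet = AA20, prob = NULL) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

# small in-memory PSM record constructor for fixtures
psm_rows <- function(sample_id, enzyme_state, atp_state, library_id,
                     is_phospho, xcorr, site_probability = NA_real_,
                     site = 10L,
                     sequence = paste0(strrep("A", 9), "S", strrep("A", 10))) {
  n <- max(length(library_id), length(xcorr))
  data.frame(sample_id = sample_id, enzyme_state = enzyme_state,
             atp_state = atp_state,
             library_id = rep_len(library_id, n),
             sequence = rep_len(sequence, n),
             is_phospho = rep_len(is_phospho, n),
             site_positions = I(lapply(rep_len(is_phospho, n), function(p)
               if (p) as.integer(site) else integer(0))),
             xcorr = rep_len(xcorr, n),
             site_probability = rep_len(site_probability, n))
}
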