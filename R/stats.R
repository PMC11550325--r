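test_result <- function(test_name, statistic, p_value, n_effective,
                        method_notes = "", degenerate = FALSE) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n_effective = as.integer(n_effective),
                 method_notes = method_notes, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s: statistic=%s, p=%.4g, n=%d%s>\n", x$test_name,
              format(x$statistic), x$p_value, x$n_effective,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# Exact null distribution of the positive-rank sum W+ over all 2^n sign
# assignments, by generating-function convolution over doubled mid-ranks
# (doubling makes tied mid-ranks integer-valued). Returns probabilities on
# support 0 .. sum(2*ranks), index i = P(2*W+ = i-1).
signed_rank_distribution <- function(ranks2) {
  probs <- numeric(sum(ranks2) + 1L)
  probs[1L] <- 1
  upto <- 1L
  for (r in ranks2) {
    cur <- probs[seq_len(upto)]
    upto <- upto + r
    probs[seq_len(upto)] <- 0.5 * (c(cur, numeric(r)) + c(numeric(r), cur))
  }
  probs
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `post - pre`. Zero differences are
#' dropped before ranking (the classic Wilcoxon reduction, not Pratt's);
#' ties among the absolute differences receive mid-ranks. With
#' `n_effective <= 25` non-zero pairs (or `mode = "exact"`) the p value is
#' exact over all `2^n` sign assignments, computed by convolution of the
#' signed-rank generating function, which is valid in the presence of ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. The two-sided p is `2 * min(P(W <= w), P(W >= w))`
#' clamped to 1. If every difference is zero the test is degenerate and
#' `p = 1`.
#'
#' @param pre,post Numeric vectors of paired values, aligned.
#' @param mode `"auto"` (default), `"exact"` or `"approximate"`.
#' @return A `test_result` with `statistic` = W+ (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(pre, post, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  stopifnot(length(pre) == length(post))
  if (length(pre) == 0L) stop("wilcoxon_signed_rank: empty sample")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(test_result("wilcoxon_signed_rank", statistic = 0, p_value = 1,
                       n_effective = 0L, "all paired differences zero",
                       degenerate = TRUE))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  exact <- switch(mode, exact = TRUE, approximate = FALSE, auto = n <= 25L)
  if (exact) {
    probs <- signed_rank_distribution(as.integer(round(2 * r)))
    k <- as.integer(round(2 * w_pos)) + 1L
    lower <- sum(probs[seq_len(k)])
    upper <- sum(probs[k:length(probs)])
    p <- min(1, 2 * min(lower, upper))
    notes <- sprintf("exact enumeration over 2^%d sign assignments", n)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    notes <- "normal approximation with tie and continuity correction"
  }
  test_result("wilcoxon_signed_rank", statistic = w_pos, p_value = p,
              n_effective = n, method_notes = notes)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test with the minimum-likelihood definition: with margins
#' fixed, the p value sums the hypergeometric probabilities of every table
#' whose probability does not exceed that of the observed table (within
#' relative tolerance `1e-7`). Rows are the two conditions (e.g. without /
#' with AI assistance), columns success / failure.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a numeric vector
#'   `c(a, b, c, d)` filled by row.
#' @return A `test_result`; `statistic` is the observed top-left count.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  stopifnot(all(dim(tab) == 2L))
  if (any(tab < 0)) stop("fisher_exact_2x2: negative counts")
  total <- sum(tab)
  if (total == 0) stop("fisher_exact_2x2: empty table")
  m <- sum(tab[1L, ])   # row 1 margin
  k <- sum(tab[, 1L])   # column 1 margin
  lo <- max(0, k - (total - m))
  hi <- min(k, m)
  support <- lo:hi
  logp <- stats::dhyper(support, m, total - m, k, log = TRUE)
  obs <- tab[1L, 1L]
  p_obs <- logp[support == obs]
  p <- sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
  test_result("fisher_exact_2x2", statistic = obs, p_value = min(1, p),
              n_effective = total,
              method_notes = "two-sided, minimum-likelihood summation")
}

#' Exact McNemar test from discordant counts
#'
#' Exact two-sided binomial test on the discordant pairs of a paired binary
#' outcome: `p = min(1, 2 * P(X <= min(b, c)))` for
#' `X ~ Binomial(b + c, 1/2)`. With no discordant pairs the test is
#' degenerate and `p = 1`.
#'
#' @param discordant_b,discordant_c The two discordant cell counts.
#' @return A `test_result`; `statistic` is `min(b, c)`.
#' @export
mcnemar_exact <- function(discordant_b, discordant_c) {
  b <- discordant_b; c <- discordant_c
  if (b < 0 || c < 0) stop("mcnemar_exact: negative counts")
  n <- b + c
  if (n == 0)
    return(test_result("mcnemar_exact", statistic = 0, p_value = 1,
                       n_effective = 0L, "no discordant pairs",
                       degenerate = TRUE))
  p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
  test_result("mcnemar_exact", statistic = min(b, c), p_value = p,
              n_effective = n, method_notes = "exact binomial, two-sided")
}
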