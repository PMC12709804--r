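#' ESS of a conjugate Beta prior
#'
#' For a binomial endpoint, a `Beta(a, b)` prior carries the information of
#' `a + b` observations (a vague `Beta(a0, b0)` updated with `a - a0`
#' successes and `b - b0` failures).
#'
#' @param a,b positive Beta parameters.
#' @return `a + b`.
#' @examples
#' beta_conjugate_ess(0.5, 0.5) # the vague prior used for independent analysis
#' @export
beta_conjugate_ess <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(a <= 0) || any(b <= 0))
    stop("Beta parameters must be positive", call. = FALSE)
  a + b
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Equal-tailed exact interval for a binomial proportion, via the Beta
#' quantile representation of the binomial tail. The lower bound is 0 when
#' `y = 0` and the upper bound is 1 when `y = n`.
#'
#' @param y responder count, `0 <= y <= n`.
#' @param n sample size.
#' @param level confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(5, 16) # approx (0.110, 0.587)
#' @export
clopper_pearson <- function(y, n, level = 0.95) {
  check_count(n, "n", positive = TRUE)
  check_count(y, "y")
  if (y > n) stop("y must not exceed n", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  lower <- if (y == 0) 0 else qbeta(alpha / 2, y, n - y + 1)
  upper <- if (y == n) 1 else qbeta(1 - alpha / 2, y + 1, n - y)
  c(lower = lower, upper = upper)
}

#' Critical count of the exact one-sided binomial test
#'
#' Smallest integer `c` such that `P(Y >= c | n, p0) <= alpha` — the
#' non-randomized rejection rule "reject H0: p <= p0 iff Y >= c".
#'
#' @param n sample size.
#' @param p0 null response probability in (0, 1).
#' @param alpha one-sided significance level in (0, 1].
#' @return Integer critical count.
#' @examples
#' exact_binomial_rule(30, 0.15, 0.05) # 9
#' @export
exact_binomial_rule <- function(n, p0, alpha = 0.05) {
  check_count(n, "n", positive = TRUE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  tails <- 1 - pbinom(0:n - 1, n, p0) # P(Y >= c) for c = 0..n
  c <- which(tails <= alpha)[1] - 1L
  if (is.na(c)) c <- n + 1L # never rejects
  as.integer(c)
}

#' Power of the exact one-sided binomial test
#'
#' `P(Y >= c | n, p1)` with the critical count `c` from
#' [exact_binomial_rule()]. At `p1 = p0` this equals the achieved size.
#'
#' @inheritParams exact_binomial_rule
#' @param p1 true response probability in `[0, 1]`.
#' @return Rejection probability.
#' @examples
#' exact_binomial_power(30, 0.15, 0.3, 0.05)
#' @export
exact_binomial_power <- function(n, p0, p1, alpha = 0.05) {
  if (p1 < 0 || p1 > 1) stop("p1 must be in [0, 1]", call. = FALSE)
  c <- exact_binomial_rule(n, p0, alpha)
  if (c > n) return(0)
  1 - pbinom(c - 1, n, p1)
}

#' Pearson chi-square heterogeneity statistic
#'
#' Pearson chi-square statistic (no continuity correction) of the K x 2
#' table of responders/non-responders against the pooled expectation — the
#' default between-group heterogeneity measure `T` driving the calibrated
#' BHM's empirical-Bayes variance.
#'
#' @param data a [basket_data] object with `K >= 2`.
#' @return The statistic, or `NA` with attribute `status = "not_computable"`
#'   when the pooled response rate is 0 or 1.
#' @export
chi_square_heterogeneity <- function(data) {
  stopifnot(inherits(data, "basket_data"))
  if (data$K < 2) stop("heterogeneity requires K >= 2", call. = FALSE)
  pbar <- sum(data$y) / sum(data$n)
  if (pbar <= 0 || pbar >= 1) {
    out <- NA_real_
    attr(out, "status") <- "not_computable"
    return(out)
  }
  e1 <- data$n * pbar
  e0 <- data$n * (1 - pbar)
  sum((data$y - e1)^2 / e1 + ((data$n - data$y) - e0)^2 / e0)
}

#' Kolmogorov-Smirnov similarity between two binary samples
#'
#' For binary outcomes the two-sample KS statistic reduces to the absolute
#' difference of observed response proportions. The scaled similarity
#' `S = max(n_k, n_i)^(1/4) * S_KS` feeds the power-prior weights.
#'
#' @param y_k,n_k counts for indication k.
#' @param y_i,n_i counts for indication i.
#' @return List with elements `s_ks` (in `[0, 1]`) and `s` (scaled).
#' @examples
#' ks_binary(6, 30, 15, 30) # s_ks = 0.3, s = 30^0.25 * 0.3
#' @export
ks_binary <- function(y_k, n_k, y_i, n_i) {
  check_count(c(n_k, n_i), "n", positive = TRUE)
  check_count(c(y_k, y_i), "y")
  if (y_k > n_k || y_i > n_i) stop("y must not exceed n", call. = FALSE)
  s_ks <- abs(y_k / n_k - y_i / n_i)
  list(s_ks = s_ks, s = max(n_k, n_i)^0.25 * s_ks)
}
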