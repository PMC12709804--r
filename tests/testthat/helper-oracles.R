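# Independent numerical oracles used across the test files. These are
# deliberately separate code paths from the package internals: quadrature
# instead of MCMC, direct tail enumeration instead of closed forms, and a
# hand-assembled power-prior chain.

# posterior mean of p under the pooled model (single logit parameter mu
# with N(mu0, sd0^2) prior and the summed binomial likelihood), by 1-D
# quadrature
oracle_pooled_mean <- function(y, n, mu0 = -2.19, sd0 = 2) {
  sy <- sum(y); sn <- sum(n)
  logw <- function(m) sy * m - sn * log1p(exp(m)) +
    dnorm(m, mu0, sd0, log = TRUE)
  # normalise by the log-weight maximum to avoid underflow
  off <- optimize(logw, c(-20, 10), maximum = TRUE)$objective
  w <- function(m) exp(logw(m) - off)
  num <- integrate(function(m) plogis(m) * w(m), -20, 10,
                   rel.tol = 1e-10)$value
  den <- integrate(w, -20, 10, rel.tol = 1e-10)$value
  num / den
}

# single-arm posterior mean under a logit-normal prior N(mu0, sd^2);
# the integration window covers the likelihood support (the prior is
# effectively flat there when sd is large)
oracle_logitnormal_mean <- function(y, n, mu0, sd) {
  logw <- function(m) y * m - n * log1p(exp(m)) +
    dnorm(m, mu0, sd, log = TRUE)
  lo <- max(-40, mu0 - 12 * sd); hi <- min(40, mu0 + 12 * sd)
  off <- optimize(logw, c(lo, hi), maximum = TRUE)$objective
  w <- function(m) exp(logw(m) - off)
  num <- integrate(function(m) plogis(m) * w(m), lo, hi,
                   rel.tol = 1e-10)$value
  den <- integrate(w, lo, hi, rel.tol = 1e-10)$value
  num / den
}

# Monte Carlo standard error of a chain mean via batch means (accounts
# for autocorrelation)
mcse_batch <- function(x, n_batch = 30) {
  m <- length(x) %/% n_batch
  bm <- vapply(seq_len(n_batch),
               function(i) mean(x[((i - 1) * m + 1):(i * m)]), numeric(1))
  sd(bm) / sqrt(n_batch)
}

# brute-force Pearson chi-square on the K x 2 responder table via the
# textbook observed/expected loop (independent of the package formula)
oracle_chisq <- function(y, n) {
  obs <- cbind(y, n - y)
  pbar <- sum(y) / sum(n)
  expd <- cbind(n * pbar, n * (1 - pbar))
  sum((obs - expd)^2 / expd)
}

# hand-assembled power-prior posterior parameters for K = 2, chaining the
# stated formulas step by step
oracle_pp_k2 <- function(y, n, a, b, s1 = 0.5, s2 = 0.5) {
  sks <- abs(y[1] / n[1] - y[2] / n[2])
  S <- max(n)^0.25 * sks
  w12 <- if (S == 0) 1 else 1 / (1 + exp(a + b * log(S)))
  list(a1 = s1 + y[1] + w12 * y[2],
       b1 = s2 + (n[1] - y[1]) + w12 * (n[2] - y[2]),
       w12 = w12)
}

scens4 <- function() builtin_scenarios()
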