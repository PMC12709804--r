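#' Exact MSE of the independent binomial estimator
#'
#' For a maximum-likelihood estimate `Y/total_n` with `Y ~ Bin(total_n, p)`
#' the estimator is unbiased with MSE `p(1-p)/total_n`. Non-integer
#' `total_n` is accepted to support the interpolation step of the ESS
#' search.
#'
#' @param p true (or plug-in) response probability.
#' @param total_n positive (possibly fractional) sample size.
#' @return `p * (1 - p) / total_n`.
#' @export
independent_mse <- function(p, total_n) {
  if (any(total_n <= 0)) stop("total_n must be positive", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  p * (1 - p) / total_n
}

new_ess_result <- function(status, method = "mse", posterior_ess = NA_real_,
                           prior_ess = NA_real_, mse_bayes = NA_real_,
                           mse_independent_at_match = NA_real_) {
  structure(list(posterior_ess = posterior_ess, prior_ess = prior_ess,
                 mse_bayes = mse_bayes,
                 mse_independent_at_match = mse_independent_at_match,
                 status = status, method = method),
            class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  cat("ESS result (", x$method, "): status = ", x$status, sep = "")
  if (x$status != "not_available")
    cat("; posterior ESS = ", round(x$posterior_ess, 1),
        ", prior ESS = ", round(x$prior_ess, 1), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.ess_result <- function(x, ...) {
  data.frame(method = x$method, posterior_ess = x$posterior_ess,
             prior_ess = x$prior_ess, mse_bayes = x$mse_bayes,
             mse_independent_at_match = x$mse_independent_at_match,
             status = x$status, stringsAsFactors = FALSE)
}

#' Convert a Bayesian MSE into an effective sample size
#'
#' Solves the MSE-matching problem: find the sample size `m + n` at which
#' an independent binomial analysis attains the same MSE as the Bayesian
#' estimator. Implemented as a grid search over integer `m` in
#' `[-n + 1, m_max]` for the minimizer of
#' `|p(1-p)/(m+n) - mse_bayes|`, refined to one decimal place by linear
#' interpolation of the signed distance between the two bracketing
#' integers. `p` of 0 or 1 makes the independent MSE identically 0, so the
#' ESS is not available there.
#'
#' @param mse_bayes positive MSE of the Bayesian estimator.
#' @param p true (design stage) or observed (analysis stage) response
#'   probability.
#' @param n enrolled sample size for the indication.
#' @param m_max upper end of the search grid; default `10 * max(n, 30) * 4`
#'   is generous because strong borrowing can push the ESS far beyond the
#'   trial size.
#' @return An `ess_result` with `posterior_ess = m* + n`,
#'   `prior_ess = m*`, and `status` one of `"ok"`, `"not_available"`
#'   (degenerate `p`), or `"capped"` (matching point outside the grid).
#' @examples
#' ess_from_mse(0.15 * 0.85 / 30, p = 0.15, n = 30) # prior ESS 0
#' @export
ess_from_mse <- function(mse_bayes, p, n, m_max = NULL) {
  check_count(n, "n", positive = TRUE)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (p == 0 || p == 1) return(new_ess_result("not_available"))
  if (!is.finite(mse_bayes) || mse_bayes <= 0)
    stop("mse_bayes must be positive", call. = FALSE)
  if (is.null(m_max)) m_max <- 40L * max(n, 30L)
  q <- p * (1 - p)
  grid <- as.numeric(seq.int(-n + 1L, m_max))
  dist <- q / (grid + n) - mse_bayes # signed, strictly decreasing in m
  if (dist[length(dist)] > 0) { # even m_max gives larger MSE than target
    res <- new_ess_result("capped", posterior_ess = m_max + n,
                          prior_ess = m_max, mse_bayes = mse_bayes,
                          mse_independent_at_match =
                            q / (m_max + n))
    res$bound <- "upper"
    return(res)
  }
  if (dist[1] < 0) { # target MSE above what a single observation gives
    res <- new_ess_result("capped", posterior_ess = 1, prior_ess = -n + 1,
                          mse_bayes = mse_bayes,
                          mse_independent_at_match = q)
    res$bound <- "lower"
    return(res)
  }
  i <- findInterval(0, -dist) # last index with dist >= 0
  m_lo <- grid[i]
  if (i == length(grid) || dist[i] == 0) {
    m_star <- m_lo
  } else {
    d0 <- dist[i]; d1 <- dist[i + 1]
    m_star <- m_lo + d0 / (d0 - d1)
  }
  new_ess_result("ok", posterior_ess = m_star + n, prior_ess = m_star,
                 mse_bayes = mse_bayes,
                 mse_independent_at_match = q / (m_star + n))
}

#' Design-stage Monte Carlo MSE of the BHM estimator
#'
#' Simulates full basket trials from a scenario, fits the hierarchical
#' model to each replication, and returns the per-indication mean squared
#' deviation of the posterior-mean estimate from the true response rate,
#' together with its bias/variance decomposition and Monte Carlo standard
#' errors.
#'
#' @param scenario a [scenario] object.
#' @param prior a [prior_spec].
#' @param reps number of simulated trials.
#' @param seed master RNG seed.
#' @param settings [mcmc_settings] used for every fit.
#' @param estimator optional function `f(y_matrix, n)` returning a
#'   `reps x K` matrix of point estimates; defaults to the BHM
#'   posterior mean under `prior`. Lets the same machinery serve the
#'   calibrated BHM and power-prior designs.
#' @return A list with `mse` (per indication), `bias`, `variance`,
#'   `mse_se` (Monte Carlo standard error of the MSE), `estimates`
#'   (`reps x K`), and the simulated `y` matrix.
#' @export
design_stage_mse_bayes <- function(scenario, prior, reps = 1000L,
                                   seed = 1L, settings = mcmc_settings(),
                                   estimator = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  K <- length(scenario$true_orr)
  y <- simulate_trials(scenario, reps, seed)
  if (is.null(estimator)) {
    sp <- prior_cpp_args(prior)
    set.seed(seed + 1L)
    est <- bhm_postmean_batch_cpp(y, as.numeric(scenario$n),
                                  prior$mu_mean, prior$mu_sd,
                                  sp$fixed, sp$value, sp$shape, sp$scale,
                                  settings$iterations, settings$burn_in,
                                  settings$thin)
  } else {
    est <- estimator(y, scenario$n)
  }
  err <- sweep(est, 2, scenario$true_orr)
  mse <- colMeans(err^2)
  bias <- colMeans(err)
  variance <- mse - bias^2
  mse_se <- apply(err^2, 2, sd) / sqrt(reps)
  list(mse = setNames(mse, paste0("arm", seq_len(K))),
       bias = bias, variance = variance, mse_se = mse_se,
       estimates = est, y = y, reps = reps, seed = seed)
}

# reps x K matrix of binomial responder counts, one row per trial, with a
# per-replication seed substream derived from the master seed
simulate_trials <- function(scenario, reps, seed) {
  set.seed(seed)
  K <- length(scenario$true_orr)
  matrix(rbinom(reps * K, size = rep(scenario$n, each = reps),
                prob = rep(scenario$true_orr, each = reps)),
         nrow = reps, ncol = K)
}

#' Design-stage MSE-based effective sample size
#'
#' Composes [design_stage_mse_bayes()] and [ess_from_mse()] with the true
#' scenario response rates: the posterior ESS per indication is the
#' independent-analysis sample size matching the BHM's Monte Carlo MSE,
#' and the prior ESS is the posterior ESS minus the enrolled `n_k`.
#'
#' @inheritParams design_stage_mse_bayes
#' @param m_max search cap forwarded to [ess_from_mse()].
#' @return A data.frame of class `ess_table` with one row per indication:
#'   `indication, method, posterior_ess, prior_ess, mse_bayes,
#'   mse_independent_at_match, status`, plus attributes `mse_se` and
#'   `ess_se` (delta-method Monte Carlo standard error).
#' @export
design_stage_ess <- function(scenario, prior, reps = 1000L, seed = 1L,
                             settings = mcmc_settings(), m_max = NULL,
                             estimator = NULL, method = "mse") {
  sim <- design_stage_mse_bayes(scenario, prior, reps, seed, settings,
                                estimator)
  K <- length(scenario$true_orr)
  rows <- lapply(seq_len(K), function(k) {
    r <- ess_from_mse(sim$mse[k], scenario$true_orr[k], scenario$n[k],
                      m_max)
    r$method <- method
    cbind(indication = paste0("arm", k), as.data.frame(r))
  })
  out <- do.call(rbind, rows)
  # delta method: posterior ESS = q/MSE, so se(ESS) ~ q * se(MSE) / MSE^2
  q <- scenario$true_orr * (1 - scenario$true_orr)
  attr(out, "mse_se") <- sim$mse_se
  attr(out, "ess_se") <- q * sim$mse_se / sim$mse^2
  attr(out, "reps") <- reps
  class(out) <- c("ess_table", "data.frame")
  out
}

#' Analysis-stage MSE-based effective sample size
#'
#' At the analysis stage the unknown truth is replaced by the observed rate
#' `phat_k = y_k / n_k`. The Bayesian MSE is computed by exact enumeration
#' over the `n_k + 1` possible own-indication outcomes `y'` (the
#' expectation is over a finite support): for each `y'` the hierarchical
#' model is refitted with indication `k` set to `y'` and the other
#' indications held at their observed values, and the squared deviations
#' `(phat^B_k(y') - phat_k)^2` are weighted by `Bin(y'; n_k, phat_k)`.
#' A common RNG seed across the enumeration keeps per-fit Monte Carlo
#' noise from accumulating. Observed rates of 0% or 100% make the
#' independent MSE identically zero, so the ESS is not available there.
#'
#' @param data a [basket_data] object.
#' @param prior a [prior_spec].
#' @param k indication index.
#' @param settings [mcmc_settings] shared by all enumeration fits.
#' @param m_max search cap forwarded to [ess_from_mse()].
#' @return An `ess_result` for indication `k`.
#' @export
analysis_stage_ess <- function(data, prior, k, settings = mcmc_settings(),
                               m_max = NULL) {
  stopifnot(inherits(data, "basket_data"))
  if (k < 1 || k > data$K) stop("k out of range", call. = FALSE)
  nk <- data$n[k]; yk <- data$y[k]
  if (yk == 0 || yk == nk) return(new_ess_result("not_available"))
  phat <- yk / nk
  yy <- data$y
  grid <- 0:nk
  ymat <- matrix(rep(yy, each = nk + 1), nrow = nk + 1)
  ymat[, k] <- grid
  sp <- prior_cpp_args(prior)
  set.seed(settings$seed)
  est <- bhm_postmean_batch_cpp(ymat, as.numeric(data$n),
                                prior$mu_mean, prior$mu_sd,
                                sp$fixed, sp$value, sp$shape, sp$scale,
                                settings$iterations, settings$burn_in,
                                settings$thin)
  w <- dbinom(grid, nk, phat)
  mse_b <- sum(w * (est[, k] - phat)^2)
  ess_from_mse(mse_b, phat, nk, m_max)
}

#' Analysis-stage ESS for every indication
#'
#' @inheritParams analysis_stage_ess
#' @return An `ess_table` data.frame with one row per indication.
#' @export
analysis_stage_ess_all <- function(data, prior, settings = mcmc_settings(),
                                   m_max = NULL) {
  rows <- lapply(seq_len(data$K), function(k) {
    r <- analysis_stage_ess(data, prior, k, settings, m_max)
    cbind(indication = data$labels[k], as.data.frame(r))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ess_table", "data.frame")
  out
}

#' Variance-ratio effective sample size
#'
#' The bias-blind comparator: posterior ESS is the plug-in binomial
#' information ratio `pbar(1 - pbar) / Var(p_k | data)` with `pbar` the
#' posterior mean, and prior ESS is that minus `n_k`. For a `Beta(a, b)`
#' posterior this equals `a + b + 1` exactly. Flagged `not_available` when
#' the observed rate is degenerate (0% or 100%), mirroring the MSE-based
#' rule.
#'
#' @param fit a `basket_fit` object.
#' @param data the [basket_data] the fit was computed from.
#' @param k indication index.
#' @return An `ess_result` with `method = "variance_ratio"`.
#' @export
variance_ratio_ess <- function(fit, data = fit$data, k) {
  stopifnot(inherits(fit, "basket_fit"))
  if (data$y[k] == 0 || data$y[k] == data$n[k])
    return(new_ess_result("not_available", method = "variance_ratio"))
  v <- fit$variance[k]
  if (!is.finite(v) || v <= 0)
    stop("posterior variance must be positive", call. = FALSE)
  pbar <- fit$mean[k]
  post_ess <- unname(pbar * (1 - pbar) / v)
  new_ess_result("ok", method = "variance_ratio",
                 posterior_ess = post_ess,
                 prior_ess = post_ess - data$n[k])
}

#' Write an ESS table to CSV
#'
#' @param ess an `ess_table` data.frame (from [design_stage_ess()] or
#'   [analysis_stage_ess_all()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ess_csv <- function(ess, path) {
  stopifnot(inherits(ess, "data.frame"))
  write.csv(as.data.frame(ess), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
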