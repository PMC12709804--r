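#' Tuning pair (a, b) for calibrated designs
#'
#' Houses the two tuning constants shared by the calibrated BHM variance
#' map `sigma2 = exp(a + b log T)` and the power-prior weight
#' `w = 1 / (1 + exp(a + b log S))`.
#'
#' @param a,b finite reals.
#' @param context `"cbhm"` or `"power_prior"`.
#' @return An object of class `tuning_pair`.
#' @export
tuning_pair <- function(a, b, context = c("cbhm", "power_prior")) {
  context <- match.arg(context)
  if (!is.finite(a) || !is.finite(b))
    stop("tuning parameters must be finite", call. = FALSE)
  structure(list(a = a, b = b, context = context), class = "tuning_pair")
}

#' Empirical-Bayes between-group variance of the calibrated BHM
#'
#' `sigma2 = exp(a + b * log(T))` with the heterogeneity statistic `T`
#' floored at `eps` (so T = 0 maps to the strongest borrowing the clamp
#' allows) and the result clamped to `[sigma2_min, sigma2_max]` to prevent
#' degenerate fits.
#'
#' @param T nonnegative heterogeneity statistic (e.g.
#'   [chi_square_heterogeneity()]).
#' @param tuning a [tuning_pair] (context `"cbhm"`).
#' @param eps floor applied to `T`.
#' @param sigma2_min,sigma2_max clamp bounds.
#' @return The between-group variance.
#' @export
cbhm_sigma2 <- function(T, tuning, eps = 1e-6, sigma2_min = 1e-4,
                        sigma2_max = 1e4) {
  if (!is.finite(T) || T < 0) stop("T must be >= 0", call. = FALSE)
  s2 <- exp(tuning$a + tuning$b * log(max(T, eps)))
  min(max(s2, sigma2_min), sigma2_max)
}

#' Fit the calibrated Bayesian hierarchical model
#'
#' Computes the between-group heterogeneity `T` from the data, maps it to
#' a fixed `sigma2` by [cbhm_sigma2()], and fits the BHM with that
#' variance. When `T` is not computable (pooled response rate 0 or 1) the
#' fit falls back to `sigma2_max` (minimal borrowing).
#'
#' @param data a [basket_data] object.
#' @param tuning a [tuning_pair] for the variance map.
#' @param settings [mcmc_settings].
#' @param mu_mean,mu_sd prior on the common mean `mu`.
#' @param level credible level.
#' @param ... clamp arguments passed to [cbhm_sigma2()].
#' @return A `cbhm_fit`/`bhm_fit`/`basket_fit` object; the chosen variance
#'   is stored as `sigma2_used` and the statistic as `T`.
#' @export
fit_cbhm <- function(data, tuning, settings = mcmc_settings(),
                     mu_mean = -2.19, mu_sd = 2, level = 0.95, ...) {
  stopifnot(inherits(data, "basket_data"))
  T <- chi_square_heterogeneity(data)
  if (is.na(T)) {
    s2 <- list(...)$sigma2_max
    if (is.null(s2)) s2 <- 1e4
  } else {
    s2 <- cbhm_sigma2(T, tuning, ...)
  }
  prior <- prior_spec(mu_mean, mu_sd, sigma2_fixed = s2,
                      label = sprintf("CBHM(a=%g, b=%g)", tuning$a,
                                      tuning$b))
  fit <- fit_bhm(data, prior, settings, level)
  fit$model <- "cbhm"
  fit$T <- T
  fit$sigma2_used <- s2
  fit$tuning <- tuning
  class(fit) <- c("cbhm_fit", class(fit))
  fit
}

#' Power-prior borrowing weight
#'
#' Logistic weight `w = 1 / (1 + exp(a + b log S))` applied to the scaled
#' similarity `S` between two indications. `S = 0` maps to weight 1 (the
#' limit for `b > 0`); the self-weight `w_kk = 1` is enforced by the
#' caller.
#'
#' @param S nonnegative scaled KS similarity (see [ks_binary()]).
#' @param tuning a [tuning_pair] (context `"power_prior"`).
#' @return Weight in `[0, 1]`.
#' @export
pp_weight <- function(S, tuning) {
  if (any(!is.finite(S) | S < 0)) stop("S must be >= 0", call. = FALSE)
  ifelse(S == 0 & tuning$b > 0, 1,
         1 / (1 + exp(tuning$a + tuning$b * log(pmax(S, .Machine$double.xmin)))))
}

#' Power-prior specification
#'
#' @param s1,s2 per-indication (or scalar) initial Beta parameters;
#'   default 0.5, the vague prior used elsewhere.
#' @param tuning a [tuning_pair] for the weights.
#' @return An object of class `pp_spec`.
#' @export
pp_spec <- function(tuning, s1 = 0.5, s2 = 0.5) {
  if (any(s1 <= 0) || any(s2 <= 0))
    stop("initial Beta parameters must be positive", call. = FALSE)
  structure(list(s1 = s1, s2 = s2, tuning = tuning), class = "pp_spec")
}

#' Fit the similarity-weighted power prior
#'
#' Pairwise pooling of other indications' counts into a conjugate Beta
#' posterior: for each indication `k`, the posterior is
#' `Beta(s1_k + sum_i w_ki y_i, s2_k + sum_i w_ki (n_i - y_i))` with
#' self-weight 1 and off-diagonal weights given by [pp_weight()] applied
#' to the scaled KS similarities. No MCMC is involved.
#'
#' @param data a [basket_data] object.
#' @param spec a [pp_spec].
#' @param level credible level.
#' @return A `pp_fit`/`basket_fit` object with exact Beta moments; also
#'   carries the `weights` matrix (rows = analysis indication k) and the
#'   per-indication nominal borrowed size `sum_i w_ki n_i - n_k`
#'   (`borrowed_n`).
#' @export
fit_power_prior <- function(data, spec, level = 0.95) {
  stopifnot(inherits(data, "basket_data"), inherits(spec, "pp_spec"))
  K <- data$K
  W <- diag(1, K)
  for (k in seq_len(K)) for (i in seq_len(K)) {
    if (i == k) next
    s <- ks_binary(data$y[k], data$n[k], data$y[i], data$n[i])$s
    W[k, i] <- pp_weight(s, spec$tuning)
  }
  s1 <- rep_len(spec$s1, K); s2 <- rep_len(spec$s2, K)
  a <- s1 + as.vector(W %*% data$y)
  b <- s2 + as.vector(W %*% (data$n - data$y))
  fit <- fit_conjugate_beta(data, a, b, level, n_draws = 0L, seed = 1L,
                            extra = list(model = "power_prior",
                                         weights = W,
                                         borrowed_n =
                                           as.vector(W %*% data$n) - data$n,
                                         spec = spec),
                            class = c("pp_fit"))
  fit
}

#' ESS-based model selection between BHM and independent analysis
#'
#' Computes the analysis-stage MSE-based prior ESS for every indication
#' under the supplied prior. If any indication has a negative prior ESS —
#' evidence that borrowing-induced bias outweighs the variance reduction —
#' the whole trial is analysed independently with a vague `Beta(0.5, 0.5)`
#' prior (`mode = "independent"`); otherwise the BHM fit is returned
#' (`mode = "bhm"`). The `"exclude"` variant instead drops only the
#' negative-ESS indications from the hierarchy (analysing them
#' independently), intended for trials with many indications.
#' Indications whose ESS is not available (observed ORR 0% or 100%) are
#' excluded from the negativity check.
#'
#' @param data a [basket_data] object.
#' @param prior [prior_spec] used both for the BHM fit and the ESS
#'   derivation (the aggressive-borrowing preset [prior_B()] by default,
#'   under which negative ESS actually occurs).
#' @param settings [mcmc_settings] for the final fit.
#' @param ess_settings [mcmc_settings] for the enumeration fits behind the
#'   analysis-stage ESS (smaller by default: there are `K * (n_k + 1)` of
#'   them).
#' @param variant `"all_or_nothing"` (default, as used in the simulation
#'   study) or `"exclude"`.
#' @param level credible level.
#' @return A list of class `ess_ms_fit`: `fit` (a `basket_fit`), `mode`,
#'   and `ess` (the per-indication `ess_table`).
#' @export
ess_based_model_selection <- function(data, prior = prior_B(),
                                      settings = mcmc_settings(),
                                      ess_settings =
                                        mcmc_settings(2000L, 500L,
                                                      seed = settings$seed),
                                      variant = c("all_or_nothing",
                                                  "exclude"),
                                      level = 0.95) {
  variant <- match.arg(variant)
  ess <- analysis_stage_ess_all(data, prior, ess_settings)
  neg <- ess$status == "ok" & ess$prior_ess < 0
  if (!any(neg)) {
    fit <- fit_bhm(data, prior, settings, level)
    return(structure(list(fit = fit, mode = "bhm", ess = ess),
                     class = "ess_ms_fit"))
  }
  if (variant == "all_or_nothing") {
    fit <- fit_independent(data, 0.5, 0.5, level)
    return(structure(list(fit = fit, mode = "independent", ess = ess),
                     class = "ess_ms_fit"))
  }
  keep <- which(!neg)
  if (length(keep) < 2) {
    fit <- fit_independent(data, 0.5, 0.5, level)
    return(structure(list(fit = fit, mode = "independent", ess = ess),
                     class = "ess_ms_fit"))
  }
  sub <- basket_data(data$labels[keep], data$n[keep], data$y[keep])
  fit_in <- fit_bhm(sub, prior, settings, level)
  fit_out <- fit_independent(data, 0.5, 0.5, level)
  mean <- fit_out$mean; variance <- fit_out$variance
  cri <- fit_out$cri
  mean[keep] <- fit_in$mean; variance[keep] <- fit_in$variance
  cri[, keep] <- fit_in$cri
  fit <- structure(list(draws = NULL, mean = mean, variance = variance,
                        cri = cri, level = level, data = data,
                        model = "ess_ms_exclude",
                        excluded = data$labels[neg],
                        bhm_fit = fit_in, independent_fit = fit_out),
                   class = "basket_fit")
  structure(list(fit = fit, mode = "exclude", ess = ess),
            class = "ess_ms_fit")
}

#' @export
print.ess_ms_fit <- function(x, ...) {
  cat("ESS-based model selection: mode =", x$mode, "\n")
  print(x$fit)
  invisible(x)
}

#' Calibrate the posterior-probability rejection threshold
#'
#' Simulates the global-null scenario, evaluates the per-replication
#' posterior tail probabilities `Pr(p_k > null_orr | data)` once, and then
#' sweeps a grid of thresholds `phi` (cheap, since the tail probabilities
#' are cached) to find the shared `phi` whose simulated per-indication
#' rejection rate is closest to `target_alpha`. Ties break toward the
#' larger (more conservative) `phi`.
#'
#' @param scenario_null a [scenario] with every arm at the null rate.
#' @param design a [design_spec] (see [design_spec()]).
#' @param target_alpha target type I error rate (default 0.05).
#' @param reps simulated trials.
#' @param seed master seed.
#' @param settings [mcmc_settings] for MCMC designs.
#' @param grid candidate thresholds.
#' @return List with `phi`, `achieved` (overall rejection rate at `phi`),
#'   `per_arm` rates, and `attainable` (`FALSE` when even the top of the
#'   grid rejects more than `target_alpha`).
#' @export
calibrate_phi <- function(scenario_null, design, target_alpha = 0.05,
                          reps = 1000L, seed = 1L,
                          settings = mcmc_settings(),
                          grid = seq(0.5, 0.999, by = 0.001)) {
  stopifnot(inherits(scenario_null, "scenario"))
  if (any(scenario_null$true_orr != scenario_null$null_orr))
    warning("calibration scenario is not a global null")
  tails <- simulate_tail_probs(scenario_null, design, reps, seed, settings)
  rate <- vapply(grid, function(phi) mean(tails > phi), numeric(1))
  i <- which(abs(rate - target_alpha) == min(abs(rate - target_alpha)))
  i <- max(i) # ties toward larger phi
  per_arm <- colMeans(tails > grid[i])
  list(phi = grid[i], achieved = rate[i], per_arm = per_arm,
       attainable = min(rate) <= target_alpha)
}

#' Calibrate design tuning parameters against prior-ESS targets
#'
#' Grid search over `(a, b)` minimizing the sum of squared deviations
#' between the simulated design-stage prior ESS and the stated targets
#' (e.g. "prior ESS around 30 for each arm of the global alternative;
#' prior ESS 0 for the null arm of the mixed scenario"). The same
#' simulated datasets are reused across the grid so candidates are
#' compared on common Monte Carlo noise.
#'
#' @param targets a list of lists, each with elements `scenario` (a
#'   [scenario]), `indication` (arm index, or vector of indices), and
#'   `prior_ess` (target value, shared by the listed arms).
#' @param context `"cbhm"` or `"power_prior"`.
#' @param grid_a,grid_b candidate values for `a` and `b`.
#' @param reps simulated trials per scenario.
#' @param seed master seed.
#' @param settings [mcmc_settings] for CBHM fits.
#' @param s1,s2 initial Beta parameters (power prior only).
#' @return List with `tuning` (the best [tuning_pair]), `objective`, and
#'   `achieved` (simulated prior ESS at the optimum, one entry per
#'   target).
#' @export
calibrate_tuning <- function(targets, context = c("cbhm", "power_prior"),
                             grid_a = seq(-6, 6, by = 0.5),
                             grid_b = seq(0, 2, by = 0.1),
                             reps = 500L, seed = 1L,
                             settings = mcmc_settings(),
                             s1 = 0.5, s2 = 0.5) {
  context <- match.arg(context)
  if (!length(targets)) stop("targets must be nonempty", call. = FALSE)
  if (!length(grid_a) || !length(grid_b))
    stop("grid must be nonempty", call. = FALSE)
  scen_key <- vapply(targets, function(t) t$scenario$label, character(1))
  scenarios <- targets[!duplicated(scen_key)]
  ys <- lapply(seq_along(scenarios), function(j)
    simulate_trials(scenarios[[j]]$scenario, reps, seed + j))
  names(ys) <- vapply(scenarios, function(t) t$scenario$label, character(1))

  eval_pair <- function(a, b) {
    tun <- tuning_pair(a, b, context)
    ach <- numeric(length(targets))
    for (j in seq_along(targets)) {
      tg <- targets[[j]]
      scen <- tg$scenario
      y <- ys[[scen$label]]
      est <- design_estimates(y, scen, context, tun, settings, s1, s2,
                              seed)
      err <- sweep(est, 2, scen$true_orr)
      mse <- colMeans(err^2)
      pe <- vapply(tg$indication, function(k) {
        r <- ess_from_mse(mse[k], scen$true_orr[k], scen$n[k])
        if (r$status == "not_available") NA_real_ else r$prior_ess
      }, numeric(1))
      ach[j] <- mean(pe)
    }
    list(objective = sum((ach - vapply(targets, `[[`, numeric(1),
                                       "prior_ess"))^2),
         achieved = ach)
  }

  best <- NULL
  for (a in grid_a) for (b in grid_b) {
    res <- eval_pair(a, b)
    if (is.null(best) || res$objective < best$objective)
      best <- c(res, list(a = a, b = b))
  }
  list(tuning = tuning_pair(best$a, best$b, context),
       objective = best$objective, achieved = best$achieved)
}

# per-replication point estimates (posterior means) for the calibrated
# designs on a precomputed responder matrix
design_estimates <- function(y, scen, context, tuning, settings, s1, s2,
                             seed) {
  reps <- nrow(y); K <- ncol(y)
  if (context == "power_prior") {
    est <- matrix(NA_real_, reps, K)
    for (r in seq_len(reps)) {
      d <- basket_data(n = scen$n, y = y[r, ])
      est[r, ] <- fit_power_prior(d, pp_spec(tuning, s1, s2))$mean
    }
    return(est)
  }
  # CBHM: sigma2 varies per replication through T
  s2vec <- vapply(seq_len(reps), function(r) {
    d <- basket_data(n = scen$n, y = y[r, ])
    T <- chi_square_heterogeneity(d)
    if (is.na(T)) 1e4 else cbhm_sigma2(T, tuning)
  }, numeric(1))
  set.seed(seed + 17L)
  bhm_postmean_batch_cpp(y, as.numeric(scen$n), -2.19, 2,
                         TRUE, s2vec, 0, 0,
                         settings$iterations, settings$burn_in,
                         settings$thin)
}
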