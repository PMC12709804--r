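#' The five built-in study scenarios
#'
#' Four tumor types, 30 patients each, null ORR 0.15 and target ORR 0.3:
#' Scenario 1 is the global null (all 0.15), Scenario 2 the global
#' alternative (all 0.3), and Scenarios 3-5 mix one, two, or three
#' efficacious arms.
#'
#' @return Named list of [scenario] objects `S1`..`S5`.
#' @export
builtin_scenarios <- function() {
  orr <- list(S1 = c(0.15, 0.15, 0.15, 0.15),
              S2 = c(0.3, 0.3, 0.3, 0.3),
              S3 = c(0.3, 0.15, 0.15, 0.15),
              S4 = c(0.3, 0.3, 0.15, 0.15),
              S5 = c(0.3, 0.3, 0.3, 0.15))
  lapply(setNames(names(orr), names(orr)), function(s)
    scenario(orr[[s]], n = rep(30L, 4L), null_orr = 0.15,
             target_orr = 0.3, label = s))
}

#' Simulate one basket trial from a scenario
#'
#' Draws `Y_k ~ Bin(n_k, p_k)` independently per indication.
#'
#' @param scenario a [scenario] object.
#' @param seed RNG seed (reproducible: same seed, same data).
#' @return A [basket_data] object.
#' @export
generate_trial <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "scenario"))
  set.seed(seed)
  y <- rbinom(length(scenario$true_orr), scenario$n, scenario$true_orr)
  basket_data(paste0("arm", seq_along(y)), scenario$n, y)
}

#' Design specification for the simulation engine
#'
#' Bundles an analysis strategy with its parameters so the operating
#' characteristics engine and the calibration helpers can treat all
#' designs uniformly.
#'
#' @param type one of `"bhm"`, `"cbhm"`, `"power_prior"`, `"ess_ms"`,
#'   `"independent"`, `"pooled"`.
#' @param prior a [prior_spec] (`bhm` and `ess_ms`; also sets the `mu`
#'   prior of `pooled`).
#' @param tuning a [tuning_pair] (`cbhm`, `power_prior`).
#' @param beta_a,beta_b initial Beta parameters (`independent`,
#'   `power_prior`).
#' @param label display label; defaults to a description of the type.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(type = c("bhm", "cbhm", "power_prior", "ess_ms",
                                 "independent", "pooled"),
                        prior = NULL, tuning = NULL, beta_a = 0.5,
                        beta_b = 0.5, label = NULL) {
  type <- match.arg(type)
  if (type %in% c("bhm", "ess_ms") && is.null(prior))
    stop(type, " design requires a prior_spec", call. = FALSE)
  if (type %in% c("cbhm", "power_prior") && is.null(tuning))
    stop(type, " design requires a tuning_pair", call. = FALSE)
  if (type == "pooled" && is.null(prior))
    prior <- prior_spec(-2.19, 2, sigma2_fixed = 0, label = "pooled")
  if (is.null(label))
    label <- if (!is.null(prior) && type == "bhm")
      paste0("bhm/", prior$label) else type
  structure(list(type = type, prior = prior, tuning = tuning,
                 beta_a = beta_a, beta_b = beta_b, label = label),
            class = "design_spec")
}

#' Fit a design to observed data
#'
#' Dispatches to the fitter matching the [design_spec] type.
#'
#' @param design a [design_spec].
#' @param data a [basket_data].
#' @param settings [mcmc_settings] for MCMC-based designs.
#' @param level credible level.
#' @return A `basket_fit` (for `ess_ms`, the `fit` element of the
#'   selection result, with the chosen `mode` attached as attribute).
#' @export
fit_design <- function(design, data, settings = mcmc_settings(),
                       level = 0.95) {
  stopifnot(inherits(design, "design_spec"))
  switch(design$type,
    bhm = fit_bhm(data, design$prior, settings, level),
    pooled = fit_bhm(data, design$prior, settings, level),
    cbhm = fit_cbhm(data, design$tuning, settings, level = level),
    power_prior = fit_power_prior(
      data, pp_spec(design$tuning, design$beta_a, design$beta_b), level),
    independent = fit_independent(data, design$beta_a, design$beta_b,
                                  level),
    ess_ms = {
      ms <- ess_based_model_selection(data, design$prior, settings,
                                      level = level)
      fit <- ms$fit
      attr(fit, "mode") <- ms$mode
      fit
    })
}

# reps x K matrices of posterior tail probabilities and point estimates
# for a design under a scenario; the workhorse shared by calibrate_phi and
# run_operating_characteristics. Conjugate designs are evaluated in closed
# form; plain (C)BHM designs go through the batched sampler; ess_ms loops.
simulate_tail_probs <- function(scenario, design, reps, seed,
                                settings = mcmc_settings(),
                                return_estimates = FALSE) {
  y <- simulate_trials(scenario, reps, seed)
  K <- ncol(y)
  thr <- scenario$null_orr
  if (design$type == "independent") {
    a <- design$beta_a + y
    b <- design$beta_b + matrix(rep(scenario$n, each = reps), reps) - y
    tails <- pbeta(thr, a, b, lower.tail = FALSE)
    est <- a / (a + b)
  } else if (design$type == "power_prior") {
    tails <- est <- matrix(NA_real_, reps, K)
    for (r in seq_len(reps)) {
      d <- basket_data(n = scenario$n, y = y[r, ])
      f <- fit_power_prior(d, pp_spec(design$tuning, design$beta_a,
                                      design$beta_b))
      tails[r, ] <- posterior_prob(f, thr)
      est[r, ] <- f$mean
    }
  } else if (design$type %in% c("bhm", "pooled", "cbhm")) {
    if (design$type == "cbhm") {
      s2 <- vapply(seq_len(reps), function(r) {
        d <- basket_data(n = scenario$n, y = y[r, ])
        T <- chi_square_heterogeneity(d)
        if (is.na(T)) 1e4 else cbhm_sigma2(T, design$tuning)
      }, numeric(1))
      mu_mean <- -2.19; mu_sd <- 2
      fixed <- TRUE; shape <- 0; scale <- 0
    } else {
      p <- design$prior
      sp <- prior_cpp_args(p)
      s2 <- sp$value; fixed <- sp$fixed; shape <- sp$shape
      scale <- sp$scale
      mu_mean <- p$mu_mean; mu_sd <- p$mu_sd
    }
    set.seed(seed + 1L)
    res <- bhm_batch_cpp(y, as.numeric(scenario$n), mu_mean, mu_sd,
                         fixed, s2, shape, scale,
                         settings$iterations, settings$burn_in,
                         settings$thin, thr)
    tails <- res$tail_prob
    est <- res$post_mean
  } else { # ess_ms
    tails <- est <- matrix(NA_real_, reps, K)
    rep_seeds <- derive_seeds(seed, reps)
    for (r in seq_len(reps)) {
      d <- basket_data(n = scenario$n, y = y[r, ])
      st <- settings; st$seed <- rep_seeds[r]
      f <- fit_design(design, d, st)
      tails[r, ] <- posterior_prob(f, thr)
      est[r, ] <- f$mean
    }
  }
  if (return_estimates) list(tails = tails, estimates = est, y = y)
  else tails
}

derive_seeds <- function(seed, reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

#' Operating characteristics across scenarios and designs
#'
#' For each scenario x design cell: simulates trials, applies the design's
#' analysis and the posterior-probability rejection rule, and accumulates
#' the per-indication rejection rate, the MSE of the posterior-mean point
#' estimate against the true rate, and (optionally) the design-stage
#' MSE-based prior ESS derived from the pooled replication set.
#'
#' @param scenarios list of [scenario] objects (e.g.
#'   [builtin_scenarios()]).
#' @param designs list of [design_spec] objects.
#' @param phi shared rejection threshold: a single number, a named vector
#'   (one per design label), or `"calibrate"` to calibrate each design to
#'   `target_alpha` on the first scenario whose arms are all at the null
#'   rate.
#' @param reps replications per cell.
#' @param seed master seed; each cell uses a distinct derived stream.
#' @param settings [mcmc_settings].
#' @param target_alpha calibration target when `phi = "calibrate"`.
#' @param compute_ess include design-stage prior ESS columns.
#' @return A tidy data.frame of class `oc_result`: one row per scenario x
#'   design x indication with columns `scenario, design, indication,
#'   true_orr, reject_pct, mse, prior_ess, ess_status, reps, mc_se, phi`.
#' @export
run_operating_characteristics <- function(scenarios, designs,
                                          phi = "calibrate",
                                          reps = 1000L, seed = 1L,
                                          settings = mcmc_settings(),
                                          target_alpha = 0.05,
                                          compute_ess = TRUE) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  if (inherits(designs, "design_spec")) designs <- list(designs)
  labels <- vapply(designs, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("design labels must be unique", call. = FALSE)

  phis <- setNames(numeric(length(designs)), labels)
  if (identical(phi, "calibrate")) {
    is_null_scen <- vapply(scenarios, function(s)
      all(s$true_orr == s$null_orr), logical(1))
    if (!any(is_null_scen))
      stop("phi = 'calibrate' needs a global-null scenario", call. = FALSE)
    s0 <- scenarios[[which(is_null_scen)[1]]]
    for (j in seq_along(designs)) {
      cal <- calibrate_phi(s0, designs[[j]], target_alpha,
                           reps = reps, seed = seed + 7919L * j,
                           settings = settings)
      phis[j] <- cal$phi
    }
  } else if (length(phi) == 1L && is.numeric(phi)) {
    phis[] <- phi
  } else {
    phis[] <- phi[labels]
  }

  out <- list()
  cell <- 0L
  for (si in seq_along(scenarios)) for (dj in seq_along(designs)) {
    cell <- cell + 1L
    scen <- scenarios[[si]]
    des <- designs[[dj]]
    sim <- simulate_tail_probs(scen, des, reps,
                               seed + 104729L * cell, settings,
                               return_estimates = TRUE)
    rej <- colMeans(sim$tails > phis[dj])
    err <- sweep(sim$estimates, 2, scen$true_orr)
    mse <- colMeans(err^2)
    K <- length(scen$true_orr)
    prior_ess <- rep(NA_real_, K)
    ess_status <- rep(NA_character_, K)
    if (compute_ess) {
      for (k in seq_len(K)) {
        r <- ess_from_mse(mse[k], scen$true_orr[k], scen$n[k])
        ess_status[k] <- r$status
        if (r$status != "not_available") prior_ess[k] <- r$prior_ess
      }
    }
    out[[cell]] <- data.frame(
      scenario = scen$label, design = des$label,
      indication = paste0("arm", seq_len(K)),
      true_orr = scen$true_orr,
      reject_pct = 100 * rej, mse = mse, prior_ess = prior_ess,
      ess_status = ess_status, reps = reps,
      mc_se = 100 * sqrt(rej * (1 - rej) / reps),
      phi = unname(phis[dj]), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  class(res) <- c("oc_result", "data.frame")
  res
}

#' Average operating characteristics over arms with the same true ORR
#'
#' Within each scenario x design cell, arms sharing a true response rate
#' are exchangeable, so their metrics are averaged; groups are labelled
#' `"A"` (alternative, ORR above the null) or `"N"` (null).
#'
#' @param results an `oc_result` data.frame.
#' @param null_orr the null rate used for the A/N labels (default 0.15).
#' @return A grouped data.frame with columns `scenario, design, group,
#'   true_orr, n_arms, reject_pct, mse, prior_ess`.
#' @export
summarize_by_truth <- function(results, null_orr = 0.15) {
  stopifnot(inherits(results, "data.frame"), nrow(results) > 0)
  key <- interaction(results$scenario, results$design, results$true_orr,
                     drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    data.frame(scenario = g$scenario[1], design = g$design[1],
               group = if (g$true_orr[1] > null_orr) "A" else "N",
               true_orr = g$true_orr[1], n_arms = nrow(g),
               reject_pct = mean(g$reject_pct), mse = mean(g$mse),
               prior_ess = mean(g$prior_ess),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scenario, out$design, -out$true_orr), ]
  rownames(out) <- NULL
  out
}

#' Reshape tidy operating characteristics into a wide per-scenario table
#'
#' One row per scenario x indication, one column block per design, with
#' ESS to one decimal, MSE in units of 1e-3, and rejection percentages to
#' one decimal — the reporting precision used throughout.
#'
#' @param results an `oc_result` data.frame.
#' @return A wide data.frame.
#' @export
oc_wide_table <- function(results) {
  designs <- unique(results$design)
  base <- unique(results[c("scenario", "indication", "true_orr")])
  out <- base
  for (d in designs) {
    g <- results[results$design == d, ]
    m <- match(interaction(base$scenario, base$indication),
               interaction(g$scenario, g$indication))
    out[[paste0(d, ".prior_ess")]] <- round(g$prior_ess[m], 1)
    out[[paste0(d, ".mse_x1e3")]] <- round(1000 * g$mse[m], 1)
    out[[paste0(d, ".reject_pct")]] <- round(g$reject_pct[m], 1)
  }
  out
}
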