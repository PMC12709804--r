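#' Full per-indication analysis report
#'
#' The analysis-stage workflow for observed basket-trial data: per
#' indication, the frequentist estimate with an exact Clopper-Pearson
#' interval, the BHM posterior mean with an equal-tailed credible
#' interval, the analysis-stage MSE-based prior ESS (`NA` for arms with
#' observed ORR 0% or 100%), and a posterior summary of the between-group
#' variance.
#'
#' @param data a [basket_data] object or path to a CSV in the
#'   `indication,n,y` dialect.
#' @param prior a [prior_spec]; [prior_A()] by default.
#' @param level confidence/credible level.
#' @param settings [mcmc_settings] for the main fit.
#' @param ess_settings [mcmc_settings] for the analysis-stage ESS
#'   enumeration (one fit per possible own-arm outcome).
#' @param ess compute the prior ESS column (the expensive part).
#' @return A data.frame of class `basket_report` with one row per
#'   indication and an attached `sigma2` posterior summary attribute.
#' @export
analyze_basket <- function(data, prior = prior_A(), level = 0.95,
                           settings = mcmc_settings(20000L, 5000L),
                           ess_settings = mcmc_settings(
                             seed = settings$seed),
                           ess = TRUE) {
  if (is.character(data)) data <- read_basket_csv(data)
  stopifnot(inherits(data, "basket_data"))
  fit <- fit_bhm(data, prior, settings, level)
  cp <- t(vapply(seq_len(data$K), function(k)
    clopper_pearson(data$y[k], data$n[k], level), numeric(2)))
  out <- data.frame(indication = data$labels, n = data$n, y = data$y,
                    orr = data$y / data$n,
                    ci_lower = cp[, 1], ci_upper = cp[, 2],
                    post_mean = unname(fit$mean),
                    cri_lower = fit$cri["lower", ],
                    cri_upper = fit$cri["upper", ],
                    prior_ess = NA_real_,
                    ess_status = NA_character_,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (ess) {
    for (k in seq_len(data$K)) {
      r <- analysis_stage_ess(data, prior, k, ess_settings)
      out$ess_status[k] <- r$status
      if (r$status != "not_available") out$prior_ess[k] <- r$prior_ess
    }
  }
  attr(out, "sigma2") <- quantile(fit$sigma2_draws, c(0.025, 0.5, 0.975))
  attr(out, "prior") <- prior$label
  attr(out, "pooled_orr") <- sum(data$y) / sum(data$n)
  class(out) <- c("basket_report", "data.frame")
  out
}

#' @export
print.basket_report <- function(x, ...) {
  cat("Basket analysis [", attr(x, "prior"), "], pooled ORR ",
      round(100 * attr(x, "pooled_orr"), 1), "%\n", sep = "")
  df <- x; class(df) <- "data.frame"
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  s2 <- attr(x, "sigma2")
  if (!is.null(s2))
    cat("sigma2 posterior (2.5/50/97.5%):",
        paste(signif(s2, 3), collapse = " / "), "\n")
  invisible(x)
}

#' Read and validate a run configuration
#'
#' YAML with top-level blocks `data` (path), `prior`
#' (`preset: A|B` or explicit `mu_mean/mu_sd/sigma2_shape/sigma2_scale/
#' sigma2_fixed`), `design` (`type` plus per-design parameters),
#' `simulation` (`reps`, `phi`), `mcmc` (`iterations`, `burn_in`, `thin`),
#' `seed`, and `output`. Unknown top-level keys are rejected so typos do
#' not silently fall back to defaults.
#'
#' @param path path to the YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("data", "prior", "design", "simulation", "mcmc", "seed",
             "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = c("run_config", class(cfg)))
}

config_prior <- function(cfg) {
  pb <- cfg$prior
  if (is.null(pb) || identical(toupper(pb$preset %||% ""), "A"))
    return(prior_A())
  if (identical(toupper(pb$preset %||% ""), "B")) return(prior_B())
  prior_spec(pb$mu_mean %||% -2.19, pb$mu_sd %||% 2,
             sigma2_shape = pb$sigma2_shape,
             sigma2_scale = pb$sigma2_scale,
             sigma2_fixed = pb$sigma2_fixed,
             label = pb$label %||% "config")
}

config_mcmc <- function(cfg, default_seed = 1L) {
  mb <- cfg$mcmc
  mcmc_settings(mb$iterations %||% 5000L, mb$burn_in %||% 2000L,
                mb$thin %||% 1L, cfg$seed %||% default_seed)
}

config_design <- function(cfg) {
  db <- cfg$design
  if (is.null(db)) return(design_spec("bhm", prior = config_prior(cfg)))
  type <- db$type %||% "bhm"
  tuning <- if (!is.null(db$a))
    tuning_pair(db$a, db$b,
                if (type == "cbhm") "cbhm" else "power_prior")
  design_spec(type, prior = config_prior(cfg), tuning = tuning,
              beta_a = db$beta_a %||% 0.5, beta_b = db$beta_b %||% 0.5,
              label = db$label %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a machine-readable run manifest
#'
#' Records everything needed to reproduce a run: seed, replication count,
#' package version, and the resolved parameter values.
#'
#' @param path output JSON path.
#' @param ... named fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package <- "essbasket"
  fields$version <- as.character(utils::packageVersion("essbasket"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write synthetic example datasets
#'
#' Generates one CSV per built-in scenario (plus a heterogeneous example
#' with an extreme arm) so the file-based workflow can be exercised
#' without real data.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return Character vector of the written paths.
#' @export
write_fixture_csvs <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scens <- builtin_scenarios()
  paths <- character(0)
  for (i in seq_along(scens)) {
    d <- generate_trial(scens[[i]], seed + i)
    p <- file.path(dir, paste0("synthetic_", names(scens)[i], ".csv"))
    write_basket_csv(d, p)
    paths <- c(paths, p)
  }
  extreme <- basket_data(c("resp_none", "resp_low", "resp_mid",
                           "resp_high"),
                         n = c(12L, 30L, 30L, 8L), y = c(0L, 5L, 9L, 7L))
  p <- file.path(dir, "synthetic_extreme.csv")
  write_basket_csv(extreme, p)
  c(paths, p)
}
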