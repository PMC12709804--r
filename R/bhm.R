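#' MCMC settings for the hierarchical model sampler
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in iterations discarded (must be below `iterations`).
#' @param thin keep every `thin`-th draw.
#' @param seed integer RNG seed; every fit is reproducible given the seed.
#' @return An object of class `mcmc_settings`.
#' @details The defaults (5000/2000) are sized for simulation loops; for a
#'   single-dataset analysis use e.g. `mcmc_settings(20000, 5000)`.
#' @export
mcmc_settings <- function(iterations = 5000L, burn_in = 2000L, thin = 1L,
                          seed = 1L) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= iterations) stop("burn_in must be < iterations", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

prior_cpp_args <- function(prior) {
  fixed <- !is.null(prior$sigma2_fixed)
  list(fixed = fixed,
       value = if (fixed) prior$sigma2_fixed else 0,
       shape = if (fixed) 0 else prior$sigma2_shape,
       scale = if (fixed) 0 else prior$sigma2_scale)
}

new_basket_fit <- function(draws, data, level, extra = list(),
                           class = character()) {
  mean <- colMeans(draws)
  variance <- apply(draws, 2, function(x) mean((x - mean(x))^2))
  alpha <- 1 - level
  cri <- apply(draws, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
               names = FALSE)
  structure(c(list(draws = draws, mean = setNames(mean, data$labels),
                   variance = setNames(variance, data$labels),
                   cri = matrix(cri, nrow = 2,
                                dimnames = list(c("lower", "upper"),
                                                data$labels)),
                   level = level, data = data),
              extra),
            class = c(class, "basket_fit"))
}

#' Fit the Bayesian hierarchical model to basket-trial data
#'
#' Binomial BHM on the log-odds scale: `Y_k ~ Bin(n_k, p_k)`,
#' `logit(p_k) = theta_k ~ N(mu, sigma2)`, with a normal prior on `mu` and
#' an inverse-gamma hyperprior (or fixed value) on `sigma2`. Sampling is a
#' Gibbs scheme with conjugate updates for `mu` and `sigma2`, slice updates
#' for each `theta_k`, and a joint translation move that keeps mixing
#' healthy under strong borrowing (`sigma2` near 0). `sigma2` fixed at 0 is
#' handled as the exact pooled model (a single logit parameter).
#'
#' @param data a [basket_data] object.
#' @param prior a [prior_spec]; see [prior_A()], [prior_B()].
#' @param settings an [mcmc_settings] object.
#' @param level credible-interval level (default 0.95).
#' @return An object of classes `bhm_fit`/`basket_fit` with posterior draws
#'   of `p_k` (`draws`), per-indication posterior `mean`, `variance` and
#'   equal-tailed credible intervals (`cri`), plus `mu_draws` and
#'   `sigma2_draws`.
#' @examples
#' d <- basket_data(n = c(30, 30, 30, 30), y = c(6, 5, 7, 6))
#' fit <- fit_bhm(d, prior_A(), mcmc_settings(2000, 500, seed = 7))
#' coef(fit)
#' @export
fit_bhm <- function(data, prior, settings = mcmc_settings(), level = 0.95) {
  stopifnot(inherits(data, "basket_data"), inherits(prior, "prior_spec"),
            inherits(settings, "mcmc_settings"))
  sp <- prior_cpp_args(prior)
  set.seed(settings$seed)
  res <- bhm_gibbs_cpp(as.numeric(data$y), as.numeric(data$n),
                       prior$mu_mean, prior$mu_sd,
                       sp$fixed, sp$value, sp$shape, sp$scale,
                       settings$iterations, settings$burn_in, settings$thin)
  theta <- res$theta
  if (any(!is.finite(theta)))
    stop("BHM sampler produced nonfinite draws (data: y = ",
         paste(data$y, collapse = ","), ")", call. = FALSE)
  p_draws <- plogis_mat(theta)
  colnames(p_draws) <- data$labels
  new_basket_fit(p_draws, data, level,
                 extra = list(mu_draws = res$mu, sigma2_draws = res$sigma2,
                              prior = prior, settings = settings,
                              model = "bhm"),
                 class = "bhm_fit")
}

plogis_mat <- function(theta) 1 / (1 + exp(-theta))

#' Independent Beta-binomial analysis
#'
#' Conjugate per-indication posteriors `Beta(a + y_k, b + n_k - y_k)`; no
#' sampling involved. The default `Beta(0.5, 0.5)` is the vague prior used
#' for independent analysis.
#'
#' @param data a [basket_data] object.
#' @param beta_a,beta_b positive parameters of the initial Beta prior.
#' @param level credible-interval level.
#' @param n_draws optional number of posterior draws to attach (the summary
#'   itself is closed-form; draws are only for interoperability).
#' @param seed seed used when `n_draws > 0`.
#' @return An `independent_fit`/`basket_fit` object with exact moments,
#'   intervals and the Beta parameters in `beta_par`.
#' @export
fit_independent <- function(data, beta_a = 0.5, beta_b = 0.5, level = 0.95,
                            n_draws = 0L, seed = 1L) {
  stopifnot(inherits(data, "basket_data"))
  if (beta_a <= 0 || beta_b <= 0)
    stop("Beta parameters must be positive", call. = FALSE)
  a <- beta_a + data$y
  b <- beta_b + data$n - data$y
  fit_conjugate_beta(data, a, b, level, n_draws, seed,
                     extra = list(model = "independent",
                                  beta_prior = c(beta_a, beta_b)),
                     class = "independent_fit")
}

fit_conjugate_beta <- function(data, a, b, level, n_draws, seed, extra,
                               class) {
  mean <- a / (a + b)
  variance <- a * b / ((a + b)^2 * (a + b + 1))
  alpha <- 1 - level
  cri <- rbind(lower = qbeta(alpha / 2, a, b),
               upper = qbeta(1 - alpha / 2, a, b))
  colnames(cri) <- data$labels
  draws <- NULL
  if (n_draws > 0L) {
    set.seed(seed)
    draws <- vapply(seq_along(a), function(k) rbeta(n_draws, a[k], b[k]),
                    numeric(n_draws))
    colnames(draws) <- data$labels
  }
  structure(c(list(beta_par = rbind(a = a, b = b), draws = draws,
                   mean = setNames(mean, data$labels),
                   variance = setNames(variance, data$labels),
                   cri = cri, level = level, data = data),
              extra),
            class = c(class, "basket_fit"))
}

#' Posterior probability of exceeding a response threshold
#'
#' `Pr(p_k > threshold | data)` per indication: exact Beta tails for
#' conjugate fits (independent analysis, power prior), Monte Carlo
#' frequency over the draws for MCMC fits.
#'
#' @param fit a `basket_fit` object.
#' @param threshold response-rate threshold (e.g. the null ORR 0.15).
#' @return Named numeric vector of tail probabilities.
#' @export
posterior_prob <- function(fit, threshold) {
  stopifnot(inherits(fit, "basket_fit"))
  if (!is.null(fit$beta_par))
    return(setNames(pbeta(threshold, fit$beta_par["a", ],
                          fit$beta_par["b", ], lower.tail = FALSE),
                    fit$data$labels))
  if (is.null(fit$draws) || nrow(fit$draws) == 0)
    stop("fit has no posterior draws", call. = FALSE)
  colMeans(fit$draws > threshold)
}

#' Per-indication rejection of the null hypothesis
#'
#' Rejects `H0k: p_k <= threshold_rate` when
#' `Pr(p_k > threshold_rate | data) > phi`.
#'
#' @param fit a `basket_fit` object.
#' @param threshold_rate null response rate.
#' @param phi posterior-probability cutoff in (0, 1).
#' @return Named logical vector.
#' @export
posterior_reject <- function(fit, threshold_rate, phi) {
  if (phi <= 0 || phi >= 1) stop("phi must be in (0, 1)", call. = FALSE)
  posterior_prob(fit, threshold_rate) > phi
}

#' @export
print.basket_fit <- function(x, ...) {
  cat("Basket fit [", x$model, "], K = ", x$data$K, "\n", sep = "")
  print(round(cbind(mean = x$mean, var = x$variance, t(x$cri)), 4))
  invisible(x)
}

#' @export
coef.basket_fit <- function(object, ...) object$mean

#' @export
summary.basket_fit <- function(object, null_orr = 0.15, ...) {
  out <- data.frame(indication = object$data$labels,
                    n = object$data$n, y = object$data$y,
                    orr = object$data$y / object$data$n,
                    post_mean = unname(object$mean),
                    post_var = unname(object$variance),
                    cri_lower = object$cri["lower", ],
                    cri_upper = object$cri["upper", ],
                    pr_above_null = unname(posterior_prob(object, null_orr)),
                    row.names = NULL)
  if (!is.null(object$sigma2_draws)) {
    attr(out, "sigma2") <- quantile(object$sigma2_draws,
                                    c(0.025, 0.5, 0.975))
  }
  class(out) <- c("summary.basket_fit", "data.frame")
  out
}

#' @export
print.summary.basket_fit <- function(x, ...) {
  df <- x; class(df) <- "data.frame"
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "sigma2")))
    cat("sigma2 posterior (2.5/50/97.5%):",
        paste(signif(attr(x, "sigma2"), 3), collapse = " / "), "\n")
  invisible(x)
}

#' @export
plot.basket_fit <- function(x, null_orr = 0.15, ...) {
  K <- x$data$K
  plot(seq_len(K), x$mean, ylim = c(0, 1), pch = 19, xaxt = "n",
       xlab = "indication", ylab = "response rate",
       main = paste("Posterior ORR estimates (", x$model, ")", sep = ""),
       ...)
  axis(1, at = seq_len(K), labels = x$data$labels)
  segments(seq_len(K), x$cri["lower", ], seq_len(K), x$cri["upper", ])
  points(seq_len(K), x$data$y / x$data$n, pch = 4, col = "grey40")
  abline(h = null_orr, lty = 2)
  invisible(x)
}

#' Export posterior draws as CSV
#'
#' Long format: draw index, indication, `p`, plus `mu` and `sigma2` columns
#' where available.
#'
#' @param fit a `basket_fit` with draws.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "basket_fit"))
  if (is.null(fit$draws)) stop("fit has no draws to export", call. = FALSE)
  m <- nrow(fit$draws)
  df <- data.frame(draw = rep(seq_len(m), fit$data$K),
                   indication = rep(fit$data$labels, each = m),
                   p = as.vector(fit$draws))
  if (!is.null(fit$mu_draws)) df$mu <- rep(fit$mu_draws, fit$data$K)
  if (!is.null(fit$sigma2_draws))
    df$sigma2 <- rep(fit$sigma2_draws, fit$data$K)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
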