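test_that("independent MSE is the binomial variance of the MLE", {
  expect_equal(independent_mse(0, 25), 0)
  expect_equal(independent_mse(0.5, 10), 0.025)
  expect_error(independent_mse(0.3, 0), "positive")
  expect_error(independent_mse(0.3, -5), "positive")
  # Monte Carlo oracle at p = 0.3, n = 30
  set.seed(99)
  sim <- mean((rbinom(2e5, 30, 0.3) / 30 - 0.3)^2)
  se <- sd((rbinom(2e5, 30, 0.3) / 30 - 0.3)^2) / sqrt(2e5)
  expect_lt(abs(independent_mse(0.3, 30) - sim), 3 * se)
})

test_that("MSE matching returns prior ESS 0 at the enrolled sample size", {
  r <- ess_from_mse(independent_mse(0.15, 30), p = 0.15, n = 30)
  expect_equal(r$status, "ok")
  expect_equal(r$prior_ess, 0)
  expect_equal(r$posterior_ess, 30)
})

test_that("degenerate rates make the ESS unavailable", {
  expect_equal(ess_from_mse(1e-3, p = 0, n = 30)$status, "not_available")
  expect_equal(ess_from_mse(1e-3, p = 1, n = 30)$status, "not_available")
  r <- ess_from_mse(1e-3, p = 0, n = 30)
  expect_true(is.na(r$posterior_ess) && is.na(r$prior_ess))
})

test_that("grid + interpolation tracks the closed-form ESS within 0.2", {
  # closed form: MSE of an independent analysis of size N is p(1-p)/N, so
  # the matching point is N* = p(1-p)/MSE exactly
  set.seed(7)
  worst <- 0
  for (i in 1:200) {
    p <- runif(1, 0.02, 0.98)
    n <- sample(5:80, 1)
    target_n <- runif(1, 1.2, 8 * n) # implied posterior ESS
    mse <- p * (1 - p) / target_n
    r <- ess_from_mse(mse, p, n)
    expect_equal(r$status, "ok")
    dev <- abs(r$posterior_ess - p * (1 - p) / mse)
    worst <- max(worst, dev)
    expect_equal(r$prior_ess, r$posterior_ess - n)
  }
  expect_lte(worst, 0.2)
})

test_that("out-of-grid matching points are flagged as capped", {
  r <- ess_from_mse(1e-9, p = 0.3, n = 30, m_max = 500)
  expect_equal(r$status, "capped")
  expect_equal(r$prior_ess, 500)
  r2 <- ess_from_mse(0.5, p = 0.3, n = 30) # worse than a single obs
  expect_equal(r2$status, "capped")
})

test_that("design-stage MSE obeys the variance + bias^2 decomposition", {
  scen <- scenario(rep(0.2, 3), n = rep(15L, 3), label = "homog")
  sim <- design_stage_mse_bayes(scen, prior_A(), reps = 60, seed = 3,
                                settings = mcmc_settings(1500, 500))
  # identity on the same draws (population variance), exact
  for (k in 1:3) {
    err <- sim$estimates[, k] - 0.2
    expect_equal(sim$mse[[k]], mean(err^2))
    expect_equal(sim$mse[[k]], sim$variance[k] + sim$bias[k]^2,
                 tolerance = 1e-12)
  }
  expect_equal(dim(sim$estimates), c(60L, 3L))
})

test_that("strong borrowing beats independent MSE under homogeneity", {
  scen <- scenario(rep(0.2, 4), n = rep(20L, 4), label = "homog")
  pr <- prior_spec(-2.19, 2, sigma2_fixed = 1e-4)
  sim <- design_stage_mse_bayes(scen, pr, reps = 150, seed = 5,
                                settings = mcmc_settings(1500, 500))
  expect_true(all(sim$mse < independent_mse(0.2, 20)))
})

test_that("design-stage ESS table is consistent and relabel-invariant", {
  scen <- scenario(c(0.2, 0.2), n = c(20L, 20L), label = "sym")
  tab <- design_stage_ess(scen, prior_A(), reps = 80, seed = 6,
                          settings = mcmc_settings(1500, 500))
  expect_s3_class(tab, "ess_table")
  ok <- tab$status == "ok"
  expect_equal(tab$prior_ess[ok], tab$posterior_ess[ok] - 20)
  # matched independent MSE reproduces the Bayesian MSE (interpolation)
  expect_equal(tab$mse_independent_at_match[ok], tab$mse_bayes[ok],
               tolerance = 0.02)
  # identical (n, p) arms are exchangeable: same inputs, same seed policy
  expect_lt(abs(tab$prior_ess[1] - tab$prior_ess[2]),
            6 * attr(tab, "ess_se")[1])
})

test_that("analysis-stage ESS: boundary arms are unavailable", {
  d <- basket_data(n = rep(30L, 3), y = c(0L, 6L, 30L))
  expect_equal(analysis_stage_ess(d, prior_A(), 1)$status,
               "not_available")
  expect_equal(analysis_stage_ess(d, prior_A(), 3)$status,
               "not_available")
})

test_that("analysis-stage ESS matches a brute-force re-implementation", {
  d <- basket_data(n = c(10L, 10L), y = c(3L, 3L))
  st <- mcmc_settings(4000, 1000, seed = 17)
  r <- analysis_stage_ess(d, prior_A(), 1, st)
  # independent path: loop y' explicitly, call the quadrature-validated
  # fitter one dataset at a time, then invert the closed-form MSE map
  phat <- 0.3
  est <- vapply(0:10, function(yp) {
    dd <- basket_data(n = c(10L, 10L), y = c(yp, 3L))
    coef(fit_bhm(dd, prior_A(), st))[1]
  }, numeric(1))
  mse_b <- sum(dbinom(0:10, 10, phat) * (est - phat)^2)
  ess_ref <- phat * (1 - phat) / mse_b
  expect_equal(r$status, "ok")
  expect_lt(abs(r$posterior_ess - ess_ref), 0.05 * ess_ref)
})

test_that("agreeing indications yield positive prior ESS at analysis", {
  d <- basket_data(n = rep(20L, 4), y = rep(5L, 4))
  st <- mcmc_settings(2000, 500, seed = 19)
  for (pr in list(prior_A(), prior_B())) {
    r <- analysis_stage_ess(d, pr, 2, st)
    expect_equal(r$status, "ok")
    expect_gt(r$prior_ess, 0)
  }
})

test_that("variance-ratio ESS reproduces the Beta identity", {
  d <- basket_data(n = c(20L, 20L), y = c(6L, 9L))
  f <- fit_independent(d, 0.5, 0.5)
  for (k in 1:2) {
    r <- variance_ratio_ess(f, d, k)
    a <- unname(f$beta_par["a", k]); b <- unname(f$beta_par["b", k])
    expect_equal(r$posterior_ess, a + b + 1)
    expect_equal(r$prior_ess, a + b + 1 - 20)
    expect_equal(r$method, "variance_ratio")
  }
  # inverse proportionality in the posterior variance
  f2 <- f; f2$variance <- f$variance / 2
  expect_equal(variance_ratio_ess(f2, d, 1)$posterior_ess,
               2 * variance_ratio_ess(f, d, 1)$posterior_ess)
  # degenerate observed rate
  dz <- basket_data(n = c(20L, 20L), y = c(0L, 9L))
  fz <- fit_independent(dz, 0.5, 0.5)
  expect_equal(variance_ratio_ess(fz, dz, 1)$status, "not_available")
})

test_that("VR and MSE prior ESS agree on homogeneous synthetic data", {
  d <- basket_data(n = rep(30L, 4), y = rep(6L, 4))
  st <- mcmc_settings(4000, 1000, seed = 23)
  f <- fit_bhm(d, prior_A(), st)
  vr <- variance_ratio_ess(f, d, 1)
  mse <- analysis_stage_ess(d, prior_A(), 1, st)
  # same order of magnitude and sign under homogeneity
  expect_gt(vr$prior_ess, 0)
  expect_gt(mse$prior_ess, 0)
  expect_lt(abs(vr$prior_ess - mse$prior_ess),
            0.6 * max(vr$prior_ess, mse$prior_ess))
})
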