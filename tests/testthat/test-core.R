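test_that("basket_data validates counts, lengths and labels", {
  d <- basket_data(c("a", "b"), n = c(30, 20), y = c(6, 0))
  expect_s3_class(d, "basket_data")
  expect_equal(d$K, 2L)
  expect_error(basket_data(c("a", "b"), n = 30, y = c(1, 2)), "length")
  expect_error(basket_data(c("a", "a"), n = c(10, 10), y = c(1, 2)),
               "duplicated")
  expect_error(basket_data(c("a", "b"), n = c(10, 10), y = c(11, 2)),
               "exceed")
  expect_error(basket_data("a", n = 10, y = -1), "nonnegative")
  expect_error(basket_data("a", n = 10.5, y = 1), "integers")
})

test_that("basket CSV round-trips and rejects malformed rows", {
  d <- basket_data(c("lung", "breast", "cns"), n = c(30, 16, 7),
                   y = c(6, 5, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_basket_csv(d, path)
  d2 <- read_basket_csv(path)
  expect_equal(d2, d)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("indication,n,y", "a,10,3", "b,10,12", "c,-5,1"), bad)
  expect_error(read_basket_csv(bad), "row\\(s\\) 2, 3")
  writeLines(c("tumor,count", "a,1"), bad)
  expect_error(read_basket_csv(bad), "columns")
})

test_that("conjugate Beta ESS is the parameter sum and rejects bad input", {
  expect_identical(beta_conjugate_ess(0.5, 0.5), 1.0)
  expect_identical(beta_conjugate_ess(1, 1), 2.0)
  expect_identical(beta_conjugate_ess(0.375, 1.5), 1.875)
  expect_error(beta_conjugate_ess(0, 1), "positive")
  expect_error(beta_conjugate_ess(1, -2), "positive")
})

test_that("Clopper-Pearson matches the published breast-cancer interval", {
  # 5/16 responders: point estimate 31.3%, 95% CI (11.0%, 58.7%)
  expect_lt(abs(5 / 16 - 0.313), 6e-4)
  ci <- clopper_pearson(5, 16, 0.95)
  expect_equal(unname(round(ci, 3)), c(0.110, 0.587))
})

test_that("Clopper-Pearson hits exact bounds and agrees with binom.test", {
  expect_equal(unname(clopper_pearson(0, 10)[1]), 0)
  expect_equal(unname(clopper_pearson(10, 10)[2]), 1)
  for (y in c(1, 3, 7)) {
    ref <- binom.test(y, 10)$conf.int
    expect_equal(unname(clopper_pearson(y, 10)), as.numeric(ref),
                 tolerance = 1e-8)
  }
  expect_error(clopper_pearson(11, 10), "exceed")
})

test_that("Clopper-Pearson intervals contain y/n and shrink with n", {
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    ci <- clopper_pearson(round(0.3 * n), n)
    expect_true(ci[1] <= 0.3 & 0.3 <= ci[2])
    unname(diff(ci))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("exact binomial rule matches brute-force tail enumeration", {
  # independent oracle: scan all c and take the smallest valid one
  brute <- function(n, p0, alpha) {
    tails <- vapply(0:n, function(c) sum(dbinom(c:n, n, p0)), numeric(1))
    (0:n)[which(tails <= alpha)[1]]
  }
  expect_identical(exact_binomial_rule(30, 0.15, 0.05), 9L)
  expect_identical(exact_binomial_rule(30, 0.15, 0.05),
                   as.integer(brute(30, 0.15, 0.05)))
  expect_identical(exact_binomial_rule(10, 0.5, 0.05),
                   as.integer(brute(10, 0.5, 0.05)))
  expect_identical(exact_binomial_rule(30, 0.15, 1.0), 0L)
})

test_that("exact binomial power behaves at boundaries and is monotone", {
  expect_lte(exact_binomial_power(30, 0.15, 0.15, 0.05), 0.05)
  expect_equal(exact_binomial_power(30, 0.15, 1.0, 0.05), 1.0)
  p1 <- seq(0.05, 0.95, by = 0.05)
  pow <- vapply(p1, function(p) exact_binomial_power(30, 0.15, p, 0.05),
                numeric(1))
  expect_true(all(diff(pow) >= 0))
})

test_that("chi-square heterogeneity matches the brute-force table", {
  d0 <- basket_data(n = rep(30L, 4), y = rep(6L, 4))
  expect_equal(chi_square_heterogeneity(d0), 0)
  d1 <- basket_data(n = c(30L, 30L), y = c(3L, 9L))
  expect_equal(chi_square_heterogeneity(d1), oracle_chisq(c(3, 9), c(30, 30)))
  # agrees with stats::chisq.test (uncorrected Pearson) as a second check
  ref <- suppressWarnings(
    chisq.test(cbind(c(3, 9), c(27, 21)), correct = FALSE)$statistic)
  expect_equal(chi_square_heterogeneity(d1), unname(ref))
  # permutation invariance
  d2 <- basket_data(n = c(20L, 30L, 25L), y = c(2L, 9L, 5L))
  d2p <- basket_data(n = c(25L, 20L, 30L), y = c(5L, 2L, 9L))
  expect_equal(chi_square_heterogeneity(d2), chi_square_heterogeneity(d2p))
  # zero iff all observed proportions equal
  expect_gt(chi_square_heterogeneity(d2), 0)
  # degenerate pooled rate flagged, not errored
  dz <- basket_data(n = c(10L, 10L), y = c(0L, 0L))
  expect_true(is.na(chi_square_heterogeneity(dz)))
  expect_equal(attr(chi_square_heterogeneity(dz), "status"),
               "not_computable")
})

test_that("binary KS statistic reduces to the proportion gap", {
  expect_equal(ks_binary(6, 30, 6, 30), list(s_ks = 0, s = 0))
  r <- ks_binary(6, 30, 15, 30)
  expect_equal(r$s_ks, 0.3)
  expect_equal(r$s, 30^0.25 * 0.3)
  # symmetry and bounds over random count pairs
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    y1 <- sample(0:n1, 1); y2 <- sample(0:n2, 1)
    a <- ks_binary(y1, n1, y2, n2); b <- ks_binary(y2, n2, y1, n1)
    expect_equal(a$s_ks, b$s_ks)
    expect_equal(a$s, b$s)
    expect_gte(a$s_ks, 0); expect_lte(a$s_ks, 1)
    # matches stats::ks.test on the expanded binary samples
    x1 <- rep(c(1, 0), c(y1, n1 - y1)); x2 <- rep(c(1, 0), c(y2, n2 - y2))
    if (y1 %in% c(0, n1) || y2 %in% c(0, n2)) next
    ref <- suppressWarnings(ks.test(x1, x2)$statistic)
    expect_equal(a$s_ks, unname(ref))
  }
})
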