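#' Basket-trial summary data
#'
#' Container for observed per-indication counts of a single-arm basket trial:
#' `K` indications, each with an enrolled sample size `n_k` and a responder
#' count `y_k`.
#'
#' @param labels character vector of indication (tumor type) names.
#' @param n integer vector of enrolled patients per indication.
#' @param y integer vector of responders per indication, `0 <= y_k <= n_k`.
#'
#' @return An object of class `basket_data`: a list with elements `labels`,
#'   `n`, `y` and `K`.
#' @examples
#' basket_data(c("lung", "breast"), n = c(30, 30), y = c(6, 12))
#' @export
basket_data <- function(labels = NULL, n, y) {
  if (is.null(labels)) labels <- paste0("indication_", seq_along(n))
  labels <- as.character(labels)
  if (length(labels) != length(n) || length(n) != length(y))
    stop("labels, n and y must have the same length", call. = FALSE)
  if (length(n) < 1L) stop("at least one indication is required", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicated indication labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  check_count(n, "n", positive = TRUE)
  check_count(y, "y")
  if (any(y > n)) {
    bad <- which(y > n)
    stop("responders exceed enrolled (y > n) for indication(s): ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, n = as.integer(n), y = as.integer(y),
                 K = length(n)),
            class = "basket_data")
}

check_count <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x != round(x)))
    stop(name, " must be finite integers", call. = FALSE)
  if (positive && any(x <= 0))
    stop(name, " must be positive", call. = FALSE)
  if (!positive && any(x < 0))
    stop(name, " must be nonnegative", call. = FALSE)
  invisible(x)
}

#' @export
print.basket_data <- function(x, ...) {
  cat("Basket trial data:", x$K, "indication(s)\n")
  print(data.frame(indication = x$labels, n = x$n, y = x$y,
                   orr = round(x$y / x$n, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.basket_data <- function(x, ...) {
  data.frame(indication = x$labels, n = x$n, y = x$y,
             stringsAsFactors = FALSE)
}

#' Read basket-trial data from CSV
#'
#' Expects a UTF-8 CSV with header `indication,n,y`, one row per indication.
#' Rows with inconsistent counts (negative, non-integer, or `y > n`) and
#' duplicated labels are rejected with row-level diagnostics.
#'
#' @param path path to the CSV file.
#' @return A [basket_data] object.
#' @export
read_basket_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("indication", "n", "y")
  if (!all(required %in% names(df)))
    stop("CSV must have columns 'indication', 'n', 'y'; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$n) | !is.finite(df$y) |
                 df$n != round(df$n) | df$y != round(df$y) |
                 df$n <= 0 | df$y < 0 | df$y > df$n)
  if (length(bad))
    stop("invalid count rows in ", path, ": row(s) ",
         paste(bad, collapse = ", "),
         " (need integer n > 0 and 0 <= y <= n)", call. = FALSE)
  basket_data(df$indication, df$n, df$y)
}

#' Write basket-trial data to CSV
#'
#' @param data a [basket_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_basket_csv <- function(data, path) {
  stopifnot(inherits(data, "basket_data"))
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hyperprior configuration for the hierarchical model
#'
#' The BHM places `theta_k = logit(p_k) ~ N(mu, sigma2)` with
#' `mu ~ N(mu_mean, mu_sd^2)`. The between-group variance `sigma2` is either
#' given an inverse-gamma hyperprior `IG(shape, scale)` or held fixed
#' (`sigma2 = 0` is the pooled analysis; a very large value approaches
#' independent analysis).
#'
#' @param mu_mean prior mean of `mu` on the log-odds scale.
#' @param mu_sd prior standard deviation of `mu` (positive).
#' @param sigma2_shape,sigma2_scale inverse-gamma hyperparameters (both
#'   positive); ignored when `sigma2_fixed` is supplied.
#' @param sigma2_fixed optional fixed value for `sigma2` (`>= 0`).
#' @param label free-text label for reports.
#' @return An object of class `prior_spec`.
#' @seealso [prior_A()], [prior_B()]
#' @export
prior_spec <- function(mu_mean = -2.19, mu_sd = 2,
                       sigma2_shape = NULL, sigma2_scale = NULL,
                       sigma2_fixed = NULL, label = "custom") {
  if (!is.numeric(mu_sd) || mu_sd <= 0) stop("mu_sd must be > 0", call. = FALSE)
  fixed <- !is.null(sigma2_fixed)
  if (fixed) {
    if (!is.numeric(sigma2_fixed) || sigma2_fixed < 0)
      stop("sigma2_fixed must be >= 0", call. = FALSE)
  } else {
    if (is.null(sigma2_shape) || is.null(sigma2_scale))
      stop("either sigma2_fixed or both sigma2_shape and sigma2_scale ",
           "must be given", call. = FALSE)
    if (sigma2_shape <= 0 || sigma2_scale <= 0)
      stop("inverse-gamma shape and scale must be > 0", call. = FALSE)
  }
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma2_fixed = if (fixed) sigma2_fixed else NULL,
                 sigma2_shape = if (fixed) NULL else sigma2_shape,
                 sigma2_scale = if (fixed) NULL else sigma2_scale,
                 label = label),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior spec [", x$label, "]: mu ~ N(", x$mu_mean, ", ", x$mu_sd,
      "^2); sigma2 ", sep = "")
  if (!is.null(x$sigma2_fixed)) cat("fixed at", x$sigma2_fixed, "\n")
  else cat("~ IG(", x$sigma2_shape, ", ", x$sigma2_scale, ")\n", sep = "")
  invisible(x)
}

#' Moderate-borrowing prior preset ("Prior A")
#'
#' `mu ~ N(-2.19, 2^2)` and `sigma2 ~ IG(0.375, 1.5)` — the hyperprior used
#' in the RAGNAR trial's hierarchical analysis, ensuring a moderate degree
#' of borrowing.
#' @return A [prior_spec].
#' @export
prior_A <- function() prior_spec(-2.19, 2, 0.375, 1.5, label = "Prior A")

#' Aggressive-borrowing prior preset ("Prior B")
#'
#' `mu ~ N(-2.19, 2^2)` and `sigma2 ~ IG(0.0005, 0.000005)`, reflecting a
#' small amount of between-indication heterogeneity and hence strong
#' information borrowing.
#' @return A [prior_spec].
#' @export
prior_B <- function() prior_spec(-2.19, 2, 0.0005, 0.000005, label = "Prior B")

#' Trial scenario: true response rates and design sample sizes
#'
#' @param true_orr per-indication true response probabilities in `[0, 1]`.
#' @param n per-indication planned sample sizes.
#' @param null_orr reference null response rate (default 0.15).
#' @param target_orr lowest clinically meaningful rate (default 0.3).
#' @param label scenario label.
#' @return An object of class `scenario`.
#' @export
scenario <- function(true_orr, n = rep(30L, length(true_orr)),
                     null_orr = 0.15, target_orr = 0.3,
                     label = "scenario") {
  if (any(true_orr < 0 | true_orr > 1))
    stop("true_orr must be in [0, 1]", call. = FALSE)
  if (length(n) != length(true_orr))
    stop("n and true_orr must have the same length", call. = FALSE)
  check_count(n, "n", positive = TRUE)
  if (null_orr >= target_orr)
    stop("null_orr must be below target_orr", call. = FALSE)
  structure(list(true_orr = as.numeric(true_orr), n = as.integer(n),
                 null_orr = null_orr, target_orr = target_orr,
                 label = label),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario [", x$label, "]: ORR = (",
      paste(x$true_orr, collapse = ", "), "), n = (",
      paste(x$n, collapse = ", "), "), null ", x$null_orr,
      ", target ", x$target_orr, "\n", sep = "")
  invisible(x)
}
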