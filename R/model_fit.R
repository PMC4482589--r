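#' Log-transform annual area burned
#'
#' Natural log of annual area burned (ha). Exact zero-burn years have a
#' small offset (default 10 ha) added before the log; the offset is applied
#' only to zeros, never to positive values.
#'
#' @param area_ha An [annual_series()] of area burned in hectares (>= 0).
#' @param zero_offset_ha Offset added to zero-burn years, default 10 ha.
#' @return An [annual_series()] on the ln(ha) scale.
#' @examples
#' a <- annual_series(2000:2002, c(0, 1, exp(3)), "area")
#' log_transform_area(a)$values  # ln(10), 0, 3
#' @export
log_transform_area <- function(area_ha, zero_offset_ha = 10) {
  stopifnot(inherits(area_ha, "annual_series"))
  v <- area_ha$values
  if (any(v < 0)) stop("area burned cannot be negative")
  v[v == 0] <- zero_offset_ha
  annual_series(area_ha$years, log(v),
                name = paste0("ln_", area_ha$name))
}

# Align 1+ predictor series and a response on a set of years; errors when a
# series does not cover the requested years.
align_series <- function(predictors, response, years = NULL) {
  if (inherits(predictors, "annual_series")) predictors <- list(predictors)
  stopifnot(length(predictors) >= 1L,
            all(vapply(predictors, inherits, TRUE, "annual_series")),
            inherits(response, "annual_series"))
  common <- Reduce(intersect, c(lapply(predictors, `[[`, "years"),
                                list(response$years)))
  if (is.null(years)) years <- common
  years <- as.integer(years)
  if (!all(years %in% common)) {
    miss <- setdiff(years, common)
    stop(sprintf("series do not cover requested years: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")))
  }
  X <- vapply(predictors, function(s) s$values[match(years, s$years)],
              numeric(length(years)))
  X <- matrix(X, nrow = length(years))
  nms <- vapply(predictors, `[[`, "", "name")
  nms[nms == ""] <- paste0("x", seq_along(nms))[nms == ""]
  colnames(X) <- make.unique(nms)
  list(years = years, X = X,
       y = response$values[match(years, response$years)])
}

#' Ordinary least squares fit of log area burned on climate metrics
#'
#' Fits `y = b0 + b1 x1 + ... + bp xp` (p <= 3) over the requested years and
#' reports the coefficient of determination, adjusted R-squared (multiple
#' regression only), residual standard deviation, and standardized slopes
#' (slopes after z-scoring predictors and response).
#'
#' @param predictors One [annual_series()] or a list of up to three.
#' @param response An [annual_series()] (ln area burned).
#' @param years Years to fit on; default all common years.
#' @param std_moments `"local"` z-scores over the fitted years (the default,
#'   appropriate for per-window parameter trajectories); `"global"` uses
#'   each full series' moments for cross-period comparability.
#' @return An object of class `fire_ols` with elements `beta0`, `betas`,
#'   `std_betas`, `r2`, `r2_adj`, `resid_sd`, `n_obs`, `predictor_names`,
#'   `years`.
#' @examples
#' x <- annual_series(1961:2000, rnorm(40), "x")
#' y <- annual_series(1961:2000, 2 * x$values + rnorm(40, 0, 0.1), "y")
#' fit_ols(x, y)$betas
#' @export
fit_ols <- function(predictors, response, years = NULL,
                    std_moments = c("local", "global")) {
  std_moments <- match.arg(std_moments)
  if (inherits(predictors, "annual_series")) predictors <- list(predictors)
  p <- length(predictors)
  if (p < 1L || p > 3L) stop("between 1 and 3 predictors are supported")
  al <- align_series(predictors, response, years)
  n <- length(al$years)
  if (n < p + 4L)
    stop(sprintf("too few observations (%d) for %d predictor(s)", n, p))
  X <- cbind(`(Intercept)` = 1, al$X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    cm <- abs(stats::cor(al$X))
    diag(cm) <- 0
    bad <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    stop(sprintf("rank-deficient design: predictors '%s' and '%s' are collinear",
                 colnames(al$X)[bad[1L]], colnames(al$X)[bad[2L]]))
  }
  fit <- stats::lm.fit(X, al$y)
  coefs <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((al$y - mean(al$y))^2)
  if (sst <= 0) stop("response has zero variance over the fitted years")
  r2 <- 1 - sse / sst
  r2_adj <- if (p >= 2L) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  sdx <- apply(al$X, 2L, stats::sd)
  sdy <- stats::sd(al$y)
  if (std_moments == "global") {
    sdx <- vapply(predictors, function(s) stats::sd(s$values), 0)
    sdy <- stats::sd(response$values)
  }
  structure(list(beta0 = unname(coefs[1L]),
                 betas = stats::setNames(coefs[-1L], colnames(al$X)),
                 std_betas = stats::setNames(coefs[-1L] * sdx / sdy,
                                             colnames(al$X)),
                 r2 = r2, r2_adj = r2_adj,
                 resid_sd = sqrt(sse / (n - p - 1)),
                 n_obs = n, predictor_names = colnames(al$X),
                 years = al$years, std_moments = std_moments),
            class = "fire_ols")
}

#' @export
print.fire_ols <- function(x, ...) {
  cat(sprintf("<fire_ols> %s ~ %s  (n = %d, %d-%d)\n", "ln(area)",
              paste(x$predictor_names, collapse = " + "), x$n_obs,
              min(x$years), max(x$years)))
  cat(sprintf("  r2 = %.3f%s, resid sd = %.3f\n", x$r2,
              if (!is.na(x$r2_adj)) sprintf(" (adj %.3f)", x$r2_adj) else "",
              x$resid_sd))
  invisible(x)
}

#' Predict from a fitted fire-climate regression
#'
#' @param object A `fire_ols` fit.
#' @param predictors The predictor series (same order as in the fit).
#' @param years Years to predict; all predictors must cover them.
#' @param ... Unused.
#' @return Named numeric vector of predictions (ln ha), names = years.
#' @export
predict.fire_ols <- function(object, predictors, years, ...) {
  if (inherits(predictors, "annual_series")) predictors <- list(predictors)
  stopifnot(length(predictors) == length(object$betas))
  years <- as.integer(years)
  X <- vapply(predictors, function(s) {
    idx <- match(years, s$years)
    if (anyNA(idx))
      stop(sprintf("predictor '%s' does not cover all prediction years",
                   s$name))
    s$values[idx]
  }, numeric(length(years)))
  X <- matrix(X, nrow = length(years))
  stats::setNames(drop(object$beta0 + X %*% object$betas), years)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j
#' on the remaining predictors. Values of 10 or more indicate problematic
#' multicollinearity; perfect collinearity reports `Inf`.
#'
#' @param predictors A list of 2-3 [annual_series()].
#' @param years Years to evaluate over; default all common years.
#' @return A list with `vif` (named numeric), `max_vif`, and `flagged`
#'   (`TRUE` when `max_vif >= 10`).
#' @export
variance_inflation_factors <- function(predictors, years = NULL) {
  if (inherits(predictors, "annual_series")) predictors <- list(predictors)
  if (length(predictors) < 2L) stop("VIF requires at least 2 predictors")
  if (length(predictors) > 3L) stop("at most 3 predictors are supported")
  al <- align_series(predictors, predictors[[1L]], years)
  X <- al$X
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    sst <- sum((X[, j] - mean(X[, j]))^2)
    sse <- sum(fit$residuals^2)
    r2j <- 1 - sse / sst
    if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, 0)
  names(vif) <- colnames(X)
  list(vif = vif, max_vif = max(vif), flagged = max(vif) >= 10)
}

#' Null distribution of the Lilliefors statistic
#'
#' Monte-Carlo draws of the Lilliefors (Kolmogorov-Smirnov with estimated
#' mean and sd) statistic under normality, for sample size `n`. The
#' distribution is parameter-free, so it can be computed once and reused
#' across tests at the same `n`.
#'
#' @param n Sample size.
#' @param n_sim Number of Monte-Carlo samples (>= 5000 recommended).
#' @param seed RNG seed.
#' @return Numeric vector of `n_sim` null statistics.
#' @export
lilliefors_null_distribution <- function(n, n_sim = 5000L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_sim),
         function(i) lilliefors_statistic(stats::rnorm(n)), 0)
}

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1L) / n))
}

#' Lilliefors goodness-of-fit test for normality
#'
#' Kolmogorov-Smirnov distance between the empirical CDF and a normal CDF
#' with estimated mean and sd; the p-value comes from a seeded Monte-Carlo
#' null (reproducible across platforms, unlike interpolation tables).
#'
#' @param x Numeric sample, n >= 10, non-constant.
#' @param alpha Significance level for the pass flag (default 0.05).
#' @param n_sim Monte-Carlo null size (default 5000).
#' @param seed RNG seed for the null.
#' @param null_stats Optional precomputed null distribution for this `n`
#'   (from [lilliefors_null_distribution()]) to avoid resimulation.
#' @return List: `statistic`, `p_value`, `pass` (TRUE when p >= alpha),
#'   `n`, `n_sim`.
#' @export
lilliefors_normality <- function(x, alpha = 0.05, n_sim = 5000L, seed = 1L,
                                 null_stats = NULL) {
  x <- as.numeric(x)
  if (length(x) < 10L) stop("Lilliefors test requires n >= 10")
  if (stats::sd(x) == 0) stop("constant series: sd is zero")
  d <- lilliefors_statistic(x)
  if (is.null(null_stats))
    null_stats <- lilliefors_null_distribution(length(x), n_sim, seed)
  p <- mean(null_stats >= d)
  list(statistic = d, p_value = p, pass = p >= alpha, n = length(x),
       n_sim = length(null_stats))
}

#' Coefficient of efficiency (CE) cross-validation skill
#'
#' `CE = 1 - MSE(model) / MSE(validation mean)`: the mean squared prediction
#' error of the model over the validation years relative to predicting the
#' validation-period mean everywhere. CE ranges over (-Inf, 1]; CE > 0 means
#' the model beats the climatological mean, and CE < 0 flags a relationship
#' that does not carry from the calibration to the validation period.
#'
#' @param observed Observed validation values (length >= 2, non-constant).
#' @param predicted Model predictions for the same years.
#' @return An object of class `skill_result`: `ce`, `mse_model`, `mse_null`,
#'   `n_validation`.
#' @examples
#' coefficient_of_efficiency(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))$ce  # 1
#' @export
coefficient_of_efficiency <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2L) stop("CE requires at least 2 validation years")
  mse_model <- mean((observed - predicted)^2)
  mse_null <- mean((observed - mean(observed))^2)
  if (mse_null == 0)
    stop("observed validation values have zero variance (null MSE is 0)")
  structure(list(ce = 1 - mse_model / mse_null, mse_model = mse_model,
                 mse_null = mse_null, n_validation = length(observed)),
            class = "skill_result")
}

#' @export
print.skill_result <- function(x, ...) {
  cat(sprintf("<skill_result> CE = %.3f (n = %d)\n", x$ce, x$n_validation))
  invisible(x)
}
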