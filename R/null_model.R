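#' Fit the constant-relationship (null) model
#'
#' One ordinary least squares fit over the entire record. Under the null,
#' the fire-climate link is constant through time and the response is the
#' fitted climate signal plus iid noise with a constant standard deviation
#' (the full-record residual sd).
#'
#' @param predictors One [annual_series()] or a list of up to three.
#' @param response An [annual_series()] (ln area burned).
#' @return An object of class `fire_null`: `model` (a `fire_ols`),
#'   `noise_sd`, `fitted` (named by year), `residuals`, `years`, plus the
#'   aligned predictor list and response.
#' @export
fit_global_null <- function(predictors, response) {
  if (inherits(predictors, "annual_series")) predictors <- list(predictors)
  al <- align_series(predictors, response, NULL)
  if (length(al$years) < 50L)
    stop(sprintf("null model requires >= 50 overlapping years (have %d)",
                 length(al$years)))
  model <- fit_ols(predictors, response, years = al$years)
  fitted <- predict(model, predictors, al$years)
  res <- al$y - fitted
  structure(list(model = model, noise_sd = model$resid_sd,
                 fitted = fitted, residuals = unname(res),
                 years = al$years, predictors = predictors,
                 response = response),
            class = "fire_null")
}

#' @export
print.fire_null <- function(x, ...) {
  cat(sprintf("<fire_null> global fit %d-%d: r2 = %.3f, noise sd = %.3f\n",
              min(x$years), max(x$years), x$model$r2, x$noise_sd))
  invisible(x)
}

#' Simulate one response record from the fitted null
#'
#' Fitted values plus noise, with the observed predictor values held fixed:
#' only the stochastic component of area burned varies across realizations.
#'
#' @param null A [fit_global_null()] result.
#' @param seed Optional RNG seed; the same seed reproduces the realization.
#' @param noise `"gaussian"` (iid Normal(0, noise_sd), the default) or
#'   `"resample"` (residuals resampled with replacement).
#' @return An [annual_series()] of simulated ln area burned.
#' @export
simulate_null_realization <- function(null, seed = NULL,
                                      noise = c("gaussian", "resample")) {
  stopifnot(inherits(null, "fire_null"))
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  n <- length(null$years)
  eps <- if (noise == "gaussian") stats::rnorm(n, 0, null$noise_sd)
         else sample(null$residuals, n, replace = TRUE)
  annual_series(null$years, unname(null$fitted) + eps,
                name = paste0(null$response$name, "_null"))
}

# Vectorized sweep statistics (r2, ce, std betas) for a matrix of response
# realizations Y (n x R) against the fixed predictor design. Used by the
# envelope builder; equivalent to running climate_fire_sweep on each column.
sweep_stats_matrix <- function(X, years, Y, width) {
  n <- length(years)
  p <- ncol(X)
  wins <- calibration_windows(min(years), max(years), width)
  W <- nrow(wins)
  R <- ncol(Y)
  r2 <- ce <- matrix(NA_real_, W, R)
  std_beta <- array(NA_real_, c(W, R, p))
  Xfull <- cbind(1, X)
  for (w in seq_len(W)) {
    cal <- which(years >= wins$start_year[w] & years <= wins$end_year[w])
    val <- setdiff(seq_len(n), cal)
    Xc <- Xfull[cal, , drop = FALSE]
    P <- solve(crossprod(Xc), t(Xc))        # (p+1) x nw projector
    Yc <- Y[cal, , drop = FALSE]
    B <- P %*% Yc                           # (p+1) x R coefficients
    Fc <- Xc %*% B
    mu_c <- colMeans(Yc)
    sse <- colSums((Yc - Fc)^2)
    sst <- colSums((Yc - rep(mu_c, each = length(cal)))^2)
    r2[w, ] <- ifelse(sst > 0, 1 - sse / sst, NA_real_)
    Yv <- Y[val, , drop = FALSE]
    Pv <- Xfull[val, , drop = FALSE] %*% B
    mu_v <- colMeans(Yv)
    msem <- colSums((Yv - Pv)^2)
    msen <- colSums((Yv - rep(mu_v, each = length(val)))^2)
    ce[w, ] <- ifelse(msen > 0, 1 - msem / msen, NA_real_)
    sdy <- sqrt(sst / (length(cal) - 1L))
    for (j in seq_len(p)) {
      sdx <- stats::sd(X[cal, j])
      std_beta[w, , j] <- ifelse(sdy > 0, B[j + 1L, ] * sdx / sdy, NA_real_)
    }
  }
  list(center_years = wins$center_year, r2 = r2, ce = ce,
       std_beta = std_beta)
}

#' Monte-Carlo null envelope for time-varying sweep statistics
#'
#' Simulates many response records from the constant-relationship null,
#' re-runs the moving-window sweep on each, and takes central quantiles
#' (default the central 95%) of every per-window statistic: r2, CE, and
#' each standardized slope. Observed trajectories that leave the envelope
#' are inconsistent with a constant fire-climate relationship.
#'
#' @param predictors One [annual_series()] or a list of up to three.
#' @param response An [annual_series()] (ln area burned).
#' @param width Odd calibration width (default 21).
#' @param n_realizations Number of null realizations (default 10000 as in
#'   the full analysis; fewer than 100 triggers an instability warning but
#'   the envelope is still computed).
#' @param seed RNG seed.
#' @param level Central coverage of the envelope (default 0.95).
#' @param noise Noise mechanism, see [simulate_null_realization()].
#' @return An object of class `null_envelope`: `center_years`, `bands` (a
#'   named list of data frames `lower`/`upper` per statistic), `level`,
#'   `n_realizations`, `seed`, and the underlying `null` fit.
#' @export
build_envelope <- function(predictors, response, width = 21L,
                           n_realizations = 10000L, seed = 1L,
                           level = 0.95, noise = c("gaussian", "resample")) {
  noise <- match.arg(noise)
  n_realizations <- as.integer(n_realizations)
  if (n_realizations < 1L) stop("n_realizations must be positive")
  if (n_realizations < 100L)
    warning("fewer than 100 realizations: envelope quantiles are unstable")
  null <- fit_global_null(predictors, response)
  al <- align_series(null$predictors, response, NULL)
  n <- length(al$years)
  set.seed(seed)
  E <- if (noise == "gaussian")
    matrix(stats::rnorm(n * n_realizations, 0, null$noise_sd), n)
  else
    matrix(sample(null$residuals, n * n_realizations, replace = TRUE), n)
  Y <- unname(null$fitted) + E
  st <- sweep_stats_matrix(al$X, al$years, Y, width)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qband <- function(m) {
    q <- apply(m, 1L, stats::quantile, probs = probs, na.rm = TRUE,
               names = FALSE)
    data.frame(center_year = st$center_years, lower = q[1L, ],
               upper = q[2L, ])
  }
  bands <- list(r2 = qband(st$r2), ce = qband(st$ce))
  pn <- colnames(al$X)
  for (j in seq_along(pn))
    bands[[paste0("std_beta_", pn[j])]] <- qband(st$std_beta[, , j])
  structure(list(center_years = st$center_years, bands = bands,
                 level = level, n_realizations = n_realizations,
                 seed = seed, noise = noise, null = null),
            class = "null_envelope")
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf(
    "<null_envelope> central %.0f%% of %d realizations, %d window centers\n",
    100 * x$level, x$n_realizations, length(x$center_years)))
  invisible(x)
}

#' Compare an observed sweep to a null envelope
#'
#' @param envelope A [build_envelope()] result.
#' @param sweep The observed [climate_fire_sweep()] (same predictors,
#'   response span and width).
#' @return Data frame with one row per window center and statistic:
#'   `center_year`, `statistic`, `observed`, `lower`, `upper`, `inside`,
#'   `side` (`"below"`/`"above"`/`""`).
#' @export
envelope_coverage <- function(envelope, sweep) {
  stopifnot(inherits(envelope, "null_envelope"),
            inherits(sweep, "fire_sweep"))
  if (!identical(envelope$center_years, sweep$center_year))
    stop("envelope and sweep window centers differ")
  rows <- lapply(names(envelope$bands), function(stat) {
    obs <- sweep[[stat]]
    if (is.null(obs)) return(NULL)
    b <- envelope$bands[[stat]]
    inside <- obs >= b$lower & obs <= b$upper
    data.frame(center_year = b$center_year, statistic = stat,
               observed = obs, lower = b$lower, upper = b$upper,
               inside = inside,
               side = ifelse(inside, "", ifelse(obs < b$lower, "below",
                                                "above")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
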