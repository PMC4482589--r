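#' Enumerate contiguous calibration windows
#'
#' All contiguous odd-width calibration periods within a span of years. The
#' 1902-2008 record with width 21 yields 87 windows, the first centered on
#' 1912 (1902-1922) and the last on 1998 (1988-2008).
#'
#' @param first_year,last_year Span of the record.
#' @param width Odd window width in years (default 21; 31 and 41 are the
#'   usual sensitivity settings).
#' @return Data frame with `start_year`, `center_year`, `end_year`, `width`.
#' @examples
#' nrow(calibration_windows(1902, 2008))  # 87
#' @export
calibration_windows <- function(first_year, last_year, width = 21L) {
  width <- as.integer(width)
  first_year <- as.integer(first_year)
  last_year <- as.integer(last_year)
  if (width %% 2L == 0L) stop("window width must be odd")
  span <- last_year - first_year + 1L
  if (span < width)
    stop(sprintf("record span (%d yr) is shorter than the window (%d yr)",
                 span, width))
  starts <- first_year:(last_year - width + 1L)
  data.frame(start_year = starts,
             center_year = starts + (width - 1L) %/% 2L,
             end_year = starts + width - 1L,
             width = width)
}

#' Moving-window calibration/verification sweep
#'
#' Fits the regression of ln area burned on the predictor set inside every
#' contiguous calibration window, then cross-validates each fitted model on
#' all remaining years (both sides of the window) with the coefficient of
#' efficiency. The result traces calibration accuracy (r2, adjusted
#' R-squared for multiple regression), skill (CE) and standardized
#' parameters through time.
#'
#' @param predictors One [annual_series()] or a list of up to three.
#' @param response An [annual_series()] (ln area burned).
#' @param width Odd calibration width in years (default 21).
#' @param std_moments Passed to [fit_ols()] (`"local"` or `"global"`).
#' @return An object of class `fire_sweep`: a data frame with one row per
#'   window (`center_year`, `start_year`, `end_year`, `r2`, `r2_adj`, `ce`,
#'   `mse_model`, `mse_null`, `beta0`, `beta_*`, `std_beta_*`, `resid_sd`),
#'   with attributes `predictor_names`, `width`, `span`.
#' @export
climate_fire_sweep <- function(predictors, response, width = 21L,
                               std_moments = c("local", "global")) {
  std_moments <- match.arg(std_moments)
  if (inherits(predictors, "annual_series")) predictors <- list(predictors)
  al <- align_series(predictors, response, NULL)
  span <- range(al$years)
  wins <- calibration_windows(span[1L], span[2L], width)
  if (nrow(wins) == 1L && width == length(al$years))
    stop("window spans the full record: no validation years for CE")
  rows <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    cal_years <- w$start_year:w$end_year
    val_years <- setdiff(al$years, cal_years)
    fit <- tryCatch(
      fit_ols(predictors, response, years = cal_years,
              std_moments = std_moments),
      error = function(e)
        stop(sprintf("window centered %d (%d-%d): %s", w$center_year,
                     w$start_year, w$end_year, conditionMessage(e)),
             call. = FALSE))
    pred <- predict(fit, predictors, val_years)
    obs <- al$y[match(val_years, al$years)]
    skill <- coefficient_of_efficiency(obs, pred)
    row <- data.frame(center_year = w$center_year, start_year = w$start_year,
                      end_year = w$end_year, r2 = fit$r2, r2_adj = fit$r2_adj,
                      ce = skill$ce, mse_model = skill$mse_model,
                      mse_null = skill$mse_null, beta0 = fit$beta0,
                      resid_sd = fit$resid_sd)
    for (nm in names(fit$betas)) {
      row[[paste0("beta_", nm)]] <- unname(fit$betas[nm])
      row[[paste0("std_beta_", nm)]] <- unname(fit$std_betas[nm])
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("fire_sweep", "data.frame"),
            predictor_names = names(fit$betas), width = width,
            span = span, response_name = response$name)
}

#' @export
print.fire_sweep <- function(x, ...) {
  cat(sprintf("<fire_sweep> %s ~ %s: %d windows of %d yr (%d-%d)\n",
              attr(x, "response_name"),
              paste(attr(x, "predictor_names"), collapse = " + "),
              nrow(x), attr(x, "width"), attr(x, "span")[1L],
              attr(x, "span")[2L]))
  cat(sprintf("  median r2 = %.3f, median CE = %.3f\n",
              stats::median(x$r2), stats::median(x$ce)))
  invisible(x)
}

#' Rank candidate predictor sets by calibration accuracy and skill
#'
#' Combines each predictor set's median windowed accuracy (r2, or adjusted
#' R-squared for multiple regression) and median cross-validation skill (CE)
#' into a ranking score. Two score modes are reported: the product of the
#' medians, and the median over windows of the per-window product r2 x CE
#' (the default ranking key).
#'
#' @param sweeps Named list of [climate_fire_sweep()] results (or a single
#'   sweep).
#' @param global_r2 Optional named numeric of full-record r2 (or adjusted
#'   R-squared) per predictor set, reported alongside.
#' @param mode Ranking key: `"median_of_products"` (default) or
#'   `"product_of_medians"`.
#' @return Data frame with one row per predictor set: `predictor_set`,
#'   `global_r2`, `median_r2`, `median_ce`, `score_product_of_medians`,
#'   `score_median_of_products`, `score`, `rank`, `score_mode`.
#' @export
rank_predictors <- function(sweeps, global_r2 = NULL,
                            mode = c("median_of_products",
                                     "product_of_medians")) {
  mode <- match.arg(mode)
  if (inherits(sweeps, "fire_sweep")) sweeps <- list(sweeps)
  if (!length(sweeps)) stop("no sweeps to rank")
  if (is.null(names(sweeps)) || any(names(sweeps) == ""))
    names(sweeps) <- vapply(sweeps, function(s)
      paste(attr(s, "predictor_names"), collapse = "+"), "")
  rows <- lapply(names(sweeps), function(nm) {
    s <- sweeps[[nm]]
    if (!nrow(s)) stop(sprintf("empty sweep for '%s'", nm))
    acc <- if (all(!is.na(s$r2_adj))) s$r2_adj else s$r2
    data.frame(predictor_set = nm,
               global_r2 = if (!is.null(global_r2) && nm %in% names(global_r2))
                 unname(global_r2[nm]) else NA_real_,
               median_r2 = stats::median(acc),
               median_ce = stats::median(s$ce),
               score_product_of_medians =
                 stats::median(acc) * stats::median(s$ce),
               score_median_of_products = stats::median(acc * s$ce),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$score <- if (mode == "median_of_products")
    out$score_median_of_products else out$score_product_of_medians
  out <- out[order(-out$score), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$score_mode <- mode
  rownames(out) <- NULL
  out
}

#' Standardized-parameter trajectories from a sweep
#'
#' @param sweep A [climate_fire_sweep()] result.
#' @return Data frame: `center_year` plus one `std_beta_*` column per
#'   predictor, suitable for overlay on a null envelope.
#' @export
parameter_series <- function(sweep) {
  stopifnot(inherits(sweep, "fire_sweep"))
  cols <- grep("^std_beta_", names(sweep), value = TRUE)
  out <- sweep[, c("center_year", cols), drop = FALSE]
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Mean overprediction bias of a model on validation years
#'
#' Mean relative error, in percent, of model predictions over validation
#' years on the ln(area) scale: `100 * (pred - obs) / obs`. A positive value
#' means the calibrated relationship overpredicts fire activity outside its
#' calibration era. Validation years whose ln response is <= 0 (sub-1-ha
#' years) are excluded with a warning. When several models are supplied the
#' across-model mean and sd of the per-model biases are reported too.
#'
#' @param models A `fire_ols` fit or a list of them.
#' @param predictors Predictor series matching each model (a single set
#'   shared by all models, or a list of sets parallel to `models`).
#' @param response The observed ln-area [annual_series()].
#' @param validation_years Years to evaluate; must be disjoint from each
#'   model's calibration years.
#' @return List: `per_model` (percent bias per model), `mean`, `sd`,
#'   `n_years_used`.
#' @export
overprediction_bias <- function(models, predictors, response,
                                validation_years) {
  single <- inherits(models, "fire_ols")
  if (single) models <- list(models)
  shared <- inherits(predictors, "annual_series") ||
    (is.list(predictors) && length(predictors) &&
       inherits(predictors[[1L]], "annual_series"))
  validation_years <- as.integer(validation_years)
  biases <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    if (length(intersect(validation_years, m$years)))
      stop("validation years overlap the calibration years")
    px <- if (shared) predictors else predictors[[i]]
    pred <- predict(m, px, validation_years)
    obs <- response$values[match(validation_years, response$years)]
    if (anyNA(obs)) stop("response does not cover all validation years")
    keep <- obs > 0
    if (!all(keep))
      warning(sprintf("excluded %d year(s) with ln response <= 0",
                      sum(!keep)))
    mean(100 * (pred[keep] - obs[keep]) / obs[keep])
  }, 0)
  list(per_model = biases, mean = mean(biases),
       sd = if (length(biases) > 1L) stats::sd(biases) else NA_real_,
       n_years_used = length(validation_years))
}
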