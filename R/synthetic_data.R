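#' Specify a regime-shift scenario for synthetic fire-climate data
#'
#' Parameterizes the conceptual regime experiments: a record (default 107 yr,
#' labeled 1902-2008) divided into periods (default boundaries 1943 and
#' 1985) where annual ln(area burned) is a linear function of an iid normal
#' climate metric plus Gaussian noise. Scenarios constrain which quantities
#' may differ among periods:
#'
#' * `constant_relationship` - identical climate moments and regression
#'   parameters throughout (the null).
#' * `climate_shift` - climate moments shift among periods while the
#'   regression parameters stay fixed (fire tracks climate).
#' * `altered_relationship` - climate moments stay fixed while the
#'   regression parameters change (default: slope doubled and intercept
#'   raised by one noise sd in the final period).
#' * `combined` - both may vary.
#'
#' @param scenario Scenario name (see above).
#' @param n_years Record length (default 107).
#' @param start_year First labeled year (default 1902).
#' @param period_boundaries Years starting each new period (default
#'   `c(1943, 1985)`).
#' @param climate_mean,climate_sd Per-period climate moments (recycled;
#'   defaults 0 and 1; `climate_shift`/`combined` default the means to
#'   `c(0, -1, 1)` mirroring a wetter mid-century and warmer recent era).
#' @param beta0,beta1 Per-period intercept (ln ha) and slope (ln ha per
#'   climate unit), recycled. Defaults 8 and 1; `altered_relationship` /
#'   `combined` default the final period to `beta1 = 2`,
#'   `beta0 = 8 + noise_sd`.
#' @param noise_sd Residual sd on the ln scale (default 1, giving full-record
#'   r2 of about 0.5 at unit slope and unit climate variance).
#' @param zero_burn_rate Proportion of zero-burn years (default 0.03).
#' @param seed RNG seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("constant_relationship",
                                       "climate_shift",
                                       "altered_relationship", "combined"),
                          n_years = 107L, start_year = 1902L,
                          period_boundaries = c(1943L, 1985L),
                          climate_mean = NULL, climate_sd = NULL,
                          beta0 = NULL, beta1 = NULL, noise_sd = 1,
                          zero_burn_rate = 0.03, seed = 1L) {
  scenario <- match.arg(scenario)
  n_years <- as.integer(n_years)
  start_year <- as.integer(start_year)
  period_boundaries <- sort(as.integer(period_boundaries))
  last_year <- start_year + n_years - 1L
  if (any(period_boundaries <= start_year) ||
      any(period_boundaries > last_year))
    stop("period boundaries must be interior to the record")
  np <- length(period_boundaries) + 1L
  vary_climate <- scenario %in% c("climate_shift", "combined")
  vary_betas <- scenario %in% c("altered_relationship", "combined")
  if (is.null(climate_mean))
    climate_mean <- if (vary_climate) c(0, -1, 1)[seq_len(np)] else 0
  if (is.null(climate_sd)) climate_sd <- 1
  if (is.null(beta1))
    beta1 <- if (vary_betas) c(rep(1, np - 1L), 2) else 1
  if (is.null(beta0))
    beta0 <- if (vary_betas) c(rep(8, np - 1L), 8 + noise_sd) else 8
  climate_mean <- rep_len(as.numeric(climate_mean), np)
  climate_sd <- rep_len(as.numeric(climate_sd), np)
  beta0 <- rep_len(as.numeric(beta0), np)
  beta1 <- rep_len(as.numeric(beta1), np)
  if (any(climate_sd <= 0)) stop("climate_sd must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (zero_burn_rate < 0 || zero_burn_rate > 0.2)
    stop("zero_burn_rate must be in [0, 0.2]")
  same <- function(v) all(abs(v - v[1L]) < 1e-12)
  if (scenario == "climate_shift" && !(same(beta0) && same(beta1)))
    stop("climate_shift requires equal regression parameters across periods")
  if (scenario == "altered_relationship" &&
      !(same(climate_mean) && same(climate_sd)))
    stop("altered_relationship requires equal climate moments across periods")
  if (scenario == "constant_relationship" &&
      !(same(beta0) && same(beta1) && same(climate_mean) && same(climate_sd)))
    stop("constant_relationship requires all parameters equal across periods")
  structure(list(scenario = scenario, n_years = n_years,
                 start_year = start_year,
                 period_boundaries = period_boundaries,
                 climate_mean = climate_mean, climate_sd = climate_sd,
                 beta0 = beta0, beta1 = beta1, noise_sd = noise_sd,
                 zero_burn_rate = zero_burn_rate, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: %d yr from %d, boundaries %s\n",
              x$scenario, x$n_years, x$start_year,
              paste(x$period_boundaries, collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic fire-climate dataset with known truth
#'
#' Draws the climate metric iid Normal(period mean, period sd), sets
#' `ln(area) = beta0_p + beta1_p * climate + Normal(0, noise_sd)` with the
#' period's parameters, exponentiates to hectares, and finally replaces the
#' configured fraction of smallest-area years with exact zeros (so the
#' log-linear truth stays interpretable for the remaining years).
#'
#' @param spec A [scenario_spec()].
#' @return List: `climate` ([annual_series()]), `area_ha` ([annual_series()],
#'   with zero-burn years), `ln_area` (pre-zeroing ln series), `truth`
#'   (generating values per year: period index, beta0, beta1, climate
#'   moments, noise draws, zero-burn years, and the spec).
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  years <- spec$start_year + seq_len(spec$n_years) - 1L
  pidx <- findInterval(years, c(min(years), spec$period_boundaries))
  climate <- stats::rnorm(spec$n_years, spec$climate_mean[pidx],
                          spec$climate_sd[pidx])
  eps <- stats::rnorm(spec$n_years, 0, spec$noise_sd)
  ln_area <- spec$beta0[pidx] + spec$beta1[pidx] * climate + eps
  area <- exp(ln_area)
  n_zero <- round(spec$zero_burn_rate * spec$n_years)
  zero_years <- integer(0)
  if (n_zero > 0L) {
    ord <- order(area)[seq_len(n_zero)]
    area[ord] <- 0
    zero_years <- years[sort(ord)]
  }
  truth <- list(spec = spec, period_index = pidx,
                beta0 = spec$beta0[pidx], beta1 = spec$beta1[pidx],
                climate_mean = spec$climate_mean[pidx],
                climate_sd = spec$climate_sd[pidx], noise = eps,
                zero_burn_years = zero_years)
  list(climate = annual_series(years, climate, "climate"),
       area_ha = annual_series(years, area, "area_burned"),
       ln_area = annual_series(years, ln_area, "ln_area_burned"),
       truth = truth)
}

#' Generate a synthetic daily fire-danger metric
#'
#' A smooth seasonal baseline (sinusoid peaking in mid August, the height of
#' the fire season) plus AR(1) daily anomalies. The record runs from 1
#' January through 31 October of each year so that fixed-end windows
#' anchored late in the season can reach back before 1 May.
#'
#' @param years Calendar years to generate.
#' @param season Unused placeholder kept for interface symmetry; the record
#'   always covers the fire season.
#' @param baseline_level,baseline_amplitude Seasonal baseline parameters
#'   (defaults 50 and 40, an index-like scale).
#' @param event_scale Innovation sd of the daily anomalies (0 gives the
#'   deterministic baseline).
#' @param ar Lag-1 coefficient of the daily anomalies (default 0.7,
#'   synoptic-scale persistence).
#' @param seed RNG seed.
#' @return A [daily_series()].
#' @export
generate_daily_metric <- function(years, season = c("05-01", "10-01"),
                                  baseline_level = 50,
                                  baseline_amplitude = 40,
                                  event_scale = 8, ar = 0.7, seed = 1L) {
  set.seed(seed)
  years <- sort(as.integer(years))
  dates <- do.call(c, lapply(years, function(y)
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-10-31", y)),
        by = "day")))
  doy <- as.integer(format(dates, "%j"))
  baseline <- baseline_level +
    baseline_amplitude * cos(2 * pi * (doy - 227) / 365)  # peak ~15 Aug
  n <- length(dates)
  anom <- numeric(n)
  if (event_scale > 0) {
    innov <- stats::rnorm(n, 0, event_scale)
    anom[1L] <- innov[1L]
    for (i in 2:n) anom[i] <- ar * anom[i - 1L] + innov[i]
  }
  daily_series(dates, baseline + anom, name = "synthetic_metric")
}

#' Generate a dataset exactly satisfying the constant-relationship null
#'
#' Unit-variance iid climate with `ln(area) = beta0 + beta1 * climate +
#' Normal(0, noise_sd)`, where the noise sd is chosen analytically so the
#' expected full-record r-squared equals `r2_target`:
#' `noise_sd = |beta1| * sqrt((1 - r2) / r2)`.
#'
#' @param beta0,beta1 Generating intercept (ln ha) and slope.
#' @param r2_target Expected full-record r2, strictly in (0, 1).
#' @param n_years Record length (default 107).
#' @param start_year First labeled year (default 1902).
#' @param seed RNG seed.
#' @return List: `climate`, `area_ha`, `ln_area` ([annual_series()]),
#'   `noise_sd`, `beta0`, `beta1`.
#' @export
generate_null_dataset <- function(beta0 = 8, beta1 = 1, r2_target = 0.5,
                                  n_years = 107L, start_year = 1902L,
                                  seed = 1L) {
  if (r2_target <= 0 || r2_target >= 1)
    stop("r2_target must be strictly inside (0, 1)")
  noise_sd <- abs(beta1) * sqrt((1 - r2_target) / r2_target)
  set.seed(seed)
  years <- as.integer(start_year) + seq_len(n_years) - 1L
  climate <- stats::rnorm(n_years)
  ln_area <- beta0 + beta1 * climate + stats::rnorm(n_years, 0, noise_sd)
  list(climate = annual_series(years, climate, "climate"),
       area_ha = annual_series(years, exp(ln_area), "area_burned"),
       ln_area = annual_series(years, ln_area, "ln_area_burned"),
       noise_sd = noise_sd, beta0 = beta0, beta1 = beta1)
}
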