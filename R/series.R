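#' Annual time series
#'
#' A named annual series: strictly increasing, gap-free integer years with
#' one real value per year. The response series holds log-transformed annual
#' area burned (ln ha); predictor series hold metric-specific units.
#'
#' @param years Integer vector of consecutive years (no gaps).
#' @param values Numeric vector, one value per year. Missing values are not
#'   permitted: trim series to their observed span instead.
#' @param name Character label for the series.
#' @return An object of class `annual_series` with fields `name`, `years`,
#'   `values`.
#' @examples
#' annual_series(1902:1911, rnorm(10), name = "demo")
#' @export
annual_series <- function(years, values, name = "series") {
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values))
    stop("`years` and `values` must have equal length")
  if (length(years) == 0L) stop("empty series")
  if (anyNA(years) || anyNA(values))
    stop("missing values are not permitted in an annual series")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be consecutive with no gaps")
  structure(list(name = as.character(name)[1L], years = years,
                 values = values),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> %s: %d yr (%d-%d)\n", x$name,
              length(x$years), min(x$years), max(x$years)))
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values)
}

#' Subset an annual series to a span of years
#'
#' @param x An `annual_series`.
#' @param years Years to keep; must all be present in `x`.
#' @return An `annual_series` restricted to `years`.
#' @export
series_window <- function(x, years) {
  stopifnot(inherits(x, "annual_series"))
  idx <- match(as.integer(years), x$years)
  if (anyNA(idx))
    stop(sprintf("series '%s' does not cover years: %s", x$name,
                 paste(years[is.na(idx)], collapse = ", ")))
  annual_series(x$years[idx], x$values[idx], name = x$name)
}

#' Daily time series
#'
#' Daily values of a fire-danger, water-balance or climate metric. Dates must
#' be strictly increasing with no duplicates; every year present should cover
#' at least the fire season so seasonal summaries are well defined.
#'
#' @param dates `Date` vector (or ISO-8601 strings), strictly increasing.
#' @param values Numeric vector, one per date.
#' @param name Character label.
#' @return An object of class `daily_series`.
#' @export
daily_series <- function(dates, values, name = "daily") {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("`dates` and `values` must have equal length")
  if (anyNA(dates) || anyNA(values)) stop("missing dates or values")
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be strictly increasing (no duplicates)")
  structure(list(name = as.character(name)[1L], dates = dates,
                 values = values),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %s: %d d (%s to %s)\n", x$name,
              length(x$dates), min(x$dates), max(x$dates)))
  invisible(x)
}

#' Seasonal summary window specification
#'
#' Describes how daily values collapse to one annual value. Two modes:
#' `fixed_end` takes the mean of `length_days` values ending on `end_date`
#' (inclusive; the window is anchored on its end and may extend before the
#' season start when daily data exist there), while `floating` computes the
#' running `length_days` mean at every placement fully inside the fire season
#' and keeps the seasonal extremum (`max` or `min`) across placements. A
#' `length_days` of 1 with `fixed_end` is a point lookup on `end_date`.
#'
#' @param mode `"fixed_end"` or `"floating"`.
#' @param length_days Positive window length in days (<= 160).
#' @param end_date `"MM-DD"` anchor, fixed_end mode only.
#' @param season_extremum `"max"`, `"min"` (floating mode) or `"none"`
#'   (fixed_end mode).
#' @param statistic Summary inside the window; `"mean"` (a 1-day mean is the
#'   point value).
#' @return An object of class `window_spec`.
#' @examples
#' window_spec("floating", 90, season_extremum = "max")   # 90-day max
#' window_spec("fixed_end", 1, end_date = "09-01")        # 1 day, 1 Sep
#' @export
window_spec <- function(mode = c("fixed_end", "floating"), length_days,
                        end_date = NULL,
                        season_extremum = c("none", "max", "min"),
                        statistic = "mean") {
  mode <- match.arg(mode)
  season_extremum <- match.arg(season_extremum)
  length_days <- as.integer(length_days)
  if (length(length_days) != 1L || is.na(length_days) || length_days < 1L)
    stop("`length_days` must be a positive integer")
  if (length_days > 160L)
    stop("`length_days` must be <= 160 (fits the fire season with slack)")
  if (mode == "fixed_end") {
    if (season_extremum != "none")
      stop("fixed_end windows take no season extremum")
    if (is.null(end_date)) stop("fixed_end windows require `end_date`")
    if (!grepl("^[0-9]{2}-[0-9]{2}$", end_date))
      stop("`end_date` must be an 'MM-DD' string")
  } else {
    if (!is.null(end_date)) stop("floating windows take no `end_date`")
    if (season_extremum == "none")
      stop("floating windows require `season_extremum` of 'max' or 'min'")
  }
  structure(list(mode = mode, statistic = statistic,
                 length_days = length_days,
                 end_date = if (mode == "fixed_end") end_date else NULL,
                 season_extremum = season_extremum),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(format_window_spec(x), "\n")
  invisible(x)
}

format_window_spec <- function(spec) {
  if (spec$mode == "fixed_end") {
    if (spec$length_days == 1L)
      sprintf("1 day, %s", spec$end_date)
    else
      sprintf("%d-day mean, %s", spec$length_days, spec$end_date)
  } else {
    sprintf("%d-day %s.", spec$length_days, spec$season_extremum)
  }
}

#' Metric definition
#'
#' Binds a metric name and category to the window specification that
#' collapses its daily record to annual values.
#'
#' @param name Metric name (e.g. `"DMC"`).
#' @param category One of `"fire_danger"`, `"water_balance"`, `"climate"`.
#' @param window A [window_spec()].
#' @param record_start_year First year with usable data.
#' @return An object of class `metric_definition`.
#' @export
metric_definition <- function(name, category = c("fire_danger",
                                                 "water_balance", "climate"),
                              window, record_start_year) {
  category <- match.arg(category)
  stopifnot(inherits(window, "window_spec"))
  structure(list(name = as.character(name)[1L], category = category,
                 window = window,
                 record_start_year = as.integer(record_start_year)),
            class = "metric_definition")
}

#' @export
print.metric_definition <- function(x, ...) {
  cat(sprintf("<metric_definition> %s [%s]: %s (record from %d)\n", x$name,
              x$category, format_window_spec(x$window), x$record_start_year))
  invisible(x)
}

month_day <- function(year, md) as.Date(sprintf("%d-%s", year, md))

#' Collapse a daily metric to one annual fire-season value per year
#'
#' Applies a [window_spec()] to every year of a daily record within the fire
#' season (default 1 May to 1 October, inclusive). Years whose daily coverage
#' is insufficient for the requested window are dropped with a warning.
#'
#' @param daily A [daily_series()].
#' @param spec A [window_spec()].
#' @param season Length-2 character vector of `"MM-DD"` season start and end.
#' @return An [annual_series()], one value per retained year.
#' @examples
#' d <- generate_daily_metric(2000:2005, seed = 1)
#' seasonal_summary(d, window_spec("floating", 30, season_extremum = "min"))
#' @export
seasonal_summary <- function(daily, spec, season = c("05-01", "10-01")) {
  stopifnot(inherits(daily, "daily_series"), inherits(spec, "window_spec"))
  yrs <- sort(unique(as.integer(format(daily$dates, "%Y"))))
  out_years <- integer(0)
  out_vals <- numeric(0)
  dropped <- integer(0)
  for (y in yrs) {
    v <- annual_window_value(daily, spec, y, season)
    if (is.na(v)) dropped <- c(dropped, y)
    else {
      out_years <- c(out_years, y)
      out_vals <- c(out_vals, v)
    }
  }
  if (length(dropped))
    warning(sprintf("dropped %d year(s) with insufficient season coverage: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (!length(out_years)) stop("no year had sufficient season coverage")
  if (any(diff(out_years) != 1L)) {
    # retain the longest contiguous run so the result is a valid annual series
    runs <- split(out_years, cumsum(c(1L, diff(out_years) != 1L)))
    keep <- runs[[which.max(lengths(runs))]]
    warning(sprintf("non-contiguous coverage; keeping %d-%d", min(keep),
                    max(keep)))
    sel <- out_years %in% keep
    out_years <- out_years[sel]
    out_vals <- out_vals[sel]
  }
  annual_series(out_years, out_vals,
                name = sprintf("%s [%s]", daily$name,
                               format_window_spec(spec)))
}

# One year's windowed value; NA when the year's coverage is insufficient.
annual_window_value <- function(daily, spec, year, season) {
  len <- spec$length_days
  if (spec$mode == "fixed_end") {
    end <- month_day(year, spec$end_date)
    need <- seq(end - len + 1L, end, by = "day")
    idx <- match(need, daily$dates)
    if (anyNA(idx)) return(NA_real_)
    mean(daily$values[idx])
  } else {
    s0 <- month_day(year, season[1])
    s1 <- month_day(year, season[2])
    need <- seq(s0, s1, by = "day")
    idx <- match(need, daily$dates)
    if (anyNA(idx)) return(NA_real_)
    v <- daily$values[idx]
    if (len > length(v)) return(NA_real_)
    rm_ <- data.table::frollmean(v, len, align = "right")
    rm_ <- rm_[!is.na(rm_)]
    if (spec$season_extremum == "max") max(rm_) else min(rm_)
  }
}

#' Enumerate a candidate grid of window specifications
#'
#' Builds the search space for [optimize_window_definition()]: for each
#' length, a floating max and a floating min, plus a fixed-end mean at each
#' requested end date. The default grid spans point values through 120-day
#' windows and late-season anchor dates.
#'
#' @param lengths Positive day counts.
#' @param end_dates `"MM-DD"` fixed-end anchors.
#' @return A deduplicated list of [window_spec()] objects.
#' @examples
#' length(candidate_window_grid())  # 63
#' @export
candidate_window_grid <- function(lengths = c(1L, 15L, 30L, 45L, 60L, 75L,
                                              90L, 105L, 120L),
                                  end_dates = c("08-01", "08-15", "09-01",
                                                "09-15", "10-01")) {
  if (!length(lengths)) stop("`lengths` must be non-empty")
  if (!length(end_dates)) stop("`end_dates` must be non-empty")
  if (any(lengths < 1)) stop("`lengths` must be positive")
  grid <- list()
  for (len in lengths) {
    grid[[length(grid) + 1L]] <- window_spec("floating", len,
                                             season_extremum = "max")
    grid[[length(grid) + 1L]] <- window_spec("floating", len,
                                             season_extremum = "min")
  }
  for (len in lengths)
    for (ed in end_dates)
      grid[[length(grid) + 1L]] <- window_spec("fixed_end", len,
                                               end_date = ed)
  keys <- vapply(grid, function(s)
    paste(s$mode, s$length_days, s$season_extremum,
          if (is.null(s$end_date)) "" else s$end_date), "")
  grid[!duplicated(keys)]
}

#' Find the window definition that best predicts the response
#'
#' Summarizes the daily metric under every candidate [window_spec()] and
#' scores each by the full-record r-squared between the annual summary and
#' the response (log area burned). Ties break toward shorter windows, then
#' fixed-end before floating. A best r-squared below 0.05 flags the metric
#' as having no informative window (diagnostic only).
#'
#' @param daily A [daily_series()].
#' @param response An [annual_series()] (ln area burned).
#' @param grid List of [window_spec()] candidates; default
#'   [candidate_window_grid()].
#' @param season Fire-season `"MM-DD"` bounds.
#' @param category Metric category recorded in the returned definition.
#' @param min_overlap Minimum overlapping years required (default 30).
#' @return A list of class `window_search`: `definition` (the winning
#'   [metric_definition()]), `scores` (data frame of every spec with its r2
#'   and overlap), `best_r2`, and `no_informative_window`.
#' @export
optimize_window_definition <- function(daily, response,
                                       grid = candidate_window_grid(),
                                       season = c("05-01", "10-01"),
                                       category = "fire_danger",
                                       min_overlap = 30L) {
  stopifnot(inherits(daily, "daily_series"),
            inherits(response, "annual_series"))
  if (!length(grid)) stop("empty candidate grid")
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    spec <- grid[[i]]
    ann <- suppressWarnings(seasonal_summary(daily, spec, season))
    common <- intersect(ann$years, response$years)
    r2 <- NA_real_
    if (length(common) >= 3L) {
      x <- ann$values[match(common, ann$years)]
      y <- response$values[match(common, response$years)]
      if (stats::sd(x) > 0 && stats::sd(y) > 0)
        r2 <- stats::cor(x, y)^2
    }
    rows[[i]] <- data.frame(spec = format_window_spec(spec),
                            mode = spec$mode,
                            length_days = spec$length_days,
                            season_extremum = spec$season_extremum,
                            end_date = if (is.null(spec$end_date)) NA_character_
                                       else spec$end_date,
                            n_overlap = length(common), r2 = r2,
                            stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  if (max(scores$n_overlap) == 0L)
    stop("no overlapping years between the daily metric and the response")
  if (max(scores$n_overlap) < min_overlap)
    stop(sprintf("only %d overlapping years (need >= %d)",
                 max(scores$n_overlap), min_overlap))
  ok <- which(!is.na(scores$r2))
  if (!length(ok)) stop("no candidate window produced a scorable summary")
  ord <- ok[order(-scores$r2[ok], scores$length_days[ok],
                  scores$mode[ok] != "fixed_end")]
  best <- ord[1L]
  def <- metric_definition(daily$name, category, grid[[best]],
                           record_start_year =
                             min(as.integer(format(daily$dates, "%Y"))))
  structure(list(definition = def, scores = scores,
                 best_index = best, best_r2 = scores$r2[best],
                 no_informative_window = scores$r2[best] < 0.05),
            class = "window_search")
}

#' @export
print.window_search <- function(x, ...) {
  cat(sprintf("<window_search> best: %s (r2 = %.3f)%s\n",
              x$scores$spec[x$best_index], x$best_r2,
              if (x$no_informative_window) "  [no informative window]" else ""))
  invisible(x)
}
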