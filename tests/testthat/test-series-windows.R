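test_that("seasonal summary of a constant daily series is the constant", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2003-10-31"), by = "day")
  d <- daily_series(dates, rep(7.25, length(dates)))
  specs <- list(window_spec("floating", 30, season_extremum = "max"),
                window_spec("floating", 90, season_extremum = "min"),
                window_spec("fixed_end", 45, end_date = "09-01"),
                window_spec("fixed_end", 1, end_date = "09-01"))
  for (spec in specs) {
    ann <- seasonal_summary(d, spec)
    expect_equal(ann$values, rep(7.25, 4))
    expect_equal(ann$years, 2000:2003)
  }
})

test_that("floating windows match a brute-force placement oracle", {
  season_days <- seq(as.Date("2001-05-01"), as.Date("2001-10-01"), by = "day")
  n <- length(season_days)
  # ramp 1..n: the 3-day max is the mean of the last 3 in-season days
  d <- daily_series(season_days, seq_len(n))
  got <- seasonal_summary(d, window_spec("floating", 3,
                                         season_extremum = "max"))
  expect_equal(got$values, mean(c(n - 2, n - 1, n)))
  # arbitrary values against the oracle, both extrema, several lengths
  set.seed(42)
  v <- rnorm(n, 50, 10)
  d2 <- daily_series(season_days, v)
  for (len in c(1L, 7L, 30L, 105L)) {
    for (ext in c("max", "min")) {
      got <- seasonal_summary(d2, window_spec("floating", len,
                                              season_extremum = ext))
      expect_equal(got$values, brute_floating(v, len, ext))
    }
  }
})

test_that("fixed-end point lookup returns the value on the anchor date", {
  dates <- seq(as.Date("1990-01-01"), as.Date("1990-10-31"), by = "day")
  v <- seq_along(dates) * 0.0
  v[dates == as.Date("1990-09-01")] <- 7.5
  d <- daily_series(dates, v)
  got <- seasonal_summary(d, window_spec("fixed_end", 1,
                                         end_date = "09-01"))
  expect_equal(got$values, 7.5)
})

test_that("fixed-end windows may reach back before the season start", {
  dates <- seq(as.Date("1990-03-01"), as.Date("1990-10-31"), by = "day")
  d <- daily_series(dates, as.numeric(format(dates, "%j")))
  # 90-day mean ending 1 Sep starts 4 Jun; 120-day ending 1 Aug starts 4 Apr
  got <- seasonal_summary(d, window_spec("fixed_end", 120,
                                         end_date = "08-01"))
  end_doy <- as.integer(format(as.Date("1990-08-01"), "%j"))
  expect_equal(got$values, mean((end_doy - 119):end_doy))
})

test_that("years with insufficient coverage are dropped with a warning", {
  full <- seq(as.Date("2000-01-01"), as.Date("2000-10-31"), by = "day")
  partial <- seq(as.Date("2001-05-15"), as.Date("2001-10-31"), by = "day")
  d <- daily_series(c(full, partial), rep(1, length(full) + length(partial)))
  expect_warning(
    got <- seasonal_summary(d, window_spec("floating", 10,
                                           season_extremum = "max")),
    "insufficient season coverage")
  expect_equal(got$years, 2000L)
})

test_that("window spec invariants are enforced", {
  expect_error(window_spec("floating", 30), "season_extremum")
  expect_error(window_spec("fixed_end", 30), "end_date")
  expect_error(window_spec("fixed_end", 30, end_date = "09-01",
                           season_extremum = "max"), "extremum")
  expect_error(window_spec("floating", 200, season_extremum = "max"),
               "160")
  expect_error(window_spec("floating", 0, season_extremum = "max"),
               "positive")
})

test_that("candidate grid enumerates floating and fixed-end combinations", {
  g <- candidate_window_grid(lengths = 30L, end_dates = "09-01")
  expect_length(g, 3L)
  expect_setequal(vapply(g, `[[`, "", "mode"),
                  c("floating", "floating", "fixed_end"))
  expect_length(candidate_window_grid(), 63L)
  expect_error(candidate_window_grid(lengths = integer(0)), "non-empty")
  expect_error(candidate_window_grid(end_dates = character(0)), "non-empty")
})

test_that("floating max >= floating min for every year on any series", {
  for (seed in 1:3) {
    d <- generate_daily_metric(1980:1989, event_scale = 10, seed = seed)
    for (len in c(5L, 45L)) {
      mx <- seasonal_summary(d, window_spec("floating", len,
                                            season_extremum = "max"))
      mn <- seasonal_summary(d, window_spec("floating", len,
                                            season_extremum = "min"))
      expect_true(all(mx$values >= mn$values))
    }
  }
})

test_that("long floating windows converge toward the season mean", {
  season_days <- seq(as.Date("2001-05-01"), as.Date("2001-10-01"), by = "day")
  n <- length(season_days)
  d <- daily_series(season_days, seq_len(n))  # monotone grid
  gap <- function(len) {
    mx <- seasonal_summary(d, window_spec("floating", len,
                                          season_extremum = "max"))$values
    mn <- seasonal_summary(d, window_spec("floating", len,
                                          season_extremum = "min"))$values
    mx - mn
  }
  gaps <- vapply(c(10L, 60L, 120L, n), gap, 0)
  expect_true(all(diff(gaps) < 0))
  expect_equal(gaps[4L], 0)  # full-season window == season mean
})

test_that("window optimization recovers the generating definition", {
  d <- generate_daily_metric(1961:2000, event_scale = 12, seed = 11)
  truth <- window_spec("floating", 30, season_extremum = "min")
  x <- seasonal_summary(d, truth)
  set.seed(12)
  resp <- annual_series(x$years, 2 * x$values + rnorm(length(x$years), 0,
                                                      0.05 * sd(x$values)),
                        "response")
  got <- optimize_window_definition(d, resp)
  win <- got$definition$window
  expect_equal(win$mode, "floating")
  expect_equal(win$length_days, 30L)
  expect_equal(win$season_extremum, "min")
  expect_false(got$no_informative_window)
  expect_equal(nrow(got$scores), 63L)
})

test_that("optimization is invariant to affine rescaling of the daily series", {
  d <- generate_daily_metric(1961:1995, event_scale = 12, seed = 21)
  x <- seasonal_summary(d, window_spec("floating", 45,
                                       season_extremum = "max"))
  set.seed(22)
  resp <- annual_series(x$years, x$values + rnorm(length(x$years), 0,
                                                  0.2 * sd(x$values)),
                        "response")
  d2 <- daily_series(d$dates, 3.5 * d$values - 100, name = d$name)
  a <- optimize_window_definition(d, resp)
  b <- optimize_window_definition(d2, resp)
  expect_equal(a$scores$r2, b$scores$r2, tolerance = 1e-10)
  expect_equal(a$best_index, b$best_index)
})

test_that("uninformative responses score near zero and the flag mirrors the threshold", {
  d <- generate_daily_metric(1961:2000, event_scale = 12, seed = 31)
  set.seed(32)
  resp <- annual_series(1961:2000, rnorm(40), "noise")
  got <- optimize_window_definition(d, resp)
  expect_lt(got$best_r2, 0.3)
  expect_identical(got$no_informative_window, got$best_r2 < 0.05)
})

test_that("single-spec grids and missing overlap behave as specified", {
  d <- generate_daily_metric(1961:1995, event_scale = 12, seed = 41)
  spec <- window_spec("fixed_end", 30, end_date = "09-01")
  x <- seasonal_summary(d, spec)
  resp <- annual_series(x$years, x$values, "response")
  got <- optimize_window_definition(d, resp, grid = list(spec))
  expect_equal(nrow(got$scores), 1L)
  expect_equal(got$best_r2, 1, tolerance = 1e-10)
  far <- annual_series(1800:1840, rnorm(41), "far")
  expect_error(optimize_window_definition(d, far), "overlap")
})

test_that("annual series reject gaps, NAs and length mismatches", {
  expect_error(annual_series(c(2000, 2002), c(1, 2)), "consecutive")
  expect_error(annual_series(2000:2001, c(1, NA)), "missing")
  expect_error(annual_series(2000:2002, 1:2), "equal length")
  expect_error(daily_series(as.Date(c("2000-01-02", "2000-01-01")), 1:2),
               "increasing")
})
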