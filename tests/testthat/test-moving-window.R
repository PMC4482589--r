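test_that("window enumeration matches the 1902-2008 design", {
  w <- calibration_windows(1902, 2008, 21)
  expect_equal(nrow(w), 87L)
  expect_equal(w$center_year[1L], 1912L)
  expect_equal(w$start_year[1L], 1902L)
  expect_equal(w$end_year[1L], 1922L)
  expect_equal(w$center_year[87L], 1998L)
  expect_equal(w$end_year[87L], 2008L)
  # shorter soil-moisture-style record
  expect_equal(nrow(calibration_windows(1916, 2008, 21)), 73L)
  # single-window boundary
  expect_equal(nrow(calibration_windows(1902, 1922, 21)), 1L)
  expect_error(calibration_windows(1902, 2008, 20), "odd")
  expect_error(calibration_windows(2000, 2010, 21), "shorter")
})

test_that("window count formula holds over random spans and widths", {
  set.seed(13)
  for (i in 1:25) {
    width <- sample(c(5L, 9L, 21L, 31L, 41L), 1)
    first <- sample(1800:1950, 1)
    last <- first + width - 1L + sample(0:120, 1)
    w <- calibration_windows(first, last, width)
    expect_equal(nrow(w), (last - first + 1L) - width + 1L)
    expect_true(all(w$end_year - w$start_year + 1L == width))
    expect_true(all(w$center_year == (w$start_year + w$end_year) / 2))
  }
})

test_that("sweep under a constant relationship shows skill nearly everywhere", {
  # expectations over replicate datasets: a single record's median window r2
  # wanders widely because 21-yr correlations are noisy and shared
  stats <- vapply(1:8, function(i) {
    d <- generate_null_dataset(r2_target = 0.5, seed = 70 + i)
    s <- climate_fire_sweep(d$climate, d$ln_area)
    c(frac_skill = mean(s$ce > 0), med_r2 = median(s$r2))
  }, numeric(2))
  expect_gte(mean(stats["frac_skill", ]), 0.9)
  expect_lt(abs(mean(stats["med_r2", ]) - 0.5), 0.1)
  d <- generate_null_dataset(r2_target = 0.5, seed = 77)
  s <- climate_fire_sweep(d$climate, d$ln_area)
  expect_equal(nrow(s), 87L)
  expect_true(all(s$mse_null > 0))
})

test_that("a full-span window has no validation years", {
  d <- generate_null_dataset(n_years = 21, seed = 1)
  expect_error(climate_fire_sweep(d$climate, d$ln_area, width = 21),
               "no validation years")
})

test_that("models calibrated inside an altered regime lose skill elsewhere", {
  g <- generate_scenario(scenario_spec("altered_relationship", seed = 31))
  y <- log_transform_area(g$area_ha)
  s <- climate_fire_sweep(g$climate, y)
  inside <- s$center_year >= 1995  # windows fully within the 1985+ regime
  expect_lt(median(s$ce[inside]), 0)
})

test_that("predictor ranking reproduces both score modes", {
  # constructed sweep statistics: r2 = (.4,.5,.6), CE = (.1,.3,.2)
  base <- climate_fire_sweep(
    generate_null_dataset(n_years = 31, seed = 3)$climate,
    generate_null_dataset(n_years = 31, seed = 3)$ln_area, width = 21)
  fake <- base[1:3, ]
  fake$r2 <- c(0.4, 0.5, 0.6)
  fake$r2_adj <- NA_real_
  fake$ce <- c(0.1, 0.3, 0.2)
  attributes(fake) <- c(attributes(fake),
                        attributes(base)[c("predictor_names", "width",
                                           "span", "response_name")])
  class(fake) <- c("fire_sweep", "data.frame")
  r <- rank_predictors(list(demo = fake))
  expect_equal(r$score_product_of_medians, 0.5 * 0.2)
  expect_equal(r$score_median_of_products, median(c(0.04, 0.15, 0.12)))
  expect_equal(r$score, 0.12)  # default mode is median_of_products
  expect_equal(r$rank, 1L)     # single set ranks first regardless
})

test_that("dominance in every window implies a higher rank in both modes", {
  d <- generate_null_dataset(r2_target = 0.6, seed = 21)
  strong <- climate_fire_sweep(d$climate, d$ln_area)
  set.seed(22)
  weak_x <- annual_series(d$climate$years,
                          d$climate$values + rnorm(107, 0, 2), "weak")
  weak <- climate_fire_sweep(weak_x, d$ln_area)
  expect_true(all(strong$r2 > weak$r2) && all(strong$ce > weak$ce))
  for (mode in c("median_of_products", "product_of_medians")) {
    r <- rank_predictors(list(strong = strong, weak = weak), mode = mode)
    expect_equal(r$predictor_set[r$rank == 1L], "strong")
  }
})

test_that("score modes coincide when statistics are constant across windows", {
  base <- climate_fire_sweep(
    generate_null_dataset(n_years = 41, seed = 5)$climate,
    generate_null_dataset(n_years = 41, seed = 5)$ln_area, width = 21)
  const <- base
  const$r2 <- 0.45
  const$r2_adj <- NA_real_
  const$ce <- 0.3
  r <- rank_predictors(list(c = const))
  expect_equal(r$score_product_of_medians, r$score_median_of_products)
})

test_that("ranking entries are invariant to predictor-set order", {
  d1 <- generate_null_dataset(seed = 41)
  set.seed(42)
  x2 <- annual_series(d1$climate$years, d1$climate$values + rnorm(107, 0, 1),
                      "x2")
  s1 <- climate_fire_sweep(d1$climate, d1$ln_area)
  s2 <- climate_fire_sweep(x2, d1$ln_area)
  a <- rank_predictors(list(A = s1, B = s2))
  b <- rank_predictors(list(B = s2, A = s1))
  a <- a[order(a$predictor_set), ]
  b <- b[order(b$predictor_set), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("parameter trajectories are flat at one for a deterministic y = 2x", {
  x <- make_series(sin(seq_len(60)), name = "x")
  y <- make_series(2 * x$values, name = "y")
  s <- climate_fire_sweep(x, y)
  tr <- parameter_series(s)
  expect_named(tr, c("center_year", "std_beta_x"))
  expect_equal(tr$std_beta_x, rep(1, nrow(tr)))
})

test_that("parameter trajectories shift at an altered-regime boundary", {
  # default altered scenario: std beta rises from 1/sqrt(2) to 2/sqrt(5)
  g <- generate_scenario(scenario_spec("altered_relationship", seed = 51))
  s <- climate_fire_sweep(g$climate, g$ln_area)
  tr <- parameter_series(s)
  early <- tr$std_beta_climate[tr$center_year <= 1970]
  late <- tr$std_beta_climate[tr$center_year >= 1995]
  expect_gt(mean(late), mean(early) + 0.1)
})

test_that("overprediction bias matches its definition", {
  y <- make_series(seq(4, 9, length.out = 86), name = "ln_area")
  x <- make_series(y$values, start = 1902L, name = "x")
  perfect <- structure(list(beta0 = 0, betas = c(x = 1),
                            years = 2100:2120), class = "fire_ols")
  inflated <- structure(list(beta0 = 0, betas = c(x = 1.2),
                             years = 2100:2120), class = "fire_ols")
  expect_equal(overprediction_bias(perfect, x, y, y$years)$per_model, 0)
  expect_equal(overprediction_bias(inflated, x, y, y$years)$per_model, 20,
               tolerance = 1e-10)
  both <- overprediction_bias(list(perfect, inflated), x, y, y$years)
  expect_equal(both$mean, 10, tolerance = 1e-10)
  expect_equal(both$sd, sd(c(0, 20)), tolerance = 1e-10)
  overlapping <- structure(list(beta0 = 0, betas = c(x = 1),
                                years = 1902:1922), class = "fire_ols")
  expect_error(overprediction_bias(overlapping, x, y, y$years), "overlap")
})

test_that("recent-regime calibration overpredicts earlier fire activity", {
  g <- generate_scenario(scenario_spec("altered_relationship", seed = 61))
  y <- log_transform_area(g$area_ha)
  fit <- fit_ols(g$climate, y, years = 1988:2008)
  bias <- overprediction_bias(fit, g$climate, y, 1902:1961)
  expect_gt(bias$per_model, 0)
})
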