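test_that("log transform offsets only exact zeros", {
  a <- make_series(c(0, 1, exp(3), 0.5))
  got <- log_transform_area(a)
  expect_equal(got$values, c(log(10), 0, 3, log(0.5)))
  expect_equal(log_transform_area(make_series(0), zero_offset_ha = 1)$values,
               0)
  expect_error(log_transform_area(make_series(c(1, -2))), "negative")
})

test_that("exact linear relationships are recovered perfectly", {
  x <- make_series(seq(-2, 2, length.out = 20), name = "x")
  y <- make_series(2 * x$values, name = "y")
  fit <- fit_ols(x, y)
  expect_equal(unname(fit$betas), 2)
  expect_equal(fit$beta0, 0)
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$std_betas), 1)
})

test_that("an orthogonal response gives zero slope and zero r2", {
  # x alternates +-1; y repeats +1,+1,-1,-1: exactly orthogonal over n = 20
  x <- rep(c(1, -1), 10)
  y <- rep(c(1, 1, -1, -1), 5)
  expect_equal(sum(x * y), 0)
  fit <- fit_ols(make_series(x, name = "x"), make_series(y, name = "y"))
  expect_equal(unname(fit$betas), 0)
  expect_equal(fit$r2, 0)
})

test_that("standardized slope equals the Pearson correlation (simple case)", {
  set.seed(5)
  for (i in 1:5) {
    xv <- rnorm(40)
    yv <- 0.6 * xv + rnorm(40)
    fit <- fit_ols(make_series(xv, name = "x"), make_series(yv, name = "y"))
    rho <- cor(xv, yv)
    expect_equal(unname(fit$std_betas), rho, tolerance = 1e-10)
    expect_equal(unname(fit$std_betas)^2, fit$r2, tolerance = 1e-10)
    expect_equal(sign(unname(fit$std_betas)), sign(rho))
  }
})

test_that("fit_ols reproduces the normal-equations oracle on random designs", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n)
    yv <- rnorm(n)
    preds <- lapply(seq_len(p), function(j)
      make_series(X[, j], name = paste0("x", j)))
    fit <- fit_ols(preds, make_series(yv, name = "y"))
    oracle <- normal_equations_fit(X, yv)
    expect_equal(unname(c(fit$beta0, fit$betas)), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("fit_ols validates its design", {
  x1 <- make_series(rnorm(30), name = "a")
  x2 <- make_series(x1$values * 2, name = "b")
  y <- make_series(rnorm(30), name = "y")
  expect_error(fit_ols(list(x1, x2), y), "collinear")
  expect_error(fit_ols(x1, y, years = 1902:1905), "too few")
  expect_error(fit_ols(x1, y, years = 1800:1850), "cover")
  expect_error(fit_ols(rep(list(x1), 4), y), "1 and 3")
})

test_that("global standardization moments differ from window-local ones", {
  set.seed(7)
  x <- make_series(rnorm(60), name = "x")
  y <- make_series(1.5 * x$values + rnorm(60), name = "y")
  loc <- fit_ols(x, y, years = 1902:1931, std_moments = "local")
  glo <- fit_ols(x, y, years = 1902:1931, std_moments = "global")
  expect_equal(loc$betas, glo$betas)  # raw slopes identical
  expect_equal(unname(glo$std_betas),
               unname(glo$betas) * sd(x$values) / sd(y$values))
  expect_false(isTRUE(all.equal(loc$std_betas, glo$std_betas)))
})

test_that("VIF matches its closed form and flags collinearity", {
  set.seed(8)
  # orthogonal pair
  a <- rnorm(50)
  b <- resid(lm(rnorm(50) ~ a))
  v <- variance_inflation_factors(list(make_series(a, name = "a"),
                                       make_series(b, name = "b")))
  expect_equal(unname(v$vif), c(1, 1), tolerance = 1e-8)
  expect_false(v$flagged)
  # sample correlation exactly 0.8 by construction
  z1 <- scale(a)[, 1]
  z2 <- scale(b)[, 1]
  x2 <- 0.8 * z1 + sqrt(1 - 0.64) * z2
  expect_equal(cor(z1, x2), 0.8, tolerance = 1e-12)
  v2 <- variance_inflation_factors(list(make_series(z1, name = "x1"),
                                        make_series(x2, name = "x2")))
  expect_equal(unname(v2$vif), rep(1 / (1 - 0.64), 2), tolerance = 1e-8)
  # duplicated predictor
  v3 <- variance_inflation_factors(list(make_series(a, name = "a"),
                                        make_series(a, name = "a2")))
  expect_true(all(is.infinite(v3$vif)))
  expect_true(v3$flagged)
  expect_error(variance_inflation_factors(list(make_series(a))), "at least 2")
})

test_that("Lilliefors statistic agrees with the nortest implementation", {
  skip_if_not_installed("nortest")
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(50 + 10 * i)
    got <- lilliefors_normality(x, n_sim = 100, seed = 1)
    expect_equal(got$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("Lilliefors test holds its nominal level and detects skewness", {
  null_stats <- lilliefors_null_distribution(107, n_sim = 4000, seed = 100)
  set.seed(101)
  pass_normal <- vapply(1:400, function(i)
    lilliefors_normality(rnorm(107), null_stats = null_stats)$pass, TRUE)
  expect_gt(mean(pass_normal), 0.91)
  expect_lt(mean(pass_normal), 0.99)
  set.seed(102)
  reject_expo <- vapply(1:100, function(i)
    !lilliefors_normality(rexp(107), null_stats = null_stats)$pass, TRUE)
  expect_gt(mean(reject_expo), 0.8)
  expect_error(lilliefors_normality(rnorm(5)), "n >= 10")
  expect_error(lilliefors_normality(rep(1, 20)), "constant")
})

test_that("CE matches closed-form cases and direct MSE arithmetic", {
  obs <- c(0, 1, 2, 3)
  expect_equal(coefficient_of_efficiency(obs, obs)$ce, 1)
  expect_equal(coefficient_of_efficiency(obs, rep(mean(obs), 4))$ce, 0)
  got <- coefficient_of_efficiency(obs, c(1, 1, 2, 2))
  expect_equal(got$mse_model, 0.5)
  expect_equal(got$mse_null, 1.25)
  expect_equal(got$ce, 0.6)
  expect_error(coefficient_of_efficiency(rep(2, 6), rnorm(6)),
               "zero variance")
  expect_error(coefficient_of_efficiency(1:4, 1:3), "equal length")
})

test_that("CE is invariant to common shifts and rescalings", {
  set.seed(10)
  for (i in 1:10) {
    obs <- rnorm(20)
    pred <- obs + rnorm(20, 0, 0.5)
    base <- coefficient_of_efficiency(obs, pred)$ce
    expect_equal(coefficient_of_efficiency(obs + 7, pred + 7)$ce, base,
                 tolerance = 1e-12)
    expect_equal(coefficient_of_efficiency(obs * 3.2, pred * 3.2)$ce, base,
                 tolerance = 1e-12)
    expect_equal(base, brute_ce(obs, pred), tolerance = 1e-12)
  }
})
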