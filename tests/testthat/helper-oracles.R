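# Independent oracles used across tests. These deliberately use brute-force
# or closed-form routes that do not share code with the package internals.

# OLS via explicit normal equations.
normal_equations_fit <- function(X, y) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1L]
}

# CE by direct MSE arithmetic.
brute_ce <- function(obs, pred) {
  1 - mean((obs - pred)^2) / mean((obs - mean(obs))^2)
}

# Brute-force floating-window summary: every placement inside the season.
brute_floating <- function(values, len, extremum) {
  means <- vapply(seq_len(length(values) - len + 1L),
                  function(i) mean(values[i:(i + len - 1L)]), 0)
  if (extremum == "max") max(means) else min(means)
}

# Total SSE of independent per-segment linear fits at given break indices
# (break = last index of the old segment).
brute_segment_sse <- function(y, breaks) {
  bounds <- c(0L, breaks, length(y))
  sum(vapply(seq_len(length(bounds) - 1L), function(m) {
    idx <- (bounds[m] + 1L):bounds[m + 1L]
    sum(stats::resid(stats::lm(y[idx] ~ idx))^2)
  }, 0))
}

# All placements of k breaks with a minimum segment length.
all_break_combos <- function(n, k, min_seg) {
  m <- n - (k + 1L) * min_seg + k
  combos <- utils::combn(m, k)
  combos + (min_seg - 1L) * seq_len(k)
}

make_series <- function(values, start = 1902L, name = "s") {
  annual_series(start + seq_along(values) - 1L, values, name)
}

# Three-regime annual ln-area record with known mean shifts.
three_regime_series <- function(means = c(8, 5, 9), changes_at = c(42L, 83L),
                                n = 107L, noise_sd = 0.5, seed = 1L,
                                start = 1902L) {
  set.seed(seed)
  pidx <- findInterval(seq_len(n), c(1L, changes_at))
  make_series(stats::rnorm(n, means[pidx], noise_sd), start = start,
              name = "ln_area")
}
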