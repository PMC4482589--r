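#' Cumulative series of log area burned
#'
#' Running sum of the annual ln-area record. Mean shifts in the annual
#' series appear as slope breaks in the cumulative series, which is what the
#' piecewise fit exploits.
#'
#' @param ln_area An [annual_series()].
#' @return An [annual_series()] of running sums.
#' @export
cumulative_series <- function(ln_area) {
  stopifnot(inherits(ln_area, "annual_series"))
  annual_series(ln_area$years, cumsum(ln_area$values),
                name = paste0("cum_", ln_area$name))
}

# Per-segment OLS cost machinery for the discontinuous DP: prefix sums give
# each segment's regression SSE in O(1).
segment_cost_fns <- function(y) {
  n <- length(y)
  t <- as.numeric(seq_len(n))
  c1 <- cumsum(rep(1, n)); ct <- cumsum(t); ctt <- cumsum(t * t)
  cy <- cumsum(y); cty <- cumsum(t * y); cyy <- cumsum(y * y)
  pre <- function(v, i, j) v[j] - if (i > 1L) v[i - 1L] else 0
  function(i, j) {
    ns <- j - i + 1L
    st <- pre(ct, i, j); stt <- pre(ctt, i, j)
    sy <- pre(cy, i, j); sty <- pre(cty, i, j); syy <- pre(cyy, i, j)
    sxx <- stt - st^2 / ns
    sxy <- sty - st * sy / ns
    syy_c <- syy - sy^2 / ns
    max(syy_c - sxy^2 / sxx, 0)
  }
}

# Exact dynamic program: minimum total per-segment OLS SSE over all
# placements of k interior breaks with a minimum segment length.
dp_breaks <- function(y, k, min_seg) {
  n <- length(y)
  cost <- segment_cost_fns(y)
  nseg <- k + 1L
  F <- matrix(Inf, nseg, n)
  arg <- matrix(NA_integer_, nseg, n)
  for (j in seq_len(n)) if (j >= min_seg) F[1L, j] <- cost(1L, j)
  if (nseg > 1L) for (m in 2L:nseg) {
    for (j in seq_len(n)) {
      if (j < m * min_seg) next
      bs <- ((m - 1L) * min_seg):(j - min_seg)
      vals <- F[m - 1L, bs] + vapply(bs, function(b) cost(b + 1L, j), 0)
      best <- which.min(vals)
      F[m, j] <- vals[best]
      arg[m, j] <- bs[best]
    }
  }
  breaks <- integer(k)
  j <- n
  if (k > 0L) for (m in nseg:2L) {
    breaks[m - 1L] <- arg[m, j]
    j <- arg[m, j]
  }
  list(breaks = breaks, sse = F[nseg, n])
}

# Closed-form normal equations for the continuous (broken-stick) fit with
# hinge knots at integer positions b: O(1) per candidate combination.
continuous_sse_machinery <- function(y) {
  n <- length(y)
  t <- as.numeric(seq_len(n))
  TTn <- n * (n + 1) * (2 * n + 1) / 6
  st_suf <- function(b) (n + b + 1) * (n - b) / 2
  stt_suf <- function(b) TTn - b * (b + 1) * (2 * b + 1) / 6
  sy_suf <- c(rev(cumsum(rev(y))), 0)           # index b+1 -> sum_{t>b} y
  sty_suf <- c(rev(cumsum(rev(t * y))), 0)
  sy_tot <- sy_suf[1L]; sty_tot <- sty_suf[1L]
  syy <- sum(y * y)
  T1 <- n * (n + 1) / 2
  fit <- function(b) {                          # b: sorted integer knots
    k <- length(b)
    q <- k + 2L
    A <- matrix(0, q, q)
    r <- numeric(q)
    A[1L, 1L] <- n; A[1L, 2L] <- T1; A[2L, 2L] <- TTn
    r[1L] <- sy_tot; r[2L] <- sty_tot
    if (k > 0L) for (j in seq_len(k)) {
      bj <- b[j]
      A[1L, 2L + j] <- st_suf(bj) - bj * (n - bj)
      A[2L, 2L + j] <- stt_suf(bj) - bj * st_suf(bj)
      r[2L + j] <- sty_suf[bj + 1L] - bj * sy_suf[bj + 1L]
      for (i in seq_len(j)) {
        bi <- b[i]
        A[2L + i, 2L + j] <- stt_suf(bj) - (bi + bj) * st_suf(bj) +
          bi * bj * (n - bj)
      }
    }
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    cf <- solve(A, r)
    list(sse = max(syy - sum(cf * r), 0), coef = cf)
  }
  fit
}

# Exhaustive search over integer knot combinations for the continuous fit.
enumerate_continuous <- function(y, k, min_seg, max_combos = 5e5) {
  n <- length(y)
  fit <- continuous_sse_machinery(y)
  m <- n - (k + 1L) * min_seg + k        # free positions after spacing
  n_combos <- choose(m, k)
  if (n_combos > max_combos)
    stop(sprintf(
      "continuous search space too large (%.0f combinations); use continuity = FALSE",
      n_combos))
  combos <- utils::combn(m, k)           # c_i strictly increasing
  best_sse <- Inf
  best_b <- NULL
  offs <- min_seg * seq_len(k)           # b_i = c_i + min_seg*i - i + (i-1)?
  for (ci in seq_len(ncol(combos))) {
    b <- combos[, ci] + offs - seq_len(k)  # enforce gaps >= min_seg
    f <- fit(b)
    if (f$sse < best_sse) {
      best_sse <- f$sse
      best_b <- b
    }
  }
  list(breaks = best_b, sse = best_sse, fit = fit)
}

#' Piecewise linear regression on the cumulative log area burned series
#'
#' Locates the globally SSE-optimal placement of `n_breakpoints` interior
#' breaks in a piecewise-linear fit to the cumulative series. The default
#' fit is continuous at the breaks (free-knot segmented regression, found by
#' exhaustive search over integer knot positions with closed-form normal
#' equations); `continuity = FALSE` fits each segment independently and uses
#' an exact dynamic program. Because the input is cumulative, each segment's
#' slope estimates the mean annual ln-area within it, so breaks mark mean
#' shifts in fire activity. A break labels the first year of the new regime.
#'
#' @param cum A [cumulative_series()] result (or any annual series).
#' @param n_breakpoints Number of interior breaks (>= 1; the full analysis
#'   uses 3).
#' @param min_segment Minimum segment length in years (default 5) to
#'   prevent edge-hugging breaks.
#' @param continuity Enforce continuity at breaks (default `TRUE`).
#' @return An object of class `changepoint_fit`: `breakpoint_years`,
#'   `breakpoint_indices`, `segment_slopes`, `sse`, `sse_null` (no-break
#'   straight-line SSE), `improvement` and `improvement_share` per break,
#'   `degenerate` (no SSE improvement over a single line), `n_breakpoints`,
#'   `continuity`, `min_segment`.
#' @export
piecewise_fit <- function(cum, n_breakpoints = 3L, min_segment = 5L,
                          continuity = TRUE) {
  stopifnot(inherits(cum, "annual_series"))
  k <- as.integer(n_breakpoints)
  min_segment <- as.integer(min_segment)
  if (k < 1L) stop("n_breakpoints must be >= 1")
  if (min_segment < 2L) stop("min_segment must be >= 2")
  y <- cum$values
  n <- length(y)
  if (n < min_segment * (k + 1L))
    stop(sprintf("record too short: %d breakpoints with %d-yr segments need >= %d yr",
                 k, min_segment, min_segment * (k + 1L)))
  if (continuity) {
    sol <- enumerate_continuous(y, k, min_segment)
    fitfun <- sol$fit
    sse0 <- fitfun(integer(0))$sse
    cf <- fitfun(sol$breaks)$coef
    slopes <- cf[2L] + cumsum(c(0, cf[-(1:2)]))
    sse_without <- vapply(seq_len(k), function(j)
      fitfun(sol$breaks[-j])$sse, 0)
  } else {
    sol <- dp_breaks(y, k, min_segment)
    cost <- segment_cost_fns(y)
    sse0 <- cost(1L, n)
    bounds <- c(0L, sol$breaks, n)
    slopes <- vapply(seq_len(k + 1L), function(m) {
      idx <- (bounds[m] + 1L):bounds[m + 1L]
      stats::cov(idx, y[idx]) / stats::var(idx)
    }, 0)
    sse_without <- vapply(seq_len(k), function(j) {
      b <- sol$breaks[-j]
      bb <- c(0L, b, n)
      sum(vapply(seq_len(length(b) + 1L), function(m)
        cost(bb[m] + 1L, bb[m + 1L]), 0))
    }, 0)
  }
  improvement <- pmax(sse_without - sol$sse, 0)
  tot <- sum(improvement)
  degenerate <- (sse0 - sol$sse) <= 1e-8 * max(sse0, 1)
  structure(list(breakpoint_years = cum$years[sol$breaks + 1L],
                 breakpoint_indices = sol$breaks,
                 segment_slopes = unname(slopes), sse = sol$sse,
                 sse_null = sse0, improvement = improvement,
                 improvement_share = if (tot > 0) improvement / tot
                                     else rep(0, k),
                 degenerate = degenerate, n_breakpoints = k,
                 continuity = continuity, min_segment = min_segment),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf("<changepoint_fit> %d break(s) at %s%s\n", x$n_breakpoints,
              paste(x$breakpoint_years, collapse = ", "),
              if (x$degenerate) "  [degenerate: no SSE improvement]" else ""))
  cat(sprintf("  segment slopes (mean annual ln-area): %s\n",
              paste(sprintf("%.2f", x$segment_slopes), collapse = ", ")))
  invisible(x)
}
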