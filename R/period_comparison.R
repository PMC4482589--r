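#' Largest significant autocorrelation lag
#'
#' Sample autocorrelations at lags 1..`max_lag` with the usual large-sample
#' 95% bound `1.96/sqrt(n)`; a lag is significant when `|r_k|` exceeds the
#' bound. The largest significant lag sets the block length for the block
#' bootstrap (0 when none is significant).
#'
#' @param x Numeric series (chronological order), n >= 20, non-constant.
#' @param max_lag Largest lag screened (default 5).
#' @return List: `lag` (largest significant, 0 if none), `acf` (r_1..r_max),
#'   `threshold`, `significant` (logical per lag).
#' @export
significant_autocorrelation_lag <- function(x, max_lag = 5L) {
  x <- as.numeric(x)
  if (length(x) < 20L) stop("autocorrelation screen requires n >= 20")
  if (stats::sd(x) == 0) stop("constant series")
  r <- drop(stats::acf(x, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf)[-1L]
  thr <- 1.96 / sqrt(length(x))
  sig <- abs(r) > thr
  list(lag = if (any(sig)) max(which(sig)) else 0L,
       acf = r, threshold = thr, significant = sig)
}

#' Kruskal-Wallis rank analysis of variance
#'
#' Rank-based one-way test that the groups share a distribution, using the
#' chi-square approximation with tie correction.
#'
#' @param groups List of 2+ numeric vectors, each with n >= 3.
#' @return List: `chi2`, `df`, `p_analytic`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$chi2  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 3L))
    stop("each group must have at least 3 observations")
  kt <- stats::kruskal.test(groups)
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p_analytic = kt$p.value)
}

# Tie-corrected H statistic without htest overhead, for bootstrap loops.
# Agrees with stats::kruskal.test (verified in the test suite).
kw_statistic <- function(values, group_index) {
  n <- length(values)
  r <- rank(values)
  rs <- rowsum(r, group_index)
  ns <- tabulate(group_index)
  ns <- ns[ns > 0L]
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  cnt <- tabulate(match(values, values))
  cnt <- cnt[cnt > 0L]
  corr <- 1 - sum(cnt^3 - cnt) / (n^3 - n)
  if (corr > 0) h / corr else 0
}

#' Block-bootstrap p-value for the Kruskal-Wallis statistic
#'
#' Builds the null by circular block resampling of the full chronological
#' series (blocks of `block_length` consecutive years wrap around the ends),
#' reassembling to the original length and splitting at the same period
#' boundaries before recomputing the statistic. Block resampling preserves
#' serial autocorrelation while destroying any true among-period structure,
#' so the test keeps its nominal level on autocorrelated series. The
#' p-value uses the +1 small-sample correction.
#'
#' @param values Numeric series in chronological order.
#' @param periods Period assignment (factor/integer), contiguous in time.
#' @param block_length Block size in years (the largest significant
#'   autocorrelation lag; 1 reduces to an ordinary permutation-style
#'   bootstrap).
#' @param n_boot Number of bootstrap resamples (default 5000, >= 1).
#' @param seed RNG seed.
#' @return List: `p_value`, `chi2_obs`, `n_boot`, `block_length`.
#' @export
block_bootstrap_pvalue <- function(values, periods, block_length,
                                   n_boot = 5000L, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  periods <- as.integer(factor(periods, levels = unique(periods)))
  if (length(periods) != n) stop("`periods` must match `values` in length")
  if (any(diff(periods) < 0L) || any(!diff(periods) %in% c(0L, 1L)))
    stop("periods must be contiguous in time")
  block_length <- as.integer(block_length)
  if (block_length < 1L) stop("block_length must be >= 1")
  if (block_length > min(tabulate(periods)))
    stop("block_length exceeds the shortest period length")
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be >= 1")
  h_obs <- kw_statistic(values, periods)
  set.seed(seed)
  n_blocks <- ceiling(n / block_length)
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    starts <- sample.int(n, n_blocks, replace = TRUE)
    idx <- (rep(starts, each = block_length) +
              rep(seq_len(block_length) - 1L, n_blocks) - 1L) %% n + 1L
    h_star <- kw_statistic(values[idx[seq_len(n)]], periods)
    if (h_star >= h_obs) exceed <- exceed + 1L
  }
  list(p_value = (1 + exceed) / (1 + n_boot), chi2_obs = h_obs,
       n_boot = n_boot, block_length = block_length)
}

#' Tukey HSD multiple comparison with compact letter display
#'
#' Pairwise comparisons under the studentized-range (honestly significant
#' difference) criterion, by default on rank-transformed values to match the
#' rank-based omnibus test. Groups that cannot be distinguished at `alpha`
#' share a letter.
#'
#' @param groups Named (or unnamed) list of 2+ numeric vectors, each n >= 3.
#' @param alpha Family-wise level (default 0.05).
#' @param on_ranks Rank-transform pooled values first (default `TRUE`).
#' @return Named character vector of letter groupings (ordered as `groups`),
#'   with the pairwise adjusted p-values in attribute `p_matrix`.
#' @export
tukey_grouping <- function(groups, alpha = 0.05, on_ranks = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 3L))
    stop("each group must have at least 3 observations")
  k <- length(groups)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_len(k))
  v <- unlist(groups, use.names = FALSE)
  if (on_ranks) v <- rank(v)
  # safe internal level names: user labels (e.g. "1902-1942") may contain
  # the separator TukeyHSD uses in its pair row names
  lev <- paste0("G", seq_len(k))
  g <- factor(rep(lev, lengths(groups)), levels = lev)
  hsd <- stats::TukeyHSD(stats::aov(v ~ g), conf.level = 1 - alpha)$g
  pmat <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (row in rownames(hsd)) {
    pair <- match(strsplit(row, "-", fixed = TRUE)[[1L]], lev)
    pmat[pair[1L], pair[2L]] <- pmat[pair[2L], pair[1L]] <- hsd[row, "p adj"]
  }
  out <- letters_from_pmatrix(pmat, alpha,
                              order_by = vapply(split(v, g), mean, 0))
  attr(out, "p_matrix") <- pmat
  out
}

# Compact letter display: maximal cliques of the "not significantly
# different" graph, lettered in order of increasing group mean. Brute-force
# subset enumeration; fine for the handful of periods compared here.
letters_from_pmatrix <- function(pmat, alpha, order_by) {
  k <- nrow(pmat)
  adj <- pmat >= alpha
  diag(adj) <- TRUE
  subsets <- lapply(seq_len(2^k - 1L), function(m)
    which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L))
  is_clique <- vapply(subsets, function(s) all(adj[s, s]), TRUE)
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i)
    !any(vapply(cliques, function(o)
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o), TRUE)),
    TRUE)
  cliques <- cliques[maximal]
  cliques <- cliques[order(vapply(cliques, function(s) min(order_by[s]), 0))]
  lab <- rep("", k)
  for (i in seq_along(cliques))
    lab[cliques[[i]]] <- paste0(lab[cliques[[i]]], letters[i])
  stats::setNames(lab, rownames(pmat))
}

#' Compare a climate metric among discrete fire-activity periods
#'
#' Orchestrates the discrete-period test for one metric: screen the series
#' for serial autocorrelation (lags 1-5); run the Kruskal-Wallis test across
#' the periods defined by the breakpoint years; when autocorrelation is
#' present, replace the analytic chi-square p-value with a circular
#' block-bootstrap p-value whose block equals the largest significant lag;
#' and, when the among-period difference is significant, attach Tukey HSD
#' letter groupings.
#'
#' @param metric An [annual_series()] of the climate metric.
#' @param breakpoints Breakpoint years (each the first year of a new
#'   period), defining >= 2 periods of >= 10 yr each.
#' @param alpha Significance level (default 0.05).
#' @param n_boot Bootstrap resamples when needed (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @param max_lag Largest autocorrelation lag screened (default 5).
#' @return An object of class `period_comparison` with fields
#'   `metric_name`, `period_labels`, `chi2`, `df`, `p_analytic`,
#'   `largest_sig_lag`, `block_length`, `p_bootstrap` (NA when the analytic
#'   p is used), `p_used`, `n_boot`, `significant`, `letters` (NA when not
#'   significant).
#' @export
compare_periods <- function(metric, breakpoints, alpha = 0.05,
                            n_boot = 5000L, seed = 1L, max_lag = 5L) {
  stopifnot(inherits(metric, "annual_series"))
  breakpoints <- sort(as.integer(breakpoints))
  if (!length(breakpoints)) stop("at least one breakpoint is required")
  if (any(breakpoints <= min(metric$years)) ||
      any(breakpoints > max(metric$years)))
    stop("breakpoints must be interior to the metric record")
  bounds <- c(min(metric$years), breakpoints, max(metric$years) + 1L)
  pidx <- findInterval(metric$years, bounds)
  sizes <- tabulate(pidx)
  if (any(sizes < 10L))
    stop(sprintf("every period needs >= 10 yr (shortest has %d)", min(sizes)))
  labels <- vapply(seq_len(length(bounds) - 1L), function(i)
    sprintf("%d-%d", bounds[i], bounds[i + 1L] - 1L), "")
  groups <- stats::setNames(split(metric$values, pidx), labels)
  scr <- significant_autocorrelation_lag(metric$values, max_lag)
  kw <- kruskal_wallis(groups)
  block <- max(scr$lag, 1L)
  p_boot <- NA_real_
  if (scr$lag >= 1L)
    p_boot <- block_bootstrap_pvalue(metric$values, pidx, block,
                                     n_boot = n_boot, seed = seed)$p_value
  p_used <- if (is.na(p_boot)) kw$p_analytic else p_boot
  significant <- p_used < alpha
  lets <- if (significant) tukey_grouping(groups, alpha = alpha)
          else stats::setNames(rep(NA_character_, length(groups)), labels)
  structure(list(metric_name = metric$name, period_labels = labels,
                 chi2 = kw$chi2, df = kw$df, p_analytic = kw$p_analytic,
                 largest_sig_lag = scr$lag, block_length = block,
                 p_bootstrap = p_boot, p_used = p_used,
                 n_boot = if (is.na(p_boot)) NA_integer_
                          else as.integer(n_boot),
                 significant = significant, letters = lets),
            class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("<period_comparison> %s: chi2 = %.2f (df %d), p = %.4g%s\n",
              x$metric_name, x$chi2, x$df, x$p_used,
              if (!is.na(x$p_bootstrap))
                sprintf(" [block bootstrap, block %d]", x$block_length)
              else " [analytic]"))
  if (x$significant)
    cat("  letters:", paste(sprintf("%s=%s", x$period_labels, x$letters),
                            collapse = "  "), "\n")
  invisible(x)
}
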