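---
title: "Detecting time-varying fire-climate relationships with fireclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting time-varying fire-climate relationships with fireclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireclim)
```

## The problem

Statistical models that predict annual area burned from climate are usually
calibrated on a few recent decades and then applied to past or future
periods. That practice assumes the fire-climate relationship is stationary.
Over a century-scale record the assumption can fail for two distinct
reasons: the climate itself may shift between regimes while the functional
link stays fixed, or the link itself may change (for example through fire
suppression, land use, or fuel build-up). The two causes leave different
statistical signatures, and `fireclim` implements the machinery to tell
them apart.

The core model is deliberately simple. With $y_t$ the natural logarithm of
annual area burned (ha) and $x_{1,t},\dots,x_{p,t}$ up to three annual
climate metrics,

$$y_t = \beta_0 + \beta_1 x_{1,t} + \dots + \beta_p x_{p,t} +
\varepsilon_t,$$

fitted by ordinary least squares inside every contiguous calibration
window (21 yr by default) of the record. Each windowed model is then used
to predict *all* years outside its window, and skill is summarized by the
coefficient of efficiency

$$CE = 1 - \frac{\sum_t (y_t - \hat y_t)^2}{\sum_t (y_t - \bar y_v)^2},$$

where $\bar y_v$ is the validation-period mean. $CE \in (-\infty, 1]$;
$CE > 0$ means the model beats the climatological mean, and $CE < 0$ is
the signature of a relationship that does not transfer between eras.
Standardized slopes (slopes after z-scoring predictor and response) trace
the *nature* of the relationship through time on a comparable scale.

## From daily metrics to annual predictors

Most fire-danger and water-balance indices are daily quantities, but one
value per year is needed. `seasonal_summary()` collapses a daily record
using a window specification: either a fixed-end mean (`n` days ending on
a given calendar date) or a floating extremum (the maximum or minimum of
the running `n`-day mean over every placement inside the 1 May-1 October
fire season). Fixed-end windows are anchored on their end date and may
reach back before 1 May when daily data exist there; a 90-day window
ending 1 September could not fit inside the season otherwise.
`optimize_window_definition()` searches a candidate grid (by default 9
lengths x {floating max, floating min} plus 9 lengths x 5 fixed end
dates, 63 specifications) and selects the one maximizing the full-record
r² against the response. The selection criterion is the full-record r²
rather than a windowed score: it is deterministic, cheap, and the
downstream sweep re-evaluates the winner window-by-window anyway. Ties
break toward shorter windows and fixed-end before floating (prefer the
simpler definition). A best r² below 0.05 sets a "no informative window"
flag; the flag is diagnostic only and never blocks output, since a weak
metric is still a legitimate input to the comparative ranking.

## The moving-window sweep and predictor ranking

`climate_fire_sweep()` enumerates every contiguous odd-width window (87
windows for a 1902-2008 record at width 21), fits the regression inside
each, and cross-validates on all remaining years on both sides of the
window. Validation uses *all* out-of-window years rather than a
contiguous block: the question is whether a locally calibrated
relationship describes the rest of the century. Width is configurable
(21, 31, 41 yr are the natural sensitivity settings); odd widths are
enforced so centers are integers. The default 21 yr balances decadal
resolution against regression sample size; below ~15 years the windowed
fits become too noisy to interpret.

`rank_predictors()` combines windowed accuracy (r², or adjusted R² for
multiple regressions) and skill (CE) into one score. Two readings exist:
the product of the medians, and the median over windows of the per-window
product r² x CE. Both are always reported; the default ranking key is the
median of products, which rewards predictors that are good *in the same
windows* rather than good on average in different ones. Standardized
slopes default to window-local moments (each window's own mean and sd),
which is the right scale for per-window parameter trajectories; a
global-moment option supports cross-period comparison of parameters on a
single scale.

## The constant-relationship null model

Time-varying windowed statistics change even when nothing about the
fire-climate link changes, simply because the response record's mean,
variance and range drift. The null model makes that baseline explicit:
one OLS fit over the entire record, plus iid Gaussian noise on the ln
scale with the full-record residual sd, with the observed predictor
values held fixed. `build_envelope()` simulates many such records
(10,000 by default), re-runs the sweep on each, and takes the central 95%
of every per-window statistic. Observed trajectories inside the envelope
are uninformative; exits -- in particular CE dropping below the lower
band -- indicate a genuinely altered relationship. Gaussian noise is the
minimal reading of "constant error rate"; a residual-resampling option
(`noise = "resample"`) relaxes normality without changing the logic. The
envelope is an informal test by construction: no p-values are attached,
and interpretation rests on where and how far trajectories exit.

The envelope builder exploits the fixed design: for each window the
hat-matrix factor is computed once and applied to all realizations as a
single matrix product, so a 500-realization envelope over 87 windows
takes under a second and the 10,000-realization default under half a
minute.

## Change points in fire activity

Discrete fire-activity periods are located by piecewise linear regression
on the *cumulative* ln-area series: a mean shift in annual values is a
slope break in the running sum, and each fitted segment's slope estimates
the mean annual ln-area inside it. Two fitting modes are provided:

* `continuity = TRUE` (default): a free-knot segmented regression,
  continuous at the breaks -- the natural choice since a cumulative
  series is continuous by construction. The globally optimal integer knot
  placement is found by exhaustive enumeration; each candidate's normal
  equations are assembled in O(1) from prefix sums, so the k = 3 search
  over a 107-yr record (~120,000 combinations) takes a few seconds.
* `continuity = FALSE`: independent per-segment fits, whose additive SSE
  admits an exact dynamic program (the classical segment-neighborhood
  recursion). This mode is faster and is the one whose optimum is
  verified against brute-force enumeration in the test suite.

A minimum segment length (default 5 yr) prevents edge-hugging breaks. A
break labels the first year of the new regime. The number of breaks is
user-specified, not selected automatically; with more breaks than true
mean shifts, the surplus break contributes little SSE improvement, so the
result reports each break's share of the total improvement to make weak
breaks identifiable. An exactly linear cumulative record is flagged
degenerate rather than treated as an error.

## Comparing climate among periods

`compare_periods()` tests whether a metric differs among the discrete
periods. The omnibus test is Kruskal-Wallis (rank-based, with tie
correction), so all conclusions are invariant to monotone transformations
of the metric. Because annual climate series can be serially correlated,
the analytic chi-square p-value is only used when no autocorrelation is
detected at lags 1-5 (|r_k| > 1.96/sqrt(n) screen). Otherwise the p-value
comes from a circular block bootstrap: the full chronological series is
resampled in blocks equal to the largest significant lag, reassembled to
original length, and split at the *same* period boundaries. This
construction preserves the serial dependence under the null while
destroying any true among-period differences; resampling within groups
would not. The bootstrap p-value uses the (1 + exceedances)/(1 + n_boot)
small-sample form so it can never be exactly zero. Significant omnibus
results get a post-hoc Tukey HSD comparison on the rank-transformed
values (matching the rank-based omnibus) and a compact letter display:
periods sharing a letter are statistically indistinguishable at the
chosen level. Raw-value post-hoc comparison is available via
`tukey_grouping(..., on_ranks = FALSE)`.

## The synthetic-data generator

`generate_scenario()` produces records with known truth for the four
conceptual regimes: constant relationship, climate shift (moments move,
parameters fixed), altered relationship (parameters move, moments fixed),
and combined. Defaults mirror the study conditions the package is built
around: 107 years labeled 1902-2008, period boundaries at 1943 and 1985,
climate iid standard normal, slope 1 ln-ha per climate sd, noise sd 1 on
the ln scale (full-record r² about 0.5), intercept 8 ln-ha (about 3,000
ha in a typical year), a 3% zero-burn rate, and -- in the altered
scenario -- slope doubled and intercept raised by one noise sd in the
final period. Climate is drawn iid rather than AR(1) because observed
predictor and response series of this kind have lag-1 autocorrelation
below 0.25; an AR option exists where serial dependence is the point of
the experiment. Zero-burn years are injected *after* the log-linear
generation by zeroing the smallest burn years, which keeps the generating
parameters interpretable for the remaining years; the log transform then
applies its 10-ha offset to exactly those zeros, as it would on real
data.

What the generator does not emulate: heavy-tailed burn distributions
beyond log-normal, autocorrelated noise in the response, measurement
error in mapped fire perimeters, and any spatial structure. Tests passing
on these synthetics therefore demonstrate that the machinery recovers
known statistical structure, not that any particular real-world record
satisfies the model.

`generate_daily_metric()` supplies daily fixtures (seasonal sinusoid plus
AR(1) anomalies, persistence 0.7, record from 1 January so fixed-end
windows can reach before the season), and `generate_null_dataset()`
builds constant-relationship records whose noise sd is set analytically
from a target r²: `noise_sd = |beta1| sqrt((1 - r2)/r2)` at unit climate
variance.

## Numerical choices and degenerate inputs

* Zero areas get a configurable offset (default 10 ha) before the log;
  the offset applies only to exact zeros, and results are insensitive to
  10 vs 1 ha because such years are rare by construction (< 3%).
* OLS fits require at least p + 4 observations and a full-rank design;
  rank deficiency is reported with the names of the collinear pair.
  Perfectly collinear predictors report VIF = Inf rather than erroring.
* The Lilliefors normality check computes its p-value from a seeded
  Monte-Carlo null distribution (5,000 samples by default) instead of the
  classical interpolation tables, so results reproduce exactly across
  platforms; the null distribution can be precomputed once per sample
  size and reused.
* CE requires non-constant observations (the null MSE would otherwise be
  zero) and at least two validation values; a window spanning the whole
  record has no validation years and errors explicitly.
* No analysis step gates on a p-value; significance flags annotate
  output but never filter it.
* All CSV artifacts are written at six significant digits, making
  repeated runs with the same seed byte-identical.
* The pipeline fans a single master seed out to fixed per-stage
  substreams, so any stage can be re-run alone with unchanged results.

## Problem sizes used in the tests

The shipped test suite runs the method at the scale of its design record:
107-yr series, 87 windows of 21 yr. Monte-Carlo components use reduced
but stated sizes -- 500-realization envelopes (quantile error at the
2.5th/97.5th percentile is then well under the +-5-point tolerance the
self-consistency check allows), 100-replicate scenario and changepoint
recovery experiments, 500-repeat bootstrap calibration at 399 resamples,
and 1,000-repeat Lilliefors level checks against a shared 5,000-sample
null. The full 10,000-realization envelope remains the default for real
analyses.

## Limitations

* The regression is linear on the ln scale with at most three predictors;
  interactions and non-linear responses are out of scope.
* Cross-validation treats out-of-window years as exchangeable; it does
  not produce contiguous-block skill estimates.
* Breakpoint count k is user-specified; the method reports improvement
  shares but will not choose k for you.
* The null envelope conditions on the observed predictor values; it asks
  whether the *response* is consistent with a constant link, not whether
  the climate record itself is stationary.
* Standard errors are not autocorrelation-corrected; the surrounding
  workflow (rank tests with block bootstrap, envelope comparisons) is
  where serial dependence is handled.
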