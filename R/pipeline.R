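#' Read an annual series from CSV
#'
#' Expects a UTF-8 CSV with header `year,value`. Gap years and non-numeric
#' cells are rejected with informative errors.
#'
#' @param path File path.
#' @param name Series name (default: file name without extension).
#' @return An [annual_series()].
#' @export
read_annual_csv <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!identical(names(df)[1:2], c("year", "value")))
    stop(sprintf("expected header 'year,value' in %s", path))
  yr <- suppressWarnings(as.numeric(df$year))
  va <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(yr) | is.na(va))
  if (length(bad))
    stop(sprintf("non-numeric cell(s) in %s at data line(s): %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  if (length(yr) > 1L && any(diff(yr) != 1)) {
    miss <- setdiff(seq(min(yr), max(yr)), yr)
    stop(sprintf("gap years in %s: %s", path,
                 paste(utils::head(miss, 10L), collapse = ", ")))
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  annual_series(yr, va, name = name)
}

#' Read a daily series from CSV
#'
#' Expects a UTF-8 CSV with header `date,value` and ISO-8601 dates.
#'
#' @param path File path.
#' @param name Series name (default: file name without extension).
#' @return A [daily_series()].
#' @export
read_daily_csv <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!identical(names(df)[1:2], c("date", "value")))
    stop(sprintf("expected header 'date,value' in %s", path))
  dt <- as.Date(df$date, format = "%Y-%m-%d")
  va <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(dt) | is.na(va))
  if (length(bad))
    stop(sprintf("unparseable cell(s) in %s at data line(s): %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  daily_series(dt, va, name = name)
}

#' Write a table as RFC-4180 CSV with fixed numeric formatting
#'
#' Numeric columns are written at 6 significant digits so repeated runs with
#' the same seed produce byte-identical artifacts.
#'
#' @param path Output path.
#' @param rows A data frame.
#' @export
write_table <- function(path, rows) {
  rows <- as.data.frame(rows)
  for (j in seq_along(rows))
    if (is.numeric(rows[[j]]) && !is.integer(rows[[j]]))
      rows[[j]] <- formatC(signif(rows[[j]], 6L), format = "g", digits = 6L)
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble an analysis configuration
#'
#' Programmatic equivalent of [read_config()]. Predictor entries are named
#' lists with `file` (annual CSV) or `daily_file` (daily CSV, summarized via
#' the candidate-window search or an explicit window spec).
#'
#' @param response_file Annual CSV of area burned in hectares.
#' @param predictors Named list of predictor entries (see details).
#' @param width Odd calibration window width (default 21).
#' @param score_mode Ranking mode, see [rank_predictors()].
#' @param n_realizations Null-envelope realization count.
#' @param changepoint_k Breakpoints for the piecewise fit (default 3).
#' @param alpha Significance level for period comparisons.
#' @param n_boot Bootstrap resamples for period comparisons.
#' @param zero_offset_ha Offset for zero-burn years (default 10).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for artifacts.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(response_file, predictors, width = 21L,
                            score_mode = "median_of_products",
                            n_realizations = 10000L, changepoint_k = 3L,
                            alpha = 0.05, n_boot = 5000L,
                            zero_offset_ha = 10, seed = 1L,
                            out_dir = "fireclim_out") {
  width <- as.integer(width)
  if (width %% 2L == 0L) stop("window width must be odd")
  if (!file.exists(response_file))
    stop(sprintf("response file not found: %s", response_file))
  if (!is.list(predictors) || is.null(names(predictors)) ||
      any(names(predictors) == ""))
    stop("`predictors` must be a named list")
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    f <- p$file %||% p$daily_file
    if (is.null(f)) stop(sprintf("predictor '%s' needs `file` or `daily_file`",
                                 nm))
    if (!file.exists(f)) stop(sprintf("predictor file not found: %s", f))
  }
  structure(list(response_file = response_file, predictors = predictors,
                 width = width, score_mode = score_mode,
                 n_realizations = as.integer(n_realizations),
                 changepoint_k = as.integer(changepoint_k), alpha = alpha,
                 n_boot = as.integer(n_boot),
                 zero_offset_ha = zero_offset_ha, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with keys matching [analysis_config()] arguments
#'   (`response_file`, `predictors`, `width`, `score_mode`,
#'   `null_model: {n_realizations, seed}`, `changepoint_k`, `alpha`,
#'   `n_boot`, `zero_offset_ha`, `seed`, `out_dir`). Relative file paths are
#'   resolved against the YAML file's directory.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  fix <- function(f) if (!is.null(f) && !file.exists(f))
    file.path(base, f) else f
  y$response_file <- fix(y$response_file)
  for (nm in names(y$predictors)) {
    y$predictors[[nm]]$file <- fix(y$predictors[[nm]]$file)
    y$predictors[[nm]]$daily_file <- fix(y$predictors[[nm]]$daily_file)
  }
  analysis_config(response_file = y$response_file,
                  predictors = y$predictors,
                  width = y$width %||% 21L,
                  score_mode = y$score_mode %||% "median_of_products",
                  n_realizations = y$null_model$n_realizations %||% 10000L,
                  changepoint_k = y$changepoint_k %||% 3L,
                  alpha = y$alpha %||% 0.05,
                  n_boot = y$n_boot %||% 5000L,
                  zero_offset_ha = y$zero_offset_ha %||% 10,
                  seed = y$seed %||% 1L,
                  out_dir = y$out_dir %||% file.path(base, "fireclim_out"))
}

# Deterministic per-stage seeds fanned out from the master seed, kept well
# inside 32-bit integer range.
stage_seed <- function(master, stage) {
  offsets <- c(envelope = 101L, period_comparison = 202L,
               lilliefors = 303L, simulate = 404L)
  (as.integer(master) %% 1000000L) * 1000L + offsets[[stage]]
}

#' Run the full fire-climate analysis pipeline
#'
#' Executes, in order: response loading and log transform, predictor
#' loading (daily metrics are collapsed through the optimal-window search),
#' full-record fits, the moving-window sweep per predictor, predictor
#' ranking, the Monte-Carlo null envelope for the top-ranked predictor,
#' changepoint detection on the cumulative log series, and among-period
#' comparison of every predictor metric. Per-stage CSV/JSON artifacts, a
#' run log and a summary JSON are written to the configured output
#' directory.
#'
#' @param config An [analysis_config()] (or path handled by
#'   [read_config()]).
#' @return The summary list, invisibly.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat(sprintf("fireclim %s | R %s | master seed %d\n",
              as.character(utils::packageVersion("fireclim")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed),
      file = log_path)
  logline <- function(fmt, ...)
    cat(sprintf(paste0("[%s] ", fmt, "\n"), format(Sys.time(), "%H:%M:%S"),
                ...), file = log_path, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logline("stage %-18s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  response <- stage("load_response", {
    area <- read_annual_csv(config$response_file, name = "area_burned")
    log_transform_area(area, config$zero_offset_ha)
  })

  predictors <- stage("load_predictors", {
    out <- list()
    for (nm in names(config$predictors)) {
      p <- config$predictors[[nm]]
      if (!is.null(p$file)) {
        out[[nm]] <- read_annual_csv(p$file, name = nm)
      } else {
        daily <- read_daily_csv(p$daily_file, name = nm)
        if (!is.null(p$window)) {
          spec <- window_spec(mode = p$window$mode,
                              length_days = p$window$length_days,
                              end_date = p$window$end_date,
                              season_extremum =
                                p$window$season_extremum %||% "none")
          out[[nm]] <- suppressWarnings(seasonal_summary(daily, spec))
          out[[nm]]$name <- nm
        } else {
          srch <- optimize_window_definition(daily, response)
          write_table(file.path(config$out_dir,
                                sprintf("window_search_%s.csv", nm)),
                      srch$scores)
          out[[nm]] <- suppressWarnings(
            seasonal_summary(daily, srch$definition$window))
          out[[nm]]$name <- nm
        }
      }
    }
    out
  })

  global_fits <- stage("global_fits", {
    fits <- lapply(predictors, function(p) fit_ols(p, response))
    stats::setNames(vapply(fits, function(f)
      if (!is.na(f$r2_adj)) f$r2_adj else f$r2, 0), names(predictors))
  })

  sweeps <- stage("sweep", {
    out <- lapply(predictors, function(p)
      climate_fire_sweep(p, response, width = config$width))
    for (nm in names(out))
      write_table(file.path(config$out_dir, sprintf("sweep_%s.csv", nm)),
                  as.data.frame(out[[nm]]))
    out
  })

  ranking <- stage("rank", {
    r <- rank_predictors(sweeps, global_r2 = global_fits,
                         mode = config$score_mode)
    write_table(file.path(config$out_dir, "predictor_ranking.csv"), r)
    r
  })
  top <- ranking$predictor_set[1L]

  envelope <- stage("envelope", {
    env <- build_envelope(predictors[[top]], response, width = config$width,
                          n_realizations = config$n_realizations,
                          seed = stage_seed(config$seed, "envelope"))
    long <- do.call(rbind, lapply(names(env$bands), function(s)
      cbind(statistic = s, env$bands[[s]])))
    write_table(file.path(config$out_dir, "null_envelope.csv"),
                long[, c("center_year", "statistic", "lower", "upper")])
    env
  })
  coverage <- envelope_coverage(envelope, sweeps[[top]])
  exits <- coverage[!coverage$inside, c("center_year", "statistic", "side")]

  cpt <- stage("changepoints", {
    fit <- piecewise_fit(cumulative_series(response),
                         n_breakpoints = config$changepoint_k)
    jsonlite::write_json(
      list(breakpoint_years = fit$breakpoint_years,
           segment_slopes = fit$segment_slopes, sse = fit$sse,
           sse_null = fit$sse_null,
           improvement_share = fit$improvement_share,
           degenerate = fit$degenerate,
           config = list(n_breakpoints = fit$n_breakpoints,
                         min_segment = fit$min_segment,
                         continuity = fit$continuity)),
      file.path(config$out_dir, "changepoints.json"),
      auto_unbox = TRUE, digits = NA)
    fit
  })

  comparisons <- stage("compare_periods", {
    rows <- lapply(names(predictors), function(nm) {
      pc <- tryCatch(
        compare_periods(predictors[[nm]], cpt$breakpoint_years,
                        alpha = config$alpha, n_boot = config$n_boot,
                        seed = stage_seed(config$seed, "period_comparison")),
        error = function(e) conditionMessage(e))
      if (is.character(pc))
        return(data.frame(metric = nm, chi2 = NA_real_, df = NA_integer_,
                          p_analytic = NA_real_, block_length = NA_integer_,
                          p_bootstrap = NA_real_, p_used = NA_real_,
                          significant = NA, letters = "", note = pc,
                          stringsAsFactors = FALSE))
      data.frame(metric = nm, chi2 = pc$chi2, df = pc$df,
                 p_analytic = pc$p_analytic, block_length = pc$block_length,
                 p_bootstrap = pc$p_bootstrap, p_used = pc$p_used,
                 significant = pc$significant,
                 letters = paste(pc$letters, collapse = "/"), note = "",
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    write_table(file.path(config$out_dir, "period_comparison.csv"), tab)
    tab
  })

  summary <- list(
    top_predictor = top,
    ranking = ranking[, c("predictor_set", "median_r2", "median_ce",
                          "score", "rank")],
    breakpoint_years = cpt$breakpoint_years,
    all_windows_inside_envelope = nrow(exits) == 0L,
    envelope_exits = exits,
    period_comparison = comparisons,
    seeds = list(master = config$seed,
                 envelope = stage_seed(config$seed, "envelope"),
                 period_comparison = stage_seed(config$seed,
                                                "period_comparison")))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 6, dataframe = "rows")
  logline("done: top predictor '%s'; breakpoints %s; %d envelope exit(s)",
          top, paste(cpt$breakpoint_years, collapse = ", "), nrow(exits))
  invisible(summary)
}
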