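#' Serialize package objects to JSON
#'
#' Lossless JSON views of fits, rolling forecasts, window searches,
#' comparisons and generator specs. Reports always embed the
#' evaluation-index-set convention in use (static in-sample t = 2..n;
#' dynamic one-step-ahead t = n+1..n_obs), since that convention is the
#' main source of irreproducible MAPE figures. Numbers are written at
#' full precision; textual summaries round to 2 decimals.
#'
#' @param x A `grey_fit`, `grey_roll`, `grey_window_search`,
#'   `grey_comparison` or `grey_spec`.
#' @return A list ready for [jsonlite::write_json()].
#' @export
grey_report <- function(x) UseMethod("grey_report")

#' @export
grey_report.grey_fit <- function(x) {
  list(
    object = "grey_fit",
    model = x$model,
    params = x$params,
    whitening = if (!is.null(x$whitening))
      list(A = x$whitening$A, B = x$whitening$B, C = x$whitening$C,
           K = x$whitening$K),
    window_periods = x$window$periods,
    observed = x$window$values,
    simulated = x$simulated,
    eval_index = x$eval_index,
    eval_convention = "in-sample, t = 2..n (t = 1 anchored to the observation)",
    in_sample_mape_pct = x$in_sample_mape,
    well_posed = x$well_posed,
    diagnostics = as.list(x$diagnostics)
  )
}

#' @export
grey_report.grey_roll <- function(x) {
  list(
    object = "grey_roll",
    model = x$model,
    window_size = x$n,
    eval_convention = sprintf(
      "one-step-ahead, t = %d..%d (first %d indices in-window, not forecast)",
      min(x$forecast_index), max(x$forecast_index), x$n),
    steps = lapply(x$steps, function(s) {
      list(t = s$t, period = s$period, window_periods = s$window_periods,
           params = s$params, forecast = s$forecast, actual = s$actual,
           rel_error_pct = 100 * s$rel_error, defined = s$defined)
    }),
    n_undefined_steps = x$n_undefined,
    overall_mape_pct = x$overall_mape
  )
}

#' @export
grey_report.grey_window_search <- function(x) {
  list(
    object = "grey_window_search",
    model = x$model,
    candidate_sizes = x$candidate_sizes,
    mape_by_size_pct = as.list(x$mape_by_size),
    best_size = x$best_size,
    ties_broken = x$ties_broken
  )
}

#' @export
grey_report.grey_comparison <- function(x) {
  list(
    object = "grey_comparison",
    eval_convention = "static: in-sample t = 2..n_obs; dynamic: one-step-ahead t = n+1..n_obs",
    entries = lapply(x$entries, function(e) {
      e[c("label", "model", "type", "n", "eval_index", "actual",
          "predicted", "rel_errors", "mape", "failed", "note")]
    }),
    ranking = x$ranking
  )
}

#' @export
grey_report.grey_spec <- function(x) {
  list(object = "grey_spec", process = x$process, length = x$length,
       seed = x$seed, noise_sd = x$noise_sd, params = x$params)
}

#' Write a JSON report
#'
#' @param x Any object with a [grey_report()] method.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grey_json <- function(x, path) {
  jsonlite::write_json(grey_report(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
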