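#' Mean absolute percentage error
#'
#' The core accuracy index for grey-model comparison:
#' \eqn{100 \times \mathrm{mean}(|predicted - actual| / actual)}.
#' Scale-invariant, and undefined when any actual value is zero —
#' hence the strict positivity requirement on observed series.
#'
#' @param actual Numeric vector of strictly positive actual values.
#' @param predicted Numeric vector of the same length.
#' @return MAPE in percent.
#' @examples
#' mape(c(2, 1), c(1.9, 1.1))  # 7.5
#' @export
mape <- function(actual, predicted) {
  mean(relative_error_series(actual, predicted))
}

#' Per-index relative errors in percent
#'
#' @inheritParams mape
#' @return Numeric vector `100 * |predicted - actual| / actual`;
#'   [mape()] is its mean.
#' @export
relative_error_series <- function(actual, predicted) {
  actual <- as.numeric(actual)
  predicted <- as.numeric(predicted)
  if (length(actual) == 0L) stop("empty input", call. = FALSE)
  if (length(actual) != length(predicted)) {
    stop(sprintf("length mismatch: %d actual vs %d predicted",
                 length(actual), length(predicted)), call. = FALSE)
  }
  if (any(!is.finite(actual)) || any(actual <= 0)) {
    stop("actual values must be finite and strictly positive", call. = FALSE)
  }
  100 * abs(predicted - actual) / actual
}

#' Compare static and rolling grey models on one series
#'
#' Fits each requested static model over the full series, runs each
#' requested dynamic (metabolic rolling) specification, and ranks all
#' entries by MAPE. Conventions, stated with every entry because they
#' drive comparability: static models are scored in-sample on
#' \eqn{t = 2..n_{obs}} (index 1 is anchored exactly by construction
#' and would deflate the average); dynamic models are scored on their
#' one-step-ahead forecasts \eqn{t = n+1..n_{obs}}.
#'
#' @param series A [grey_series].
#' @param static Character vector of static model names (see
#'   [fit_grey()]); may be empty.
#' @param dynamic List of dynamic specifications, each a list with
#'   `model` and optionally `n`; when `n` is absent it is chosen by
#'   [optimize_window()] over `candidates`.
#' @param candidates Window-size candidates for automatic selection.
#' @return An object of class `grey_comparison`: per-model entries
#'   (label, type, evaluation index set, actual, predicted, relative
#'   errors in percent, MAPE) and a `ranking` data frame sorted by
#'   MAPE. Infeasible requests become failed entries, not errors.
#' @export
compare_models <- function(series,
                           static = c("gm", "dgm", "dngm", "idgm", "ddgm"),
                           dynamic = list(),
                           candidates = 4:10) {
  series <- as_grey_series(series)
  if (length(static) == 0L && length(dynamic) == 0L) {
    stop("nothing to compare: no static or dynamic model requested",
         call. = FALSE)
  }
  entries <- list()
  n_obs <- length(series)
  for (m in static) {
    label <- toupper(m)
    e <- tryCatch({
      fit <- fit_grey(series, m)
      idx <- fit$eval_index
      pred <- fit$simulated[idx]
      act <- series$values[idx]
      rel <- relative_error_series(act, pred)
      list(label = label, model = m, type = "static", n = n_obs,
           eval_index = idx, actual = act, predicted = pred,
           rel_errors = rel, mape = mean(rel), failed = FALSE, note = NA_character_)
    }, error = function(err) {
      list(label = label, model = m, type = "static", n = n_obs,
           eval_index = integer(), actual = numeric(), predicted = numeric(),
           rel_errors = numeric(), mape = NA_real_, failed = TRUE,
           note = conditionMessage(err))
    })
    entries[[length(entries) + 1L]] <- e
  }
  for (spec in dynamic) {
    m <- spec$model
    e <- tryCatch({
      n <- spec$n
      chosen <- NULL
      if (is.null(n)) {
        chosen <- optimize_window(series, m, candidates)
        n <- chosen$best_size
      }
      r <- roll_forecast(series, m, n)
      label <- sprintf("%s(n=%d)",
                       switch(m, gm = "MGM", dngm = "DNMGM",
                              paste0("M-", toupper(m))), n)
      def <- is.finite(r$rel_error)
      list(label = label, model = m, type = "dynamic", n = n,
           eval_index = r$forecast_index[def], actual = r$actual[def],
           predicted = r$forecast[def], rel_errors = 100 * r$rel_error[def],
           mape = r$overall_mape, failed = FALSE,
           note = if (!is.null(chosen)) "window size chosen by MAPE sweep" else NA_character_,
           window_search = chosen)
    }, error = function(err) {
      list(label = sprintf("%s(n=%s)",
                           switch(m, gm = "MGM", dngm = "DNMGM",
                                  paste0("M-", toupper(m))),
                           if (is.null(spec$n)) "auto" else spec$n),
           model = m, type = "dynamic",
           n = if (is.null(spec$n)) NA_integer_ else spec$n,
           eval_index = integer(), actual = numeric(), predicted = numeric(),
           rel_errors = numeric(), mape = NA_real_, failed = TRUE,
           note = conditionMessage(err))
    })
    entries[[length(entries) + 1L]] <- e
  }
  mapes <- vapply(entries, function(e) e$mape, numeric(1))
  ranking <- data.frame(
    label = vapply(entries, function(e) e$label, character(1)),
    type = vapply(entries, function(e) e$type, character(1)),
    window = vapply(entries, function(e) as.integer(e$n), integer(1)),
    mape_pct = mapes,
    stringsAsFactors = FALSE
  )
  ranking <- ranking[order(is.na(ranking$mape_pct), ranking$mape_pct), ]
  rownames(ranking) <- NULL
  structure(list(series_periods = series$periods, entries = entries,
                 ranking = ranking),
            class = "grey_comparison")
}

#' @export
print.grey_comparison <- function(x, ...) {
  cat(sprintf("<grey_comparison> %d model(s) on periods %d..%d\n",
              length(x$entries), min(x$series_periods), max(x$series_periods)))
  df <- x$ranking
  df$mape_pct <- sprintf("%.2f", df$mape_pct)
  print(df, row.names = FALSE)
  cat("  (static MAPE: in-sample t = 2..n_obs; dynamic MAPE: one-step-ahead t = n+1..n_obs)\n")
  invisible(x)
}

#' @export
as.data.frame.grey_comparison <- function(x, ...) {
  do.call(rbind, lapply(x$entries, function(e) {
    if (e$failed || length(e$eval_index) == 0L) return(NULL)
    data.frame(label = e$label, type = e$type, t = e$eval_index,
               actual = e$actual, predicted = e$predicted,
               rel_error_pct = e$rel_errors, stringsAsFactors = FALSE)
  }))
}
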