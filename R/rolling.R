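#' Metabolic rolling one-step-ahead forecasting
#'
#' Turns any static grey model into a dynamic one by "metabolism":
#' before each forecast the newest observation is appended, the oldest
#' dropped, and the model refitted on the resulting fixed-size window
#' of the `n` most recent actual observations. Applied to GM(1,1) this
#' yields the metabolic MGM(1,1); applied to DNGM(1,1) it yields
#' DNMGM(1,1). Each index \eqn{t = n+1, \dots, n_{obs}} is forecast one
#' step ahead from the window \eqn{t-n, \dots, t-1}; windows contain
#' actual observations only, never earlier forecasts.
#'
#' @param series A [grey_series] of length at least `n + 1`.
#' @param model Static model selector, see [fit_grey()].
#' @param n Window size (number of most recent observations per refit),
#'   at least the model's minimum window.
#' @return An object of class `grey_roll`: model, window size, per-step
#'   records (window periods, fitted parameters, forecast, actual,
#'   relative error), the forecast index set, and `overall_mape`
#'   (percent, over the defined forecast steps \eqn{t = n+1..n_{obs}};
#'   the first `n` indices are in-window and not forecast).
#' @examples
#' s <- generate_series(grey_spec("exact_geometric", length = 8,
#'                                first = 256, ratio = 0.5))
#' roll_forecast(s, "dgm", n = 4)$overall_mape   # ~0: exact process
#' @export
roll_forecast <- function(series, model = c("dngm", "gm", "dgm", "idgm", "ddgm"),
                          n) {
  series <- as_grey_series(series)
  model <- match.arg(model)
  n <- as.integer(n)
  mn <- model_min_window(model)
  if (n < mn) {
    stop(sprintf("window size %d below the %s minimum of %d", n,
                 toupper(model), mn), call. = FALSE)
  }
  n_obs <- length(series)
  if (n_obs < n + 1L) {
    stop(sprintf(
      "series too short to roll: need at least n + 1 = %d observations for window size %d (got %d)",
      n + 1L, n, n_obs), call. = FALSE)
  }
  idx <- seq.int(n + 1L, n_obs)
  steps <- vector("list", length(idx))
  forecast <- actual <- rel_error <- rep(NA_real_, length(idx))
  for (j in seq_along(idx)) {
    t <- idx[j]
    win <- grey_series(series$values[(t - n):(t - 1L)],
                       series$periods[(t - n):(t - 1L)])
    step <- list(t = t, period = series$periods[t],
                 window_periods = win$periods,
                 params = NULL, forecast = NA_real_,
                 actual = series$values[t], rel_error = NA_real_,
                 defined = FALSE, note = NA_character_)
    fc <- tryCatch({
      fit <- fit_grey(win, model)
      step$params <- fit$params
      step$fit <- fit
      utils::tail(simulate_static(fit, horizon = 1L)$values, 1L)
    }, error = function(e) {
      warning(sprintf("step t=%d (period %d): fit failed and is excluded from MAPE: %s",
                      t, series$periods[t], conditionMessage(e)), call. = FALSE)
      step$note <<- conditionMessage(e)
      NA_real_
    })
    if (is.finite(fc)) {
      step$forecast <- fc
      step$rel_error <- abs(fc - step$actual) / step$actual
      step$defined <- TRUE
    }
    forecast[j] <- step$forecast
    actual[j] <- step$actual
    rel_error[j] <- step$rel_error
    steps[[j]] <- step
  }
  defined <- is.finite(rel_error)
  structure(list(
    model = model, n = n,
    series_periods = series$periods,
    forecast_index = idx,
    steps = steps,
    forecast = forecast, actual = actual, rel_error = rel_error,
    n_undefined = sum(!defined),
    overall_mape = 100 * mean(rel_error[defined])
  ), class = "grey_roll")
}

#' @export
print.grey_roll <- function(x, ...) {
  lbl <- switch(x$model, gm = "MGM", dngm = "DNMGM",
                paste0("rolling ", toupper(x$model)))
  cat(sprintf("<grey_roll> %s(1,1), window size n = %d, %d forecast steps (t = %d..%d)\n",
              lbl, x$n, length(x$forecast_index), min(x$forecast_index),
              max(x$forecast_index)))
  if (x$n_undefined > 0)
    cat(sprintf("  %d step(s) undefined (ill-posed window), excluded from MAPE\n",
                x$n_undefined))
  cat(sprintf("  one-step-ahead MAPE over forecast steps: %.2f%%\n",
              x$overall_mape))
  invisible(x)
}

#' @export
as.data.frame.grey_roll <- function(x, ...) {
  data.frame(
    t = x$forecast_index,
    period = vapply(x$steps, function(s) as.integer(s$period), integer(1)),
    window_start = vapply(x$steps, function(s) min(s$window_periods), integer(1)),
    window_end = vapply(x$steps, function(s) max(s$window_periods), integer(1)),
    actual = x$actual,
    forecast = x$forecast,
    rel_error_pct = 100 * x$rel_error
  )
}

#' Select the rolling-window size by MAPE
#'
#' Runs [roll_forecast()] for every candidate window size and returns
#' the one-step-ahead MAPE per candidate together with the argmin.
#' Candidates infeasible for the series (too large to leave a forecast
#' step, or below the model minimum) are skipped with a warning and
#' recorded as `NA`. Ties go to the smallest size.
#'
#' @param series A [grey_series].
#' @param model Static model selector, see [fit_grey()].
#' @param candidates Integer vector of window sizes; the default 4..10
#'   is the conventional sweep for short annual series.
#' @return An object of class `grey_window_search`: `candidate_sizes`,
#'   `mape_by_size` (percent, `NA` where skipped), `best_size`,
#'   `ties_broken`, plus the underlying `grey_roll` objects.
#' @export
optimize_window <- function(series, model = c("dngm", "gm", "dgm", "idgm", "ddgm"),
                            candidates = 4:10) {
  series <- as_grey_series(series)
  model <- match.arg(model)
  candidates <- as.integer(candidates)
  if (length(candidates) == 0L) {
    stop("candidate list must not be empty", call. = FALSE)
  }
  n_obs <- length(series)
  mn <- model_min_window(model)
  mape <- stats::setNames(rep(NA_real_, length(candidates)),
                          as.character(candidates))
  rolls <- stats::setNames(vector("list", length(candidates)),
                           as.character(candidates))
  for (j in seq_along(candidates)) {
    n <- candidates[j]
    if (n < mn || n_obs < n + 1L) {
      warning(sprintf(
        "window size %d infeasible for a %d-point series with %s (needs %d..%d); skipped",
        n, n_obs, toupper(model), mn, n_obs - 1L), call. = FALSE)
      next
    }
    r <- roll_forecast(series, model, n)
    rolls[[j]] <- r
    mape[j] <- r$overall_mape
  }
  if (all(is.na(mape))) {
    stop("no feasible candidate window size", call. = FALSE)
  }
  best_m <- min(mape, na.rm = TRUE)
  # tie tolerance: MAPEs within 1e-9 percentage points are
  # indistinguishable in practice (e.g. exact processes, where every
  # candidate is correct to rounding); ties go to the smallest size
  at_min <- candidates[!is.na(mape) & mape <= best_m + 1e-9]
  structure(list(
    model = model,
    candidate_sizes = candidates,
    mape_by_size = mape,
    best_size = min(at_min),
    ties_broken = length(at_min) > 1L,
    rolls = rolls
  ), class = "grey_window_search")
}

#' @export
print.grey_window_search <- function(x, ...) {
  cat(sprintf("<grey_window_search> %s, candidates %s\n", toupper(x$model),
              paste(x$candidate_sizes, collapse = ", ")))
  print(round(x$mape_by_size, 4))
  cat(sprintf("  best window size: n = %d%s\n", x$best_size,
              if (x$ties_broken) " (tie broken toward the smallest size)" else ""))
  invisible(x)
}

#' @export
as.data.frame.grey_window_search <- function(x, ...) {
  data.frame(window_size = x$candidate_sizes,
             mape_pct = as.numeric(x$mape_by_size),
             best = x$candidate_sizes == x$best_size)
}

#' Extrapolate beyond the series by rolling on forecasts
#'
#' The first forecast uses the last `n` actual observations; each
#' subsequent step appends its own forecast to the window (beyond the
#' sample, metabolism necessarily feeds on predictions). This is the
#' out-of-sample counterpart of [roll_forecast()], which during
#' retrospective evaluation only ever uses actual observations.
#'
#' @inheritParams roll_forecast
#' @param horizon Number of steps beyond the last observation,
#'   \eqn{\ge 1}.
#' @return A [grey_series] of `horizon` forecast values with periods
#'   continued at the observed spacing.
#' @export
roll_extrapolate <- function(series, model = c("dngm", "gm", "dgm", "idgm", "ddgm"),
                             n, horizon) {
  series <- as_grey_series(series)
  model <- match.arg(model)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  n <- as.integer(n)
  mn <- model_min_window(model)
  if (n < mn || length(series) < n) {
    stop(sprintf("need at least n = %d (>= model minimum %d) observations",
                 n, mn), call. = FALSE)
  }
  vals <- series$values
  per <- series$periods
  step <- if (length(per) > 1L) per[2L] - per[1L] else 1L
  out_v <- numeric(horizon)
  out_p <- integer(horizon)
  for (h in seq_len(horizon)) {
    m <- length(vals)
    win <- structure(list(periods = per[(m - n + 1L):m],
                          values = vals[(m - n + 1L):m]),
                     class = "grey_series")
    fit <- fit_grey(win, model)
    fc <- utils::tail(simulate_static(fit, horizon = 1L)$values, 1L)
    out_v[h] <- fc
    out_p[h] <- per[length(per)] + step
    vals <- c(vals, fc)
    per <- c(per, out_p[h])
  }
  structure(list(periods = out_p, values = out_v), class = "grey_series")
}
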