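#' Map whitening-equation parameters to recursion parameters
#'
#' The nonhomogeneous grey model is defined in continuous time by the
#' whitening equation \eqn{dx^{(1)}/dt + A x^{(1)} = Bt + C}. Its exact
#' discrete counterpart on the accumulated scale is the recursion
#' \eqn{x^{(1)}(t+1) = \alpha x^{(1)}(t) + \beta t + \gamma} with
#' \deqn{\alpha = e^{-A},\quad \beta = \frac{B}{A}(1 - e^{-A}),\quad
#'   \gamma = (1 - e^{-A})\left(\frac{C}{A} - \frac{B}{A^2}\right) + \frac{B}{A}.}
#'
#' @param A Continuous decay/growth rate per index step (nonzero).
#' @param B Slope of the nonhomogeneous (linear-in-time) drive.
#' @param C Constant drive.
#' @return List with elements `alpha`, `beta`, `gamma`.
#' @seealso [recursion_to_whitening()] for the inverse mapping.
#' @export
whitening_to_recursion <- function(A, B, C) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C))
  if (A == 0) stop("A must be nonzero (the mapping divides by A)", call. = FALSE)
  al <- exp(-A)
  list(alpha = al,
       beta  = (B / A) * (1 - al),
       gamma = (1 - al) * (C / A - B / A^2) + B / A)
}

#' Map recursion parameters to whitening-equation parameters
#'
#' Inverse of [whitening_to_recursion()]: \eqn{A = -\ln\alpha},
#' \eqn{B = A\beta/(1-\alpha)},
#' \eqn{C = A\,[(\gamma - B/A)/(1-\alpha) + B/A^2]}.
#' Defined only for \eqn{\alpha > 0}, \eqn{\alpha \ne 1}.
#'
#' @param alpha,beta,gamma Recursion parameters of
#'   \eqn{x^{(1)}(t+1) = \alpha x^{(1)}(t) + \beta t + \gamma}.
#' @param x1_initial Optional initial accumulated value
#'   \eqn{x^{(1)}(1)}; when supplied, the response coefficient
#'   \eqn{K = x^{(1)}(1) - B/A + B/A^2 - C/A} is computed and stored.
#' @return An object of class `grey_whitening`: list with `A`, `B`,
#'   `C`, `K` (NA unless `x1_initial` given) and `x1_initial`.
#' @export
recursion_to_whitening <- function(alpha, beta, gamma, x1_initial = NULL) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  if (alpha <= 0 || abs(alpha - 1) < 1e-12) {
    stop(paste(
      "whitening parameters are defined only for alpha > 0 and alpha != 1;",
      "use the fitted recursion directly for prediction"
    ), call. = FALSE)
  }
  A <- -log(alpha)
  B <- A * beta / (1 - alpha)
  C <- A * ((gamma - B / A) / (1 - alpha) + B / A^2)
  K <- if (is.null(x1_initial)) NA_real_ else
    x1_initial - B / A + B / A^2 - C / A
  structure(list(A = A, B = B, C = C, K = K,
                 x1_initial = if (is.null(x1_initial)) NA_real_ else x1_initial),
            class = "grey_whitening")
}

#' DNGM(1,1) time-response function
#'
#' Closed-form solution of the whitening equation on the accumulated
#' scale, anchored at the initial condition \eqn{x^{(1)}(1)}:
#' \deqn{x^{(1)}(t) = K e^{-A(t-1)} + \frac{B}{A}t - \frac{B}{A^2} + \frac{C}{A},
#'   \qquad K = x^{(1)}(1) - \frac{B}{A} + \frac{B}{A^2} - \frac{C}{A}.}
#'
#' @param params A `grey_whitening` object or list with `A`, `B`, `C`.
#' @param x1_initial Initial accumulated value \eqn{x^{(1)}(1) > 0}.
#' @param t Index (vector allowed), each \eqn{\ge 1}.
#' @return Accumulated-scale value(s) \eqn{x^{(1)}(t)}.
#' @export
dngm_time_response <- function(params, x1_initial, t) {
  check_whitening(params)
  if (any(t < 1)) stop("t must be >= 1", call. = FALSE)
  A <- params$A; B <- params$B; C <- params$C
  K <- x1_initial - B / A + B / A^2 - C / A
  K * exp(-A * (t - 1)) + (B / A) * t - B / A^2 + C / A
}

#' DNGM(1,1) reduction (restoration) formula
#'
#' Original-scale fitted value obtained by differencing the time
#' response:
#' \deqn{\hat x^{(0)}(t) = (1 - e^{A})\,K\,e^{-A(t-1)} + \frac{B}{A}, \quad t \ge 2.}
#' Index 1 is anchored to the observation and is not restored.
#'
#' @inheritParams dngm_time_response
#' @param t Index (vector allowed), each \eqn{\ge 2}.
#' @return Original-scale restored value(s) \eqn{\hat x^{(0)}(t)}.
#' @export
dngm_restore <- function(params, x1_initial, t) {
  check_whitening(params)
  if (any(t < 2)) {
    stop("t must be >= 2: index 1 is anchored to the observation, not restored",
         call. = FALSE)
  }
  A <- params$A; B <- params$B; C <- params$C
  K <- x1_initial - B / A + B / A^2 - C / A
  (1 - exp(A)) * K * exp(-A * (t - 1)) + B / A
}

check_whitening <- function(params) {
  if (is.null(params) || !all(c("A", "B", "C") %in% names(params)) ||
      !all(is.finite(c(params$A, params$B, params$C))) || params$A == 0) {
    stop(paste(
      "whitening parameters unavailable (alpha <= 0 or alpha == 1 at fit time);",
      "use recursion-based prediction via simulate_static()"
    ), call. = FALSE)
  }
  invisible(params)
}

# --- least-squares backbone -------------------------------------------------

# QR least squares with a reciprocal-condition diagnostic. Cramer's rule
# gives the same answer on well-posed systems and is used only as an
# independent oracle in the tests.
grey_lsq <- function(X, y) {
  qr_ <- qr(X)
  rc <- if (qr_$rank < ncol(X)) 0 else tryCatch(1 / kappa(qr_, exact = TRUE),
                                                error = function(e) 0)
  coef <- qr.coef(qr_, y)
  coef[is.na(coef)] <- 0     # rank-deficient: any LS solution; flagged below
  list(coef = as.numeric(coef),
       residuals = as.numeric(y - X %*% coef),
       rcond = rc,
       well_posed = rc >= 1e-12)
}

model_min_window <- function(model) {
  switch(model, ddgm = 3L, gm = , dgm = , dngm = , idgm = 4L,
         stop(sprintf("unknown model '%s'", model), call. = FALSE))
}

check_window <- function(window, model) {
  window <- as_grey_series(window)
  mn <- model_min_window(model)
  if (length(window) < mn) {
    stop(sprintf("%s requires a window of at least %d observations (got %d)",
                 toupper(model), mn, length(window)), call. = FALSE)
  }
  window
}

new_grey_fit <- function(model, window, params, ls, simulated,
                         diagnostics = character(), extra = list()) {
  obs <- window$values
  n <- length(obs)
  rel <- abs(simulated[-1L] - obs[-1L]) / obs[-1L]
  structure(c(list(
    model = model,
    window = window,
    params = params,
    simulated = simulated,
    recursion_residuals = ls$residuals,
    rcond = ls$rcond,
    well_posed = ls$well_posed,
    eval_index = seq.int(2L, n),
    in_sample_mape = 100 * mean(rel),
    diagnostics = c(diagnostics,
                    if (!ls$well_posed)
                      "near-singular design matrix: parameters are one least-squares solution among many")
  ), extra), class = "grey_fit")
}

#' @export
print.grey_fit <- function(x, ...) {
  cat(sprintf("<grey_fit> %s on periods %d..%d (n = %d)\n",
              toupper(x$model), min(x$window$periods), max(x$window$periods),
              length(x$window)))
  cat("  parameters:",
      paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  cat(sprintf("  in-sample MAPE (t = 2..%d): %.2f%%\n",
              length(x$window), x$in_sample_mape))
  if (!x$well_posed) cat("  WARNING:", x$diagnostics, "\n")
  invisible(x)
}

# --- model fits -------------------------------------------------------------

#' Fit the discrete nonhomogeneous grey model DNGM(1,1)
#'
#' Estimates \eqn{(\alpha, \beta, \gamma)} of the accumulated-scale
#' recursion \eqn{x^{(1)}(t+1) = \alpha x^{(1)}(t) + \beta t + \gamma}
#' by least squares over the \eqn{n-1} stacked equations
#' (\eqn{t = 1, \dots, n-1}; the drift regressor is the source index
#' \eqn{t}). When \eqn{\alpha > 0} and \eqn{\alpha \ne 1} the
#' continuous whitening parameters \eqn{(A, B, C)} are also stored via
#' [recursion_to_whitening()]. Fitted values iterate the recursion from
#' \eqn{x^{(1)}(1) = x^{(0)}(1)} and restore by differencing, so the
#' value at \eqn{t = 1} is anchored to the observation.
#'
#' @param window A [grey_series] of at least 4 observations (a length-4
#'   window interpolates its three recursion equations exactly).
#' @return An object of class `grey_fit`.
#' @examples
#' s <- grey_series(c(1, 2.5, 2.25, 2.125, 2.0625))
#' fit <- fit_dngm(s)              # recovers alpha=0.5, beta=1, gamma=2
#' fit$whitening$A                 # log(2)
#' @export
fit_dngm <- function(window) {
  window <- check_window(window, "dngm")
  x1 <- ago(window)$values
  n <- length(x1)
  k <- seq_len(n - 1L)
  ls <- grey_lsq(cbind(x1[k], k, 1), x1[k + 1L])
  params <- list(alpha = ls$coef[1L], beta = ls$coef[2L], gamma = ls$coef[3L])
  wh <- if (params$alpha > 0 && abs(params$alpha - 1) >= 1e-12) {
    recursion_to_whitening(params$alpha, params$beta, params$gamma,
                           x1_initial = x1[1L])
  } else NULL
  diag <- if (is.null(wh))
    "alpha <= 0 or alpha == 1: whitening parameters undefined, recursion-based prediction in use"
  else character()
  fit <- new_grey_fit("dngm", window, params, ls,
                      simulated = grey_path_dngm(params, x1[1L], n),
                      diagnostics = diag,
                      extra = list(whitening = wh))
  fit
}

grey_path_dngm <- function(params, x1_initial, len) {
  x1hat <- numeric(len)
  x1hat[1L] <- x1_initial
  if (len > 1L) for (t in seq_len(len - 1L)) {
    x1hat[t + 1L] <- params$alpha * x1hat[t] + params$beta * t + params$gamma
  }
  iago(x1hat)
}

#' Fit the classical grey model GM(1,1)
#'
#' Standard construction: background values
#' \eqn{z^{(1)}(k) = \tfrac12 (x^{(1)}(k) + x^{(1)}(k-1))}, least
#' squares on the grey differential equations
#' \eqn{x^{(0)}(k) = -a z^{(1)}(k) + b} for \eqn{k = 2, \dots, n}, time
#' response \eqn{\hat x^{(1)}(k) = (x^{(0)}(1) - b/a) e^{-a(k-1)} + b/a},
#' restoration by differencing. A development coefficient
#' \eqn{|a| < 10^{-12}} (e.g. a constant window) degenerates to the
#' linear time response \eqn{\hat x^{(1)}(k) = x^{(0)}(1) + b(k-1)},
#' i.e. a flat forecast.
#'
#' @param window A [grey_series] of at least 4 observations.
#' @return A `grey_fit`.
#' @export
fit_gm <- function(window) {
  window <- check_window(window, "gm")
  x0 <- window$values
  x1 <- ago(window)$values
  n <- length(x0)
  z <- (x1[-1L] + x1[-n]) / 2
  ls <- grey_lsq(cbind(-z, 1), x0[-1L])
  params <- list(a = ls$coef[1L], b = ls$coef[2L])
  diag <- if (abs(params$a) < 1e-12)
    "development coefficient a ~ 0: degenerate linear time response (flat forecast)"
  else character()
  new_grey_fit("gm", window, params, ls,
               simulated = grey_path_gm(params, x0[1L], n),
               diagnostics = diag)
}

grey_path_gm <- function(params, x0_initial, len) {
  k <- seq_len(len)
  x1hat <- if (abs(params$a) < 1e-12) {
    x0_initial + params$b * (k - 1)
  } else {
    (x0_initial - params$b / params$a) * exp(-params$a * (k - 1)) +
      params$b / params$a
  }
  iago(x1hat)
}

#' Fit the discrete grey model DGM(1,1)
#'
#' Least squares on the accumulated-scale recursion
#' \eqn{x^{(1)}(k+1) = \beta_1 x^{(1)}(k) + \beta_2}; fitted and
#' forecast values iterate the recursion from
#' \eqn{x^{(1)}(1) = x^{(0)}(1)} and restore by differencing. Exact on
#' geometric sequences (unlike GM(1,1), whose restoration carries an
#' inherent discretisation bias there).
#'
#' @param window A [grey_series] of at least 4 observations.
#' @return A `grey_fit`.
#' @export
fit_dgm <- function(window) {
  window <- check_window(window, "dgm")
  x1 <- ago(window)$values
  n <- length(x1)
  ls <- grey_lsq(cbind(x1[-n], 1), x1[-1L])
  params <- list(beta1 = ls$coef[1L], beta2 = ls$coef[2L])
  new_grey_fit("dgm", window, params, ls,
               simulated = grey_path_lin(params, x1[1L], n, restore = 1L))
}

# iterate y(k+1) = b1 y(k) + b2 from y(1), then difference `restore` times
grey_path_lin <- function(params, y_initial, len, restore = 0L) {
  y <- numeric(len)
  y[1L] <- y_initial
  if (len > 1L) for (t in seq_len(len - 1L)) {
    y[t + 1L] <- params$beta1 * y[t] + params$beta2
  }
  r <- 0L
  while (r < restore) {
    y <- iago(y)
    r <- r + 1L
  }
  y
}

#' Fit the indirect discrete grey model IDGM(1,1)
#'
#' Treats the accumulated sequence \eqn{x^{(1)}} as the raw data,
#' accumulates once more to \eqn{x^{(2)}}, fits the DGM recursion
#' \eqn{x^{(2)}(k+1) = \beta_1 x^{(2)}(k) + \beta_2}, and restores
#' twice by differencing (each pass anchored at its first observed
#' element). This is the plain reconstruction of the
#' indirect-modelling idea (the defining equations are not fixed by a
#' single canonical reference; see the package vignette).
#'
#' @param window A [grey_series] of at least 4 observations.
#' @return A `grey_fit`.
#' @export
fit_idgm <- function(window) {
  window <- check_window(window, "idgm")
  x1 <- ago(window)$values
  x2 <- cumsum(x1)
  n <- length(x2)
  ls <- grey_lsq(cbind(x2[-n], 1), x2[-1L])
  params <- list(beta1 = ls$coef[1L], beta2 = ls$coef[2L])
  new_grey_fit("idgm", window, params, ls,
               simulated = grey_path_lin(params, x2[1L], n, restore = 2L))
}

#' Fit the direct discrete grey model DDGM(1,1)
#'
#' Models the raw data with no accumulation at all: least squares on
#' \eqn{x^{(0)}(k+1) = \beta_1 x^{(0)}(k) + \beta_2}, simulation and
#' forecasting by iterating from \eqn{x^{(0)}(1)}. Appropriate when the
#' original sequence itself is already approximately nonhomogeneous
#' exponential, so that accumulation would disturb the pattern.
#'
#' @param window A [grey_series] of at least 3 observations.
#' @return A `grey_fit`.
#' @export
fit_ddgm <- function(window) {
  window <- check_window(window, "ddgm")
  x0 <- window$values
  n <- length(x0)
  ls <- grey_lsq(cbind(x0[-n], 1), x0[-1L])
  params <- list(beta1 = ls$coef[1L], beta2 = ls$coef[2L])
  new_grey_fit("ddgm", window, params, ls,
               simulated = grey_path_lin(params, x0[1L], n, restore = 0L))
}

#' Fit a grey model by name
#'
#' @param window A [grey_series].
#' @param model One of `"gm"`, `"dgm"`, `"dngm"`, `"idgm"`, `"ddgm"`.
#' @return A `grey_fit`.
#' @export
fit_grey <- function(window, model = c("dngm", "gm", "dgm", "idgm", "ddgm")) {
  model <- match.arg(model)
  switch(model,
         gm = fit_gm(window), dgm = fit_dgm(window), dngm = fit_dngm(window),
         idgm = fit_idgm(window), ddgm = fit_ddgm(window))
}

# full original-scale path (in-sample + extrapolation) of length `len`
grey_path <- function(fit, len) {
  switch(fit$model,
    dngm = grey_path_dngm(fit$params, ago(fit$window)$values[1L], len),
    gm   = grey_path_gm(fit$params, fit$window$values[1L], len),
    dgm  = grey_path_lin(fit$params, fit$window$values[1L], len, restore = 1L),
    idgm = grey_path_lin(fit$params, fit$window$values[1L], len, restore = 2L),
    ddgm = grey_path_lin(fit$params, fit$window$values[1L], len, restore = 0L)
  )
}

#' Simulate and extrapolate a fitted grey model
#'
#' Returns the restored in-sample fitted values over the fitted window
#' followed by `horizon` extrapolated values, all on the original
#' scale. Extrapolation iterates the model's own recursion (or, for
#' GM(1,1), evaluates its time response) beyond the window.
#'
#' @param fit A `grey_fit`.
#' @param horizon Number of extrapolation steps, \eqn{\ge 0}.
#' @return A [grey_series] of length `length(fit$window) + horizon`,
#'   with periods continued at the window's spacing.
#' @export
simulate_static <- function(fit, horizon = 0L) {
  stopifnot(inherits(fit, "grey_fit"))
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  if (!fit$well_posed) {
    stop("cannot simulate an ill-posed fit: ", paste(fit$diagnostics,
         collapse = "; "), call. = FALSE)
  }
  n <- length(fit$window)
  vals <- grey_path(fit, n + as.integer(horizon))
  per <- fit$window$periods
  step <- if (n > 1L) per[2L] - per[1L] else 1L
  periods <- c(per, if (horizon > 0) per[n] + step * seq_len(horizon))
  # fitted values may dip <= 0 on awkward windows; positivity is an
  # observed-data invariant, not a fitted-value one
  structure(list(periods = as.integer(periods), values = as.numeric(vals)),
            class = "grey_series")
}
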