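#' Specify a synthetic grey-process series
#'
#' Generator specifications for the data regimes the grey models
#' assume, so every stage of the pipeline is testable without external
#' data:
#' \describe{
#'   \item{`exact_dngm`}{constant-plus-decaying-exponential on the
#'     original scale, \eqn{x^{(0)}(t) = (1-e^{A}) K e^{-A(t-1)} + B/A}
#'     for \eqn{t \ge 2} with \eqn{x^{(0)}(1)} anchored at `x1_1` —
#'     the family the DNGM reduction formula produces. Parameters
#'     `A`, `B`, `C`, `x1_1`.}
#'   \item{`exact_geometric`}{\eqn{x^{(0)}(t) = first \cdot ratio^{t-1}}.}
#'   \item{`noisy_dngm`}{an `exact_dngm` series with multiplicative
#'     Gaussian noise, each value scaled by \eqn{(1+\epsilon_t)},
#'     \eqn{\epsilon_t \sim N(0, noise\_sd)}, floored at `1e-6` to keep
#'     positivity.}
#'   \item{`break_series`}{two exact DNGM regimes concatenated at
#'     `break_index` (regime time restarts after the break), with
#'     optional multiplicative noise — a decline-then-rise structural
#'     break of the kind annual accident-fatality records show.}
#' }
#'
#' @param process One of `"exact_dngm"`, `"exact_geometric"`,
#'   `"noisy_dngm"`, `"break_series"`.
#' @param length Series length, at least 4.
#' @param seed Integer seed; mandatory whenever `noise_sd > 0`. Never
#'   derived from the clock.
#' @param noise_sd Noise standard deviation as a fraction of level;
#'   must be 0 for `exact_*` processes.
#' @param ... Process parameters: `A`, `B`, `C`, `x1_1` (DNGM-type,
#'   possibly via [dngm_shape()]); `first`, `ratio` (geometric);
#'   `pre`, `post`, `break_index` (break series, `pre`/`post` each a
#'   list with `A`, `B`, `C`, `x1_1`).
#' @return An object of class `grey_spec`.
#' @export
grey_spec <- function(process = c("exact_dngm", "exact_geometric",
                                  "noisy_dngm", "break_series"),
                      length, seed = NULL, noise_sd = 0, ...) {
  process <- match.arg(process)
  length <- as.integer(length)
  if (length < 4L) stop("generated series must have length >= 4", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (startsWith(process, "exact_") && noise_sd != 0) {
    stop(sprintf("%s requires noise_sd = 0", process), call. = FALSE)
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is mandatory for noisy processes", call. = FALSE)
  }
  params <- list(...)
  need <- switch(process,
                 exact_dngm = , noisy_dngm = c("A", "B", "C", "x1_1"),
                 exact_geometric = c("first", "ratio"),
                 break_series = c("pre", "post", "break_index"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop(sprintf("%s needs parameter(s): %s", process,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(process = process, length = length,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 noise_sd = noise_sd, params = params),
            class = "grey_spec")
}

#' DNGM whitening parameters from a shape description
#'
#' Convenience parametrisation of the `exact_dngm` family by what the
#' curve looks like: it starts at `first`, and for \eqn{t \ge 2}
#' follows \eqn{(first - level)\,e^{-rate\,(t-1)} + level}, i.e. decays
#' toward (or, with `first < level`, rises toward) the asymptote
#' `level` at exponential rate `rate`. Returns the corresponding
#' whitening parameters `A`, `B`, `C`, `x1_1`.
#'
#' @param first First value of the series (also \eqn{x^{(1)}(1)}).
#' @param level Asymptotic level \eqn{B/A} of the original-scale curve.
#' @param rate Exponential rate \eqn{A > 0}.
#' @return List with `A`, `B`, `C`, `x1_1`, usable as `grey_spec(...)`
#'   parameters.
#' @export
dngm_shape <- function(first, level, rate) {
  stopifnot(rate > 0, first > 0)
  A <- rate
  B <- A * level
  K <- (first - level) / (1 - exp(A))
  # K = x1_1 - B/A + B/A^2 - C/A  =>  C = A (x1_1 - B/A + B/A^2 - K)
  C <- A * (first - B / A + B / A^2 - K)
  list(A = A, B = B, C = C, x1_1 = first)
}

exact_dngm_values <- function(p, len) {
  A <- p$A; B <- p$B; C <- p$C
  K <- p$x1_1 - B / A + B / A^2 - C / A
  t <- seq_len(len)
  v <- (1 - exp(A)) * K * exp(-A * (t - 1)) + B / A
  v[1L] <- p$x1_1
  v
}

#' Generate a synthetic series from a specification
#'
#' Deterministic given the spec (identical spec + seed always yields
#' the identical series); the caller's RNG state is left untouched.
#'
#' @param spec A [grey_spec].
#' @param start_period First period label (default 1).
#' @return A [grey_series].
#' @examples
#' generate_series(grey_spec("exact_dngm", length = 5,
#'                           A = log(2), B = 2 * log(2), C = 2, x1_1 = 1))
#' @export
generate_series <- function(spec, start_period = 1L) {
  stopifnot(inherits(spec, "grey_spec"))
  p <- spec$params
  len <- spec$length
  v <- switch(spec$process,
    exact_dngm = , noisy_dngm = exact_dngm_values(p, len),
    exact_geometric = p$first * p$ratio^(seq_len(len) - 1),
    break_series = {
      bi <- as.integer(p$break_index)
      if (bi < 1L || bi >= len) {
        stop("break_index must lie strictly inside the series", call. = FALSE)
      }
      c(exact_dngm_values(p$pre, bi), exact_dngm_values(p$post, len - bi))
    })
  if (any(v <= 0)) {
    stop("process parameters produce nonpositive values; choose a positive asymptote/level",
         call. = FALSE)
  }
  if (spec$noise_sd > 0) {
    v <- with_preserved_rng(spec$seed, {
      pmax(v * (1 + stats::rnorm(len, 0, spec$noise_sd)), 1e-6)
    })
  }
  grey_series(v, seq.int(start_period, length.out = len))
}

# run expr under set.seed(seed), restoring the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Built-in generator presets
#'
#' Two fixed, documented study conditions:
#' \describe{
#'   \item{`fig2-like`}{length-20 structural-break series: 14 periods
#'     declining from about 2800 toward a floor of 1500 (rate 0.18),
#'     then a gradual 6-period recovery from about 1610 toward 2600
#'     (rate 0.18), multiplicative noise sd 0.03, seed 4202 — the
#'     decline-then-rise shape of two decades of annual construction
#'     fatality counts, with a continuous level at the break (the
#'     process parameters change, the level does not jump, as in real
#'     annual records).}
#'   \item{`table1-like`}{length-10 noisy DNGM series (first 110,
#'     level 60, rate 0.25, noise sd 0.06, seed 1001) for window-sweep
#'     tests: feasible for window candidates 4..9, infeasible for 10.}
#' }
#'
#' @param name `"fig2-like"` or `"table1-like"`.
#' @return A [grey_spec].
#' @export
preset_spec <- function(name) {
  presets <- c("fig2-like", "table1-like")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets)) {
    stop(sprintf("unknown preset '%s'; available presets: %s",
                 paste(name, collapse = ","), paste(presets, collapse = ", ")),
         call. = FALSE)
  }
  switch(name,
    "fig2-like" = grey_spec("break_series", length = 20L, seed = 4202L,
                            noise_sd = 0.03,
                            pre = dngm_shape(first = 2800, level = 1500,
                                             rate = 0.18),
                            post = dngm_shape(first = 1610, level = 2600,
                                              rate = 0.18),
                            break_index = 14L),
    "table1-like" = do.call(grey_spec, c(
      list("noisy_dngm", length = 10L, seed = 1001L, noise_sd = 0.06),
      dngm_shape(first = 110, level = 60, rate = 0.25)))
  )
}

#' @export
print.grey_spec <- function(x, ...) {
  cat(sprintf("<grey_spec> %s, length %d, noise_sd %g, seed %s\n",
              x$process, x$length, x$noise_sd,
              if (is.na(x$seed)) "none" else x$seed))
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}
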