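#' Construct a grey time series
#'
#' The universal input container for all grey models: a univariate,
#' strictly positive, equally spaced series \eqn{x^{(0)}} with integer
#' period labels (typically years). Period labels are metadata only;
#' all model mathematics uses the 1-based index \eqn{t = 1, \dots, n}.
#'
#' @param values Numeric vector of strictly positive observations.
#' @param periods Integer period labels, strictly increasing with unit
#'   spacing. Defaults to `seq_along(values)`.
#' @return An object of class `grey_series`: a list with elements
#'   `periods` and `values`.
#' @examples
#' grey_series(c(2, 1, 0.5, 0.25), periods = 2001:2004)
#' @export
grey_series <- function(values, periods = seq_along(values)) {
  values <- as.numeric(values)
  periods <- as.integer(periods)
  if (length(values) < 1L) {
    stop("a grey series needs at least one observation", call. = FALSE)
  }
  if (length(values) != length(periods)) {
    stop("`values` and `periods` must have the same length", call. = FALSE)
  }
  if (anyNA(values) || anyNA(periods)) {
    stop("grey series must not contain missing values", call. = FALSE)
  }
  bad <- which(values <= 0)
  if (length(bad)) {
    stop(sprintf(
      "all values must be strictly positive (MAPE and the grey recursions are undefined at zero); offending period(s): %s",
      paste(periods[bad], collapse = ", ")
    ), call. = FALSE)
  }
  if (length(periods) > 1L) {
    d <- diff(periods)
    if (any(d != d[1L]) || d[1L] <= 0L) {
      stop("periods must be strictly increasing with constant spacing",
           call. = FALSE)
    }
  }
  structure(list(periods = periods, values = values), class = "grey_series")
}

#' @export
print.grey_series <- function(x, ...) {
  cat(sprintf("<grey_series> %d observations, periods %d..%d\n",
              length(x$values), min(x$periods), max(x$periods)))
  print(stats::setNames(x$values, x$periods))
  invisible(x)
}

#' @export
length.grey_series <- function(x) length(x$values)

#' @export
as.data.frame.grey_series <- function(x, ...) {
  data.frame(period = x$periods, value = x$values)
}

as_grey_series <- function(x) {
  if (inherits(x, "grey_series")) return(x)
  grey_series(x)
}

#' First-order accumulated generating operation (1-AGO)
#'
#' Computes the accumulation sequence
#' \eqn{x^{(1)}(k) = \sum_{i \le k} x^{(0)}(i)}, the internal modelling
#' scale of GM(1,1), DGM(1,1), DNGM(1,1) and IDGM(1,1).
#'
#' @param series A [grey_series] (or bare positive numeric vector).
#' @return An object of class `grey_ago`: list with `values` (the
#'   accumulated sequence, strictly increasing) and `origin` (the input
#'   series).
#' @seealso [iago()] for the inverse operation.
#' @examples
#' ago(grey_series(c(1, 2, 3)))$values  # 1 3 6
#' @export
ago <- function(series) {
  series <- as_grey_series(series)
  structure(list(values = cumsum(series$values), origin = series),
            class = "grey_ago")
}

#' Inverse accumulated generating operation (IAGO)
#'
#' First differencing with the first element kept:
#' \eqn{y(1) = x^{(1)}(1)}, \eqn{y(k) = x^{(1)}(k) - x^{(1)}(k-1)}.
#' Exact inverse of [ago()]: `iago(ago(s))` reproduces `s`.
#'
#' @param acc A `grey_ago` object or a numeric vector of accumulated
#'   values.
#' @return Numeric vector of restored original-scale values.
#' @examples
#' iago(c(1, 3, 6))  # 1 2 3
#' @export
iago <- function(acc) {
  v <- if (inherits(acc, "grey_ago")) acc$values else as.numeric(acc)
  if (length(v) < 1L) stop("cannot difference an empty sequence", call. = FALSE)
  c(v[1L], diff(v))
}

#' Read a grey series from CSV
#'
#' The file contract is two columns with header `period,value`, UTF-8,
#' `.` decimal separator; periods must parse as integers.
#'
#' @param path Path to a CSV file.
#' @return A [grey_series].
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("period", "value") %in% names(df))) {
    stop(sprintf(
      "CSV at %s must have header columns `period,value` (found: %s)",
      path, paste(names(df), collapse = ",")
    ), call. = FALSE)
  }
  per <- suppressWarnings(as.numeric(df$period))
  bad <- is.na(per) | per != round(per)
  if (any(bad)) {
    stop(sprintf("non-integer period at line(s) %s of %s",
                 paste(which(bad) + 1L, collapse = ", "), path),
         call. = FALSE)
  }
  per <- as.integer(per)
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    stop(sprintf("non-numeric value at line(s) %s of %s",
                 paste(which(is.na(val)) + 1L, collapse = ", "), path),
         call. = FALSE)
  }
  grey_series(val, per)
}

#' Write a grey series to CSV
#'
#' @param series A [grey_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  series <- as_grey_series(series)
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
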