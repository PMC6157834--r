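#' Concentration-time curve
#'
#' A sampled concentration-time function, the common container for arterial
#' input functions (AIFs) and tissue curves. Time is in seconds; concentration
#' in any consistent unit (conventionally mM). Sampling may be non-uniform but
#' times must be strictly increasing and non-negative.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, `times[1] >= 0`.
#' @param values Numeric vector of concentrations, same length as `times`.
#' @return An object of class `"dce_curve"`: a list with elements `times` and
#'   `values`.
#' @examples
#' cv <- dce_curve(seq(0, 298, by = 2), rep(0, 150))
#' length(cv$times)
#' @export
dce_curve <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length", call. = FALSE)
  if (length(times) < 2L)
    stop("a curve needs at least two samples", call. = FALSE)
  if (anyNA(times) || anyNA(values))
    stop("curve contains missing values", call. = FALSE)
  if (times[1L] < 0)
    stop("times must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values), class = "dce_curve")
}

#' @export
print.dce_curve <- function(x, ...) {
  cat(sprintf("<dce_curve> %d samples over [%g, %g] s, peak %.4g\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.dce_curve <- function(x, ...) {
  data.frame(time_s = x$times, concentration = x$values)
}

#' @export
length.dce_curve <- function(x) length(x$times)

#' @rdname dce_curve
#' @param x Object to test or convert.
#' @export
is_dce_curve <- function(x) inherits(x, "dce_curve")

as_curve <- function(x) {
  if (is_dce_curve(x)) return(x)
  if (is.data.frame(x) && ncol(x) >= 2L) return(dce_curve(x[[1L]], x[[2L]]))
  stop("cannot interpret input as a concentration-time curve", call. = FALSE)
}

#' Read or write a curve as two-column delimited text
#'
#' Curves are exchanged as plain text with columns (time_s, concentration);
#' whitespace- or comma-delimited, with an optional header line.
#'
#' @param path Path to a text file.
#' @return `read_curve()` returns a [dce_curve]; `write_curve()` returns the
#'   path invisibly.
#' @export
read_curve <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           comment.char = "#")
  dce_curve(tab[[1L]], tab[[2L]])
}

#' @rdname read_curve
#' @param curve A [dce_curve].
#' @export
write_curve <- function(curve, path) {
  curve <- as_curve(curve)
  utils::write.table(
    data.frame(time_s = curve$times, concentration = curve$values),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Evaluate a (possibly delayed) curve on an arbitrary time grid
#'
#' Linear interpolation with zero-padding before the first sample and
#' last-value extension after the last, so that a bolus that has not yet
#' arrived contributes nothing. A positive `delay` shifts the curve later in
#' time: the returned value at time `t` is `curve(t - delay)`.
#'
#' @param curve A [dce_curve].
#' @param times Numeric vector of query times (seconds).
#' @param delay Time shift in seconds (may be negative).
#' @return Numeric vector of interpolated values.
#' @export
curve_at <- function(curve, times, delay = 0) {
  curve <- as_curve(curve)
  stats::approx(curve$times + delay, curve$values, xout = times,
                yleft = 0, yright = curve$values[length(curve$values)])$y
}

#' Hematocrit correction of a blood concentration curve
#'
#' Converts whole-blood contrast concentration to plasma concentration,
#' `Cp = Cb / (1 - Hct)`. Kinetic models take the AIF as *plasma*
#' concentration; whether a measured arterial curve needs this correction
#' depends on how it was derived, so the correction is explicit and optional.
#'
#' @param curve A [dce_curve] of whole-blood concentration.
#' @param hct Hematocrit as a fraction; default 0.45.
#' @return A [dce_curve] of plasma concentration.
#' @export
hct_correct <- function(curve, hct = 0.45) {
  curve <- as_curve(curve)
  if (hct < 0 || hct >= 1) stop("hct must be in [0, 1)", call. = FALSE)
  dce_curve(curve$times, curve$values / (1 - hct))
}

# Cumulative trapezoidal integral of y over x, same length as x (first entry 0).
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

# Definite trapezoidal integral of a curve over [a, b]; integrates the
# piecewise-linear interpolant, adding the partial end panels.
trapz_window <- function(curve, a, b) {
  tt <- curve$times
  if (b <= a) return(0)
  grid <- sort(unique(c(a, b, tt[tt > a & tt < b])))
  vals <- curve_at(curve, grid)
  sum(diff(grid) * (vals[-1L] + vals[-length(vals)]) / 2)
}

# Unit conversions: user-facing flows are ml/100g/min; internally all rate
# constants are fraction per second (tissue density 1 g/ml assumed).
flow_to_si <- function(x) x / 6000
flow_from_si <- function(x) x * 6000
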