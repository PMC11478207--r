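#' Uniformly sampled voltage trace
#'
#' A `trace` is the universal currency of the pipeline: a voltage time
#' series sampled at a uniform interval `dt` (ms), starting at `t0` (ms,
#' may be negative for stimulus-aligned recordings), with values in mV.
#'
#' @param values numeric vector of voltages (mV); all finite, length >= 2.
#' @param dt sampling interval in ms, > 0.
#' @param t0 time of the first sample in ms (default 0).
#' @return An object of class `trace`: a list with elements `values`,
#'   `dt`, `t0`.
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.5)
#' head(trace_times(tr))
#' @export
trace <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a trace needs at least 2 samples, got ", length(values))
  if (!all(is.finite(values)))
    stop("trace values must all be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (ms)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("t0 must be a single finite number (ms)")
  structure(list(values = values, dt = as.numeric(dt), t0 = as.numeric(t0)),
            class = "trace")
}

#' Sample times of a trace
#'
#' @param x a [trace()].
#' @return Numeric vector `t0 + (0:(n-1)) * dt`, in ms.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
length.trace <- function(x) length(x$values)

#' @export
print.trace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<trace> %d samples, dt = %g ms, span [%g, %g] ms\n",
              n, x$dt, x$t0, x$t0 + (n - 1) * x$dt))
  cat(sprintf("  voltage range [%.4g, %.4g] mV\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(time_ms = trace_times(x), voltage_mV = x$values)
}

# Truncate two traces to their overlapping time window (shared dt required).
# Returns a list(x, y) of equal-length traces on a common time base.
align_traces <- function(x, y, tol = 1e-9) {
  stopifnot(inherits(x, "trace"), inherits(y, "trace"))
  if (abs(x$dt - y$dt) > tol * max(x$dt, y$dt))
    stop("dt mismatch: ", x$dt, " vs ", y$dt, " ms")
  dt <- x$dt
  # offset of y's grid relative to x's, in samples; must be near-integer
  k <- (y$t0 - x$t0) / dt
  if (abs(k - round(k)) > 1e-6)
    stop("time grids are not commensurate (offset ", y$t0 - x$t0, " ms)")
  k <- round(k)
  nx <- length(x$values); ny <- length(y$values)
  # overlap in x's sample indices (0-based)
  lo <- max(0L, k)
  hi <- min(nx - 1L, k + ny - 1L)
  if (hi - lo + 1L < 2L)
    stop("traces share fewer than 2 overlapping samples")
  xi <- (lo:hi) + 1L
  yi <- (lo:hi) - k + 1L
  list(x = trace(x$values[xi], dt, x$t0 + lo * dt),
       y = trace(y$values[yi], dt, x$t0 + lo * dt))
}
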