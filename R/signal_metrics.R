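#' Descriptive statistics of a trace
#'
#' @param x a [trace()] with at least 2 samples.
#' @return A list of class `descriptive_stats`: `mean`, `sd` (sample,
#'   n-1 denominator), `min`, `max` (all mV) and `n`.
#' @export
descriptive_stats <- function(x) {
  stopifnot(inherits(x, "trace"))
  v <- x$values
  if (length(v) < 2L) stop("need at least 2 samples")
  structure(list(mean = mean(v), sd = stats::sd(v),
                 min = min(v), max = max(v), n = length(v)),
            class = "descriptive_stats")
}

#' Coefficient of variation (percent, signed)
#'
#' `CV = sd/mean * 100`, computed on the raw values; the sign follows
#' the mean (voltage means can be negative, so the CV is signed here).
#'
#' @param x a [trace()].
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  stopifnot(inherits(x, "trace"))
  s <- descriptive_stats(x)
  if (abs(s$mean) <= 1e-12 * s$sd)
    stop("CV undefined: mean is ~0 relative to the sd")
  s$sd / s$mean * 100
}

rms <- function(v) sqrt(mean(v^2))

# centred moving average with shrinking windows at the edges
moving_average <- function(v, window) {
  if (window %% 2 == 0) window <- window + 1L
  h <- (window - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Signal-to-noise ratio in dB
#'
#' `SNR = 20 log10(RMS_signal / RMS_noise)`. When no explicit noise
#' trace is given, the noise is estimated as the residual of a centred
#' moving average of the signal (window in samples, default 51; edge
#' windows shrink).
#'
#' @param signal a [trace()].
#' @param noise optional [trace()] holding the noise record; if `NULL`,
#'   the moving-average residual estimator is used.
#' @param window moving-average window in samples (odd; default 51).
#' @return SNR in dB.
#' @export
snr_db <- function(signal, noise = NULL, window = 51L) {
  stopifnot(inherits(signal, "trace"))
  s <- signal$values
  nse <- if (is.null(noise)) {
    s - moving_average(s, window)
  } else {
    stopifnot(inherits(noise, "trace"))
    noise$values
  }
  rn <- rms(nse)
  if (rn <= 0) stop("noise RMS is zero; SNR undefined")
  20 * log10(rms(s) / rn)
}

#' Pearson correlation of two traces
#'
#' @param x,y [trace()]s of equal length, each with nonzero variance.
#' @return Sample Pearson r in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  stopifnot(inherits(x, "trace"), inherits(y, "trace"))
  if (length(x$values) != length(y$values))
    stop("length mismatch: ", length(x$values), " vs ", length(y$values))
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x$values, y$values)
}

#' Root mean square error between two traces
#'
#' @param x,y [trace()]s of equal length.
#' @return RMSE in mV.
#' @export
rmse <- function(x, y) {
  stopifnot(inherits(x, "trace"), inherits(y, "trace"))
  if (length(x$values) != length(y$values))
    stop("length mismatch: ", length(x$values), " vs ", length(y$values))
  sqrt(mean((x$values - y$values)^2))
}

#' Maximum absolute sample-wise difference
#'
#' @param x,y [trace()]s of equal length on a shared time base.
#' @return List with `value` (mV) and `time` (ms) of the first
#'   occurrence of the maximum; ties break to the earliest time.
#' @export
max_abs_diff <- function(x, y) {
  stopifnot(inherits(x, "trace"), inherits(y, "trace"))
  if (length(x$values) != length(y$values))
    stop("length mismatch: ", length(x$values), " vs ", length(y$values))
  d <- abs(x$values - y$values)
  k <- which.max(d)  # first index at the max
  list(value = d[k], time = trace_times(x)[k])
}

# raw cross-covariance sums c(tau) = sum_t x[t] y[t+tau] for
# tau = -L..L, via zero-padded FFT; returns a (2L+1)-vector
xcov_sums_fft <- function(x, y, L) {
  n <- length(x)
  m <- stats::nextn(n + L, 2)
  fx <- stats::fft(c(x, numeric(m - n)))
  fy <- stats::fft(c(y, numeric(m - n)))
  z <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / m
  # z[1 + tau] for tau >= 0; z[m + 1 + tau] for tau < 0
  c(z[m + 1 - (L:1)], z[seq_len(L + 1)])
}

#' Cross-correlation lag between two traces
#'
#' Both series are demeaned; the lag maximising the cross-correlation
#' of `x` with `y` shifted by tau over `[-max_lag, max_lag]` is
#' returned. Sign convention: a negative lag means the output (`y`)
#' leads (precedes) the input (`x`). The correlation at each lag is
#' normalised by the overlap count (unbiased): with near-periodic
#' stimuli the biased (divide-by-N) estimator systematically aliases a
#' large true lag to a small one, because shrinking overlap penalises
#' the true peak more than an in-phase alias near zero. Ties break to
#' the smallest |lag|, then to the negative lag.
#'
#' @param x,y [trace()]s with equal `dt` (the stimulus and the
#'   response).
#' @param max_lag maximum |lag| searched, in ms; default half the
#'   shorter trace's span.
#' @return Lag in ms (a multiple of `dt`).
#' @export
xcorr_lag <- function(x, y, max_lag = NULL) {
  stopifnot(inherits(x, "trace"), inherits(y, "trace"))
  if (abs(x$dt - y$dt) > 1e-9 * max(x$dt, y$dt))
    stop("dt mismatch: ", x$dt, " vs ", y$dt, " ms")
  dt <- x$dt
  n <- min(length(x$values), length(y$values))
  span <- (n - 1) * dt
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag >= span) stop("max_lag must be smaller than the trace span")
  L <- floor(max_lag / dt)
  xv <- x$values[seq_len(n)] - mean(x$values[seq_len(n)])
  yv <- y$values[seq_len(n)] - mean(y$values[seq_len(n)])
  taus <- (-L):L
  cc <- xcov_sums_fft(xv, yv, L) / (n - abs(taus))
  best <- max(cc)
  cand <- taus[cc >= best - 1e-12 * max(1, abs(best))]
  cand <- cand[order(abs(cand), cand)]
  cand[1] * dt
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Exact sup-difference of the two empirical CDFs over the pooled
#' sample points, with the asymptotic Kolmogorov p-value at effective
#' size `n1 n2 / (n1 + n2)` (series truncated at 100 terms). `H` is the
#' rejection indicator at alpha = 0.05.
#'
#' @param x,y numeric samples (or [trace()]s, whose values are used).
#' @return List of class `ks_result`: `D` in [0,1], `p`, `H`.
#' @export
ks_two_sample <- function(x, y) {
  if (inherits(x, "trace")) x <- x$values
  if (inherits(y, "trace")) y <- y$values
  if (length(x) < 1L || length(y) < 1L) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- sort(unique(c(x, y)))
  # ECDF at the pooled points via sorted-rank counting; exact
  F1 <- findInterval(pooled, sort(x)) / n1
  F2 <- findInterval(pooled, sort(y)) / n2
  D <- max(abs(F1 - F2))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- sqrt(ne) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(max(p, 0), 1)
  structure(list(D = D, p = p, H = p < 0.05), class = "ks_result")
}

#' Matched quantile pairs for a Q-Q comparison
#'
#' Quantiles of both samples at the shared probability grid
#' `seq(0, 1, length.out = n_q)`, using the linear-interpolation
#' quantile rule (R type 7). For equal-length samples with
#' `n_q = length(x)` the pairs equal the two sorted samples.
#'
#' @param x,y numeric samples (or [trace()]s).
#' @param n_q number of quantiles (>= 2).
#' @return Data frame with columns `input_q`, `output_q` (both
#'   non-decreasing, mV).
#' @export
qq_points <- function(x, y, n_q = 100L) {
  if (inherits(x, "trace")) x <- x$values
  if (inherits(y, "trace")) y <- y$values
  if (n_q < 2L) stop("need n_q >= 2")
  p <- seq(0, 1, length.out = n_q)
  data.frame(input_q = unname(stats::quantile(x, p, type = 7)),
             output_q = unname(stats::quantile(y, p, type = 7)))
}

#' Full input/output comparison report
#'
#' Assembles every stimulus/response metric for one stimulation mode:
#' descriptive statistics of both traces, mean difference
#' (input mean - output mean), signed coefficients of variation, SNR of
#' both traces and the SNR gain, Pearson correlation, RMSE, maximum
#' absolute difference and its time, cross-correlation lag (negative =
#' output leads) and the two-sample Kolmogorov-Smirnov test. Traces
#' with different but commensurate time bases are truncated to their
#' overlapping window first.
#'
#' @param input,output [trace()]s (stimulus and sample response).
#' @param max_lag lag search bound in ms (default half the overlap
#'   span).
#' @param snr_window moving-average window (samples) for the SNR noise
#'   estimator.
#' @return A list of class `comparison_report`.
#' @examples
#' p <- make_mode_preset("tonic")
#' s <- simulate_izhikevich(p$params, p$drive, 500)
#' rep <- compare(s, s)
#' rep$r; rep$rmse
#' @export
compare <- function(input, output, max_lag = NULL, snr_window = 51L) {
  al <- align_traces(input, output)
  x <- al$x; y <- al$y
  cv_safe <- function(tr) tryCatch(coefficient_of_variation(tr),
                                   error = function(e) NA_real_)
  in_stats <- descriptive_stats(x)
  out_stats <- descriptive_stats(y)
  snr_in <- snr_db(x, window = snr_window)
  snr_out <- snr_db(y, window = snr_window)
  md <- max_abs_diff(x, y)
  ks <- ks_two_sample(x, y)
  lag <- xcorr_lag(x, y, max_lag)
  structure(list(
    input_stats = in_stats,
    output_stats = out_stats,
    delta_mean = in_stats$mean - out_stats$mean,
    cv_input = cv_safe(x),
    cv_output = cv_safe(y),
    snr_input_db = snr_in,
    snr_output_db = snr_out,
    snr_gain_db = snr_out - snr_in,
    r = pearson_r(x, y),
    rmse = rmse(x, y),
    max_diff = md$value,
    max_diff_time = md$time,
    lag_ms = lag,
    lag_samples = round(lag / x$dt),
    ks = ks,
    dt = x$dt,
    n = in_stats$n
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(render_report_text(x), sep = "\n")
  invisible(x)
}
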