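#' Izhikevich neuron parameters
#'
#' The two-variable quadratic integrate-and-fire model with recovery:
#' \deqn{dv/dt = 0.04 v^2 + 5 v + 140 - u + I}
#' \deqn{du/dt = a (b v - u)}
#' with the after-spike reset: when \eqn{v \ge v_{peak}}, the emitted
#' sample is clipped to `v_peak` and the state is reset to
#' \eqn{(c, u + d)}.
#'
#' @param a recovery time-scale (dimensionless, > 0).
#' @param b recovery sensitivity to subthreshold v (dimensionless).
#' @param c after-spike reset of v (mV).
#' @param d after-spike increment of u (dimensionless).
#' @param v_peak spike cut-off (mV, default 30).
#' @param v0 initial membrane potential (mV, default -70).
#' @param u0 initial recovery variable (default `b * v0`).
#' @return An `izh_params` list.
#' @export
izh_params <- function(a, b, c, d, v_peak = 30, v0 = -70, u0 = b * v0) {
  for (nm in c("a", "b", "c", "d", "v_peak", "v0", "u0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(nm, " must be a single finite number")
  }
  if (a <= 0) stop("a must be > 0")
  if (v_peak <= c) stop("v_peak must exceed the reset c")
  if (v0 > v_peak) stop("v0 must not exceed v_peak")
  structure(list(a = a, b = b, c = c, d = d,
                 v_peak = v_peak, v0 = v0, u0 = u0),
            class = "izh_params")
}

#' Injected-current program
#'
#' Describes the current I(t) driving a simulated neuron. Kinds:
#' `step` (0 before `onset`, `amplitude` after), `ramp` (slope
#' `amplitude` per ms from `onset`), `pulse_train` (rectangular pulses of
#' width `pulse_width` every `period` from `onset`), `custom` (explicit
#' per-sample values, recycled with zero-fill past the end). An optional
#' `t_off` switches the drive back to zero at that time; this lets ramped
#' protocols (e.g. accommodation) be expressed as pure data.
#'
#' @param kind one of `"step"`, `"ramp"`, `"pulse_train"`, `"custom"`.
#' @param amplitude current amplitude (model units); for `ramp` it is the
#'   slope in units per ms.
#' @param onset start time of the drive (ms, >= 0).
#' @param pulse_width,period pulse geometry (ms), `pulse_train` only;
#'   `pulse_width < period` required.
#' @param samples numeric vector of current values, `custom` only,
#'   aligned to the simulation grid starting at t = 0.
#' @param t_off optional time (ms) after which the drive is zero.
#' @return A `drive_spec` list.
#' @export
drive_spec <- function(kind = c("step", "ramp", "pulse_train", "custom"),
                       amplitude = 0, onset = 0, pulse_width = NULL,
                       period = NULL, samples = NULL, t_off = NA_real_) {
  kind <- match.arg(kind)
  if (onset < 0) stop("onset must be >= 0")
  if (kind == "pulse_train") {
    if (is.null(pulse_width) || is.null(period))
      stop("pulse_train needs pulse_width and period")
    if (pulse_width >= period)
      stop("pulse_width must be < period")
  }
  if (kind == "custom" && (is.null(samples) || !is.numeric(samples)))
    stop("custom drive needs a numeric `samples` vector")
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 pulse_width = pulse_width, period = period,
                 samples = samples, t_off = t_off),
            class = "drive_spec")
}

# Evaluate the drive at vector times t (ms). Vectorised.
drive_current <- function(drive, t) {
  stopifnot(inherits(drive, "drive_spec"))
  I <- switch(drive$kind,
    step = ifelse(t >= drive$onset, drive$amplitude, 0),
    ramp = pmax(0, t - drive$onset) * drive$amplitude,
    pulse_train = {
      ph <- (t - drive$onset) %% drive$period
      ifelse(t >= drive$onset & ph < drive$pulse_width, drive$amplitude, 0)
    },
    custom = {
      # samples are aligned to the simulation grid; zero-fill past the end
      out <- numeric(length(t))
      k <- seq_len(min(length(t), length(drive$samples)))
      out[k] <- drive$samples[k]
      out
    })
  if (!is.na(drive$t_off)) I[t >= drive$t_off] <- 0
  I
}

#' Simulate the Izhikevich neuron
#'
#' Forward-Euler integration of the two-variable model at a fixed step.
#' Emitted spike samples are clipped at `v_peak` so traces are bounded;
#' the sample after each clipped one starts from the reset value `c`.
#' Reset event times are recorded in the `spikes` attribute of the
#' returned trace (ms).
#'
#' @param params an [izh_params()].
#' @param drive a [drive_spec()].
#' @param duration run length in ms (> dt).
#' @param dt integration step in ms (default 0.25, the de-facto standard
#'   for this model).
#' @return A [trace()] of `floor(duration/dt) + 1` samples starting at
#'   t = 0, with attribute `spikes` (numeric vector of reset times, ms).
#' @examples
#' p <- make_mode_preset("tonic")
#' tr <- simulate_izhikevich(p$params, p$drive, duration = 500)
#' length(attr(tr, "spikes"))
#' @export
simulate_izhikevich <- function(params, drive, duration, dt = 0.25) {
  stopifnot(inherits(params, "izh_params"), inherits(drive, "drive_spec"))
  if (!(duration > dt && dt > 0)) stop("need duration > dt > 0")
  n <- floor(duration / dt) + 1L
  tt <- (seq_len(n) - 1) * dt
  I <- drive_current(drive, tt)
  vout <- numeric(n)
  v <- params$v0; u <- params$u0
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d
  vp <- params$v_peak
  spikes <- numeric(0)
  for (k in seq_len(n)) {
    if (!is.finite(v) || !is.finite(u))
      stop(sprintf("divergence at step %d (t = %g ms): v = %g, u = %g",
                   k, tt[k], v, u))
    if (v >= vp) {
      # the reset replaces this step's Euler update, so the sample
      # after a clipped one is exactly c
      vout[k] <- vp
      spikes <- c(spikes, tt[k])
      v <- cc
      u <- u + d
      next
    }
    vout[k] <- v
    dv <- 0.04 * v * v + 5 * v + 140 - u + I[k]
    du <- a * (b * v - u)
    v <- v + dt * dv
    u <- u + dt * du
  }
  out <- trace(vout, dt, t0 = 0)
  attr(out, "spikes") <- spikes
  out
}

#' Canonical firing-regime presets
#'
#' Returns the parameter set and drive program for one of the five
#' stimulation regimes used to drive the proteinoid sample:
#' accommodation (gradually adapting, ramped drive), chattering
#' (periodic bursts), induced/triggered (a rebound spike after a brief
#' hyperpolarising pulse), phasic (one initial spike then silence) and
#' tonic (sustained periodic firing). Values follow the standard
#' reference parameterisations of the model; they are plain data and the
#' caller may override any field.
#'
#' @param mode one of `"accommodation"`, `"chattering"`, `"induced"`,
#'   `"phasic"`, `"tonic"`.
#' @return A list with elements `params` ([izh_params()]), `drive`
#'   ([drive_spec()]) and `duration` (suggested run length, ms).
#' @export
make_mode_preset <- function(mode) {
  presets <- list(
    accommodation = list(
      params = izh_params(a = 0.02, b = 1, c = -55, d = 4,
                          v0 = -65, u0 = -16),
      drive = drive_spec("ramp", amplitude = 1 / 25, onset = 0, t_off = 200),
      duration = 400),
    chattering = list(
      params = izh_params(a = 0.02, b = 0.2, c = -50, d = 2, v0 = -70),
      drive = drive_spec("step", amplitude = 10, onset = 10),
      duration = 500),
    induced = list(
      params = izh_params(a = 0.03, b = 0.25, c = -60, d = 4, v0 = -64),
      drive = drive_spec("pulse_train", amplitude = -15, onset = 20,
                         pulse_width = 5, period = 1e9),
      duration = 200),
    phasic = list(
      params = izh_params(a = 0.02, b = 0.25, c = -65, d = 6, v0 = -64),
      drive = drive_spec("step", amplitude = 0.5, onset = 20),
      duration = 500),
    tonic = list(
      params = izh_params(a = 0.02, b = 0.2, c = -65, d = 6, v0 = -70),
      drive = drive_spec("step", amplitude = 14, onset = 10),
      duration = 500)
  )
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% names(presets)))
    stop("unknown mode ", deparse(mode), "; valid modes: ",
         paste(names(presets), collapse = ", "))
  presets[[mode]]
}

#' Detect spike times by upward threshold crossing
#'
#' A spike time is recorded at each sample k where
#' `value[k-1] < threshold <= value[k]`.
#'
#' @param trace a [trace()].
#' @param threshold crossing level in mV.
#' @return Numeric vector of crossing times (ms); may be empty.
#' @export
detect_spikes <- function(trace, threshold) {
  stopifnot(inherits(trace, "trace"))
  v <- trace$values
  k <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  trace_times(trace)[k]
}
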