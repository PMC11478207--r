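#' Ground-truth parameters for a synthetic proteinoid response
#'
#' Emulates the recorded omeprazole-proteinoid responses: strong
#' amplitude compression (gain a few percent), a positive baseline
#' shift of a fraction of a mV, a mode-dependent lead or lag, low-pass
#' smoothing and additive white Gaussian noise. These are the knobs the
#' recovery tests invert.
#'
#' @param gain dimensionless amplitude scale (typically 0.01-0.05).
#' @param offset baseline shift in mV (typically 0.3-0.8).
#' @param lag shift in ms, rounded to the nearest sample; negative
#'   means the output leads (precedes) the input.
#' @param lowpass_tau smoothing time constant in ms (>= 0; 0 = none).
#' @param noise_sd white-noise standard deviation in mV (>= 0).
#' @param seed integer RNG seed; the generator is reproducible given it.
#' @param edge_policy `"wrap"` (circular shift) or `"hold"` (edge
#'   values replicated).
#' @return A `synth_params` list.
#' @export
synth_params <- function(gain, offset, lag, lowpass_tau = 0,
                         noise_sd = 0, seed = 1L,
                         edge_policy = c("wrap", "hold")) {
  edge_policy <- match.arg(edge_policy)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (lowpass_tau < 0) stop("lowpass_tau must be >= 0")
  structure(list(gain = gain, offset = offset, lag = lag,
                 lowpass_tau = lowpass_tau, noise_sd = noise_sd,
                 seed = as.integer(seed), edge_policy = edge_policy),
            class = "synth_params")
}

# shift v so the output is the input delayed by k samples
# (out[t] = v[t - k]); k < 0 advances (output leads)
shift_samples <- function(v, k, edge_policy) {
  n <- length(v)
  if (k == 0) return(v)
  if (abs(k) >= n) stop("|lag| of ", k, " samples exceeds the trace length")
  if (edge_policy == "wrap") {
    idx <- ((seq_len(n) - 1 - k) %% n) + 1L
    v[idx]
  } else {
    idx <- pmin(pmax(seq_len(n) - k, 1L), n)
    v[idx]
  }
}

#' Generate a synthetic proteinoid response
#'
#' `output = gain * lowpass(shift(input - mean(input), lag)) + offset +
#' noise`: the gain compresses the input's fluctuations about its mean,
#' so the output baseline equals `offset` (the recorded responses sit
#' at a small positive mean regardless of the stimulus baseline). The
#' lag is realised as an integer-sample shift (wrap or hold edges), the
#' low-pass as one exact first-order smoothing stage (note a causal
#' low-pass adds its own group delay on top of `lag`), and the noise is
#' white Gaussian. Same `dt`, `t0` and length as the input;
#' reproducible given the seed (the caller's RNG state is untouched).
#'
#' @param input a [trace()] (the stimulus).
#' @param params a [synth_params()].
#' @return The response [trace()].
#' @examples
#' p <- make_mode_preset("tonic")
#' stim <- simulate_izhikevich(p$params, p$drive, 500)
#' resp <- generate_response(stim, synth_params(0.03, 0.8, lag = 40))
#' @export
generate_response <- function(input, params) {
  stopifnot(inherits(input, "trace"), inherits(params, "synth_params"))
  k <- round(params$lag / input$dt)
  n <- length(input$values)
  if (n < 2 * abs(k))
    stop("input too short for |lag| = ", params$lag,
         " ms (need >= ", 2 * abs(k), " samples, have ", n, ")")
  v <- shift_samples(input$values - mean(input$values), k, params$edge_policy)
  v <- lp1(v, params$lowpass_tau, input$dt)
  v <- params$gain * v + params$offset
  if (params$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(params$seed)
    v <- v + stats::rnorm(n, 0, params$noise_sd)
  }
  trace(v, input$dt, input$t0)
}

# per-mode ground-truth registry: lag (ms) and offset (mV) follow the
# recorded per-mode characteristics; gain = output sd / input sd of the
# same recordings. No smoothing in the presets: a causal low-pass would
# add its group delay to the injected lag and the presets exist to make
# the ground truth exactly recoverable (lowpass_tau stays available to
# callers emulating the recordings' smoothing).
synth_preset_table <- function() {
  list(
    accommodation = synth_params(gain = 0.028, offset = 0.60, lag = -306,
                                 noise_sd = 0.2),
    chattering    = synth_params(gain = 0.026, offset = 0.48, lag = -1981,
                                 noise_sd = 0.2),
    induced       = synth_params(gain = 0.028, offset = 0.34, lag = 1590,
                                 noise_sd = 0.2),
    phasic        = synth_params(gain = 0.040, offset = 0.54, lag = -359,
                                 noise_sd = 0.2),
    tonic         = synth_params(gain = 0.023, offset = 0.80, lag = -1231,
                                 noise_sd = 0.2)
  )
}

# tile one simulated sweep into a long stimulation record with
# jittered inter-sweep rest gaps (uniform 50-250 ms at the baseline
# level). An aperiodic sweep-onset process is what makes a large
# lead/lag uniquely identifiable by cross-correlation: with exactly
# periodic stimulation every lag alias one sweep period apart is
# indistinguishable. Real recordings are aperiodic through drift and
# trial-to-trial variability; the jitter stands in for that.
build_sweep_stimulus <- function(preset, duration, dt, seed) {
  sweep <- simulate_izhikevich(preset$params, preset$drive,
                               preset$duration, dt)
  baseline <- sweep$values[1]
  n_target <- floor(duration / dt) + 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  pieces <- list()
  n_have <- 0L
  while (n_have < n_target) {
    gap <- rep(baseline, round(stats::runif(1, 50, 250) / dt))
    pieces[[length(pieces) + 1L]] <- c(sweep$values, gap)
    n_have <- n_have + length(pieces[[length(pieces)]])
  }
  trace(unlist(pieces)[seq_len(n_target)], dt, 0)
}

#' Paired synthetic stimulus/response fixture for one mode
#'
#' Emulates one recording session: the mode's Izhikevich waveform is
#' played as repeated stimulation sweeps separated by jittered rest
#' gaps (as a waveform generator looping the stimulus would, with the
#' jitter standing in for the aperiodicity of real recordings), long
#' enough to accommodate the mode's lead/lag; the synthetic proteinoid
#' response is generated with the mode's ground-truth
#' gain/offset/lag/noise preset. Reproducible given the seed.
#'
#' @param name mode name (`accommodation`, `chattering`, `induced`,
#'   `phasic`, `tonic`).
#' @param seed RNG seed for sweep jitter and response noise (default 1).
#' @param duration stimulus length in ms (default 10000).
#' @param dt integration step in ms (default 0.25).
#' @return List with `stimulus` ([trace()]), `response` ([trace()]) and
#'   `truth` (the [synth_params()] used).
#' @examples
#' sc <- scenario("accommodation", seed = 7)
#' compare(sc$stimulus, sc$response, max_lag = 2500)$lag_ms  # -306
#' @export
scenario <- function(name, seed = 1L, duration = 10000, dt = 0.25) {
  reg <- synth_preset_table()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(reg)))
    stop("unknown scenario ", deparse(name), "; valid: ",
         paste(names(reg), collapse = ", "))
  truth <- reg[[name]]
  truth$seed <- as.integer(seed)
  mp <- make_mode_preset(name)
  stim <- build_sweep_stimulus(mp, duration, dt, seed = as.integer(seed))
  resp <- generate_response(stim, truth)
  list(stimulus = stim, response = resp, truth = truth)
}
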