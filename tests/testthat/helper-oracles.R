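# Independent oracles used across the suite. These stay deliberately
# naive (loops, enumeration) so they share no code path with the
# implementation they check.

# brute-force ECDF sup-difference over the pooled support
ks_D_oracle <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (q in pts) {
    d <- max(d, abs(mean(x <= q) - mean(y <= q)))
  }
  d
}

# brute-force overlap-normalised cross-correlation lag (samples)
xcorr_lag_oracle <- function(xv, yv, L) {
  xv <- xv - mean(xv); yv <- yv - mean(yv)
  n <- length(xv)
  taus <- (-L):L
  cc <- vapply(taus, function(tau) {
    t1 <- max(1, 1 - tau); t2 <- min(n, n - tau)
    sum(xv[t1:t2] * yv[(t1:t2) + tau]) / (n - abs(tau))
  }, numeric(1))
  best <- max(cc)
  cand <- taus[cc >= best - 1e-12 * max(1, abs(best))]
  cand[order(abs(cand), cand)][1]
}

# naive fixed-step integration of the spiking model at a fine step,
# reporting only the spike count (reference for dt-robustness checks)
izh_spike_count_oracle <- function(params, drive, duration, dt) {
  n <- floor(duration / dt) + 1L
  v <- params$v0; u <- params$u0
  count <- 0L
  for (k in seq_len(n)) {
    t <- (k - 1) * dt
    I <- drive_eval_oracle(drive, t)
    if (v >= params$v_peak) {
      count <- count + 1L
      v <- params$c
      u <- u + params$d
    } else {
      dv <- 0.04 * v * v + 5 * v + 140 - u + I
      du <- params$a * (params$b * v - u)
      v <- v + dt * dv
      u <- u + dt * du
    }
  }
  count
}

drive_eval_oracle <- function(drive, t) {
  I <- switch(drive$kind,
    step = if (t >= drive$onset) drive$amplitude else 0,
    ramp = max(0, t - drive$onset) * drive$amplitude,
    pulse_train = {
      ph <- (t - drive$onset) %% drive$period
      if (t >= drive$onset && ph < drive$pulse_width) drive$amplitude else 0
    },
    custom = stop("oracle does not support custom drives"))
  if (!is.na(drive$t_off) && t >= drive$t_off) I <- 0
  I
}

make_sine_trace <- function(omega, dt = 0.25, n = 4000) {
  trace(sin(omega * (0:(n - 1)) * dt), dt = dt)
}
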