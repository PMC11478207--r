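#' Omeprazole-proteinoid modulation parameters
#'
#' Terms by which the complex is proposed to modify Izhikevich dynamics:
#' an effective capacitance rescaling `Cm`, an added conductance `gOP`
#' toward reversal `EOP`, an extra recovery-attenuation rate `kOP`, and
#' shifts of the spike threshold (`dV_OP`), reset potential (`dc_OP`)
#' and reset increment (`dd_OP`).
#'
#' @param Cm effective capacitance scale (> 0, default 1).
#' @param gOP added conductance (model units, >= 0).
#' @param EOP reversal potential of the added conductance (mV).
#' @param kOP recovery attenuation rate (per ms, >= 0).
#' @param dV_OP spike-threshold shift (mV).
#' @param dc_OP reset-potential shift (mV; reset goes to `c - dc_OP`).
#' @param dd_OP reset-increment shift (dimensionless).
#' @return An `op_mod_params` list. All zeros (with Cm = 1) reduce the
#'   modulated model to the base Izhikevich neuron exactly.
#' @export
op_mod_params <- function(Cm = 1, gOP = 0, EOP = -65, kOP = 0,
                          dV_OP = 0, dc_OP = 0, dd_OP = 0) {
  if (Cm <= 0) stop("Cm must be > 0")
  if (gOP < 0) stop("gOP must be >= 0")
  if (kOP < 0) stop("kOP must be >= 0")
  structure(list(Cm = Cm, gOP = gOP, EOP = EOP, kOP = kOP,
                 dV_OP = dV_OP, dc_OP = dc_OP, dd_OP = dd_OP),
            class = "op_mod_params")
}

#' Simulate the modulated Izhikevich neuron
#'
#' Integrates
#' \deqn{C_m dv/dt = 0.04 v^2 + 5 v + 140 - u + I - g_{OP}(v - E_{OP})}
#' \deqn{du/dt = a (b v - u) - k_{OP} u}
#' with the modified reset: when \eqn{v \ge v_{peak} + \Delta V_{OP}},
#' the emitted sample is clipped at that threshold and the state becomes
#' \eqn{(c - \Delta c_{OP},\; u + d + \Delta d_{OP})}; below threshold
#' the continuous equations keep running.
#'
#' @inheritParams simulate_izhikevich
#' @param mod an [op_mod_params()].
#' @return A [trace()] with `spikes` attribute, as [simulate_izhikevich()].
#' @export
simulate_op_neuron <- function(params, mod, drive, duration, dt = 0.25) {
  stopifnot(inherits(params, "izh_params"), inherits(mod, "op_mod_params"),
            inherits(drive, "drive_spec"))
  if (!(duration > dt && dt > 0)) stop("need duration > dt > 0")
  n <- floor(duration / dt) + 1L
  tt <- (seq_len(n) - 1) * dt
  I <- drive_current(drive, tt)
  vout <- numeric(n)
  v <- params$v0; u <- params$u0
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d
  vth <- params$v_peak + mod$dV_OP
  spikes <- numeric(0)
  for (k in seq_len(n)) {
    if (!is.finite(v) || !is.finite(u))
      stop(sprintf("divergence at step %d (t = %g ms): v = %g, u = %g",
                   k, tt[k], v, u))
    if (v >= vth) {
      # reset replaces this step's update, mirroring the base simulator
      vout[k] <- vth
      spikes <- c(spikes, tt[k])
      v <- cc - mod$dc_OP
      u <- u + d + mod$dd_OP
      next
    }
    vout[k] <- v
    dv <- (0.04 * v * v + 5 * v + 140 - u + I[k] -
             mod$gOP * (v - mod$EOP)) / mod$Cm
    du <- a * (b * v - u) - mod$kOP * u
    v <- v + dt * dv
    u <- u + dt * du
  }
  out <- trace(vout, dt, t0 = 0)
  attr(out, "spikes") <- spikes
  out
}

#' Two-pole low-pass transfer function parameters
#'
#' The complex's filtering action is modelled in the frequency domain as
#' a gain `K_OP` behind two cascaded first-order low-pass poles with
#' time constants `tau_OP` (introduced by the complex) and `tau_m`
#' (the membrane time constant).
#'
#' @param tau_OP,tau_m time constants in ms (>= 0; 0 disables a pole).
#' @param K_OP dimensionless gain.
#' @return A `transfer_params` list.
#' @export
transfer_params <- function(tau_OP, K_OP, tau_m) {
  if (tau_OP < 0 || tau_m < 0) stop("time constants must be >= 0")
  structure(list(tau_OP = tau_OP, K_OP = K_OP, tau_m = tau_m),
            class = "transfer_params")
}

#' Analytic magnitude of the transfer function
#'
#' \deqn{|H(\omega)| = \frac{|K_{OP}|}{\sqrt{1+(\omega\tau_{OP})^2}\,
#'   \sqrt{1+(\omega\tau_m)^2}}}
#'
#' @param params a [transfer_params()].
#' @param omega angular frequency in rad/ms (vectorised, >= 0).
#' @return Non-negative magnitude(s).
#' @export
transfer_magnitude <- function(params, omega) {
  stopifnot(inherits(params, "transfer_params"), all(omega >= 0))
  abs(params$K_OP) / (sqrt(1 + (omega * params$tau_OP)^2) *
                        sqrt(1 + (omega * params$tau_m)^2))
}

# one exact first-order exponential-smoothing stage, pole exp(-dt/tau),
# unit DC gain; initialised at the first sample so constants pass through
lp1 <- function(x, tau, dt) {
  if (tau <= 0) return(x)
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1]))
}

#' Apply the discrete transfer filter to a trace
#'
#' Realises the two-pole low-pass as two cascaded exact first-order
#' exponential-smoothing stages (pole `exp(-dt/tau)` each,
#' unconditionally stable) followed by the gain `K_OP`. Time base is
#' preserved.
#'
#' @param trace a [trace()] with at least 8 samples.
#' @param params a [transfer_params()].
#' @return The filtered [trace()].
#' @export
apply_transfer <- function(trace, params) {
  stopifnot(inherits(trace, "trace"), inherits(params, "transfer_params"))
  if (length(trace$values) < 8L) stop("trace too short to filter (need >= 8)")
  y <- lp1(trace$values, params$tau_OP, trace$dt)
  y <- lp1(y, params$tau_m, trace$dt)
  trace(params$K_OP * y, trace$dt, trace$t0)
}

#' Binding-reaction parameters
#'
#' Mass-action binding of omeprazole (O) to proteinoid sites (P),
#' P + O <-> PO, with on/off rates and total concentrations, plus the
#' linear coefficient `alpha_E` by which bound complex perturbs the
#' local field proxy about baseline `E0`.
#'
#' @param kon association rate (per concentration per ms, >= 0).
#' @param koff dissociation rate (per ms, >= 0).
#' @param P_tot,O_tot total site / ligand concentrations (>= 0).
#' @param alpha_E field perturbation per unit bound complex (mV).
#' @param E0 baseline field proxy (mV).
#' @return A `binding_params` list.
#' @export
binding_params <- function(kon, koff, P_tot, O_tot, alpha_E = 0, E0 = 0) {
  if (any(c(kon, koff, P_tot, O_tot) < 0))
    stop("rates and totals must be >= 0")
  structure(list(kon = kon, koff = koff, P_tot = P_tot, O_tot = O_tot,
                 alpha_E = alpha_E, E0 = E0),
            class = "binding_params")
}

#' Equilibrium bound-complex concentration
#'
#' Solves the mass-action equilibrium
#' `kon (P_tot - PO)(O_tot - PO) = koff PO` for the physical root,
#' i.e. the smaller root of the quadratic with `Kd = koff/kon`;
#' `koff = 0` gives complete binding `min(P_tot, O_tot)`.
#'
#' @param params a [binding_params()].
#' @return Equilibrium `[PO]`, within `[0, min(P_tot, O_tot)]`.
#' @export
binding_equilibrium <- function(params) {
  stopifnot(inherits(params, "binding_params"))
  P <- params$P_tot; O <- params$O_tot
  if (params$kon == 0 && params$koff == 0)
    stop("kon = koff = 0: equilibrium undefined")
  if (params$kon == 0) return(0)       # no association
  if (O == 0 || P == 0) return(0)
  if (params$koff == 0) return(min(P, O))
  Kd <- params$koff / params$kon
  s <- P + O + Kd
  po <- (s - sqrt(s * s - 4 * P * O)) / 2
  min(max(po, 0), min(P, O))
}

#' Field perturbation from bound complex
#'
#' Linear closure `E = E0 + alpha_E * [PO]` for the local-field change
#' induced by omeprazole binding (the functional form of the
#' perturbation is not constrained further; linearity is the simplest
#' monotone coupling and is flagged as an assumption).
#'
#' @param params a [binding_params()].
#' @param bound bound-complex concentration (>= 0).
#' @return Field proxy in mV.
#' @export
field_perturbation <- function(params, bound) {
  stopifnot(inherits(params, "binding_params"), all(bound >= 0))
  params$E0 + params$alpha_E * bound
}

#' Boltzmann gating parameters
#'
#' @param z gating charge (dimensionless; sign sets the direction of
#'   voltage dependence).
#' @param V_half half-activation voltage (mV).
#' @param thermal_voltage kT/e in mV (default 25.7 at 298 K), so all
#'   gating arithmetic stays in mV.
#' @return A `gating_params` list.
#' @export
gating_params <- function(z, V_half, thermal_voltage = 25.7) {
  if (thermal_voltage <= 0) stop("thermal_voltage must be > 0")
  structure(list(z = z, V_half = V_half, thermal_voltage = thermal_voltage),
            class = "gating_params")
}

#' Channel open probability (Boltzmann)
#'
#' \deqn{P_{open}(V) = \frac{1}{1 + e^{-z (V - V_{1/2}) / (kT/e)}}}
#'
#' @param V membrane potential in mV (vectorised).
#' @param params a [gating_params()].
#' @return Probability in (0, 1).
#' @export
popen <- function(V, params) {
  stopifnot(inherits(params, "gating_params"))
  stats::plogis(params$z * (V - params$V_half) / params$thermal_voltage)
}

#' Simplified membrane equation parameters
#'
#' Minimal decomposition of the ionic currents: a passive leak plus one
#' Boltzmann-gated current,
#' \deqn{C_m dV/dt = -g_{leak}(V-E_{leak})
#'   - g_{gate} P_{open}(V) (V-E_{gate}) + I_{ext}.}
#'
#' @param Cm_mem membrane capacitance (> 0).
#' @param g_leak,E_leak leak conductance (>= 0) and reversal (mV).
#' @param g_gate,E_gate gated conductance (>= 0) and reversal (mV).
#' @param gating a [gating_params()].
#' @param I_ext a [drive_spec()] for the external current (default none).
#' @param V0 initial potential (mV, default `E_leak`).
#' @return A `membrane_params` list.
#' @export
membrane_params <- function(Cm_mem, g_leak, E_leak, g_gate = 0, E_gate = 0,
                            gating = gating_params(2, -20),
                            I_ext = drive_spec("step", amplitude = 0),
                            V0 = E_leak) {
  if (Cm_mem <= 0) stop("Cm_mem must be > 0")
  if (g_leak < 0 || g_gate < 0) stop("conductances must be >= 0")
  stopifnot(inherits(gating, "gating_params"), inherits(I_ext, "drive_spec"))
  structure(list(Cm_mem = Cm_mem, g_leak = g_leak, E_leak = E_leak,
                 g_gate = g_gate, E_gate = E_gate, gating = gating,
                 I_ext = I_ext, V0 = V0),
            class = "membrane_params")
}

#' Simulate the simplified membrane equation
#'
#' Forward-Euler integration of the leak + gated-current membrane model.
#'
#' @param params a [membrane_params()].
#' @param duration run length (ms).
#' @param dt step (ms).
#' @return A [trace()] starting at t = 0.
#' @export
simulate_membrane <- function(params, duration, dt) {
  stopifnot(inherits(params, "membrane_params"))
  if (!(duration > dt && dt > 0)) stop("need duration > dt > 0")
  n <- floor(duration / dt) + 1L
  tt <- (seq_len(n) - 1) * dt
  I <- drive_current(params$I_ext, tt)
  V <- numeric(n)
  v <- params$V0
  for (k in seq_len(n)) {
    V[k] <- v
    if (!is.finite(v))
      stop(sprintf("divergence at step %d (t = %g ms): V = %g", k, tt[k], v))
    dv <- (-params$g_leak * (v - params$E_leak) -
             params$g_gate * popen(v, params$gating) * (v - params$E_gate) +
             I[k]) / params$Cm_mem
    v <- v + dt * dv
  }
  trace(V, dt, 0)
}

#' Reaction-diffusion medium parameters
#'
#' One-dimensional excitable medium
#' \deqn{\partial V/\partial t = D \nabla^2 V + f(V)}
#' integrated by explicit finite differences with no-flux (mirror)
#' boundaries. The reaction term is pluggable; the default is the cubic
#' excitable nonlinearity `k V (1 - V)(V - a)` (a = 0.1, k = 1), which
#' supports propagating activation fronts without further assumptions.
#'
#' @param D diffusion coefficient (space^2 / ms, >= 0).
#' @param dx spatial step (> 0).
#' @param dt time step in ms (> 0); the explicit stability bound
#'   `D * dt / dx^2 <= 1/2` is enforced at simulation time.
#' @param n_nodes number of spatial nodes (>= 3).
#' @param reaction function `f(V)` returning the reaction rate,
#'   vectorised over nodes; `NULL` means no reaction.
#' @param init initial field (mV), recycled to `n_nodes`.
#' @return An `rd_params` list.
#' @export
rd_params <- function(D, dx, dt, n_nodes,
                      reaction = function(V) V * (1 - V) * (V - 0.1),
                      init = 0) {
  if (D < 0) stop("D must be >= 0")
  if (dx <= 0 || dt <= 0) stop("dx and dt must be > 0")
  if (n_nodes < 3) stop("need n_nodes >= 3")
  if (!is.null(reaction) && !is.function(reaction))
    stop("reaction must be a function or NULL")
  structure(list(D = D, dx = dx, dt = dt, n_nodes = as.integer(n_nodes),
                 reaction = reaction,
                 init = rep_len(as.numeric(init), n_nodes)),
            class = "rd_params")
}

#' Simulate the reaction-diffusion medium
#'
#' Explicit (FTCS) integration with no-flux boundaries. With zero
#' reaction the discrete Laplacian conserves the nodal sum exactly.
#'
#' @param params an [rd_params()].
#' @param duration run length (ms).
#' @return Matrix `n_nodes x n_steps` (columns are time points,
#'   including the initial condition), in mV, with attributes `dt`, `dx`.
#' @export
simulate_rd <- function(params, duration) {
  stopifnot(inherits(params, "rd_params"))
  r <- params$D * params$dt / params$dx^2
  if (r > 0.5 + 1e-12)
    stop(sprintf("explicit stability violated: D*dt/dx^2 = %.4g > 1/2", r))
  n_steps <- floor(duration / params$dt) + 1L
  V <- params$init
  out <- matrix(NA_real_, params$n_nodes, n_steps)
  out[, 1] <- V
  f <- params$reaction
  for (k in seq_len(n_steps - 1L)) {
    # zero-gradient ghost nodes -> no flux; nodal sum telescopes to zero
    lap <- c(V[2] - V[1],
             V[seq_len(params$n_nodes - 2L) + 2L] -
               2 * V[seq_len(params$n_nodes - 2L) + 1L] +
               V[seq_len(params$n_nodes - 2L)],
             V[params$n_nodes - 1L] - V[params$n_nodes])
    V <- V + r * lap + if (is.null(f)) 0 else params$dt * f(V)
    if (!all(is.finite(V)))
      stop(sprintf("divergence at step %d (t = %g ms)", k, k * params$dt))
    out[, k + 1L] <- V
  }
  attr(out, "dt") <- params$dt
  attr(out, "dx") <- params$dx
  out
}
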