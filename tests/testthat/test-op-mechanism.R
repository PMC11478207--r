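test_that("zero modulation reduces to the base neuron across presets", {
  m0 <- op_mod_params()
  for (mode in c("accommodation", "chattering", "induced", "phasic", "tonic")) {
    mp <- make_mode_preset(mode)
    base <- simulate_izhikevich(mp$params, mp$drive, mp$duration)
    mod <- simulate_op_neuron(mp$params, m0, mp$drive, mp$duration)
    expect_lt(max(abs(base$values - mod$values)), 1e-9)
  }
})

test_that("modulation terms act in the expected directions", {
  mp <- make_mode_preset("tonic")
  # a raised threshold bounds the trace at the new level and thins the
  # spike train (the quadratic escape still reaches any finite
  # threshold, so firing cannot stop entirely)
  hi <- op_mod_params(dV_OP = 1000)
  tr <- simulate_op_neuron(mp$params, hi, mp$drive, 500)
  base500 <- simulate_izhikevich(mp$params, mp$drive, 500)
  expect_lt(length(attr(tr, "spikes")), length(attr(base500, "spikes")))
  expect_lte(max(tr$values), 1030)
  # an inhibitory shunt toward rest cannot raise the spike count
  base <- simulate_izhikevich(mp$params, mp$drive, 1000)
  shunt <- simulate_op_neuron(mp$params, op_mod_params(gOP = 5, EOP = -65),
                              mp$drive, 1000)
  expect_lte(length(attr(shunt, "spikes")), length(attr(base, "spikes")))
  # reset shifts land where the piecewise rule says
  sh <- op_mod_params(dc_OP = 3, dV_OP = 2)
  tr2 <- simulate_op_neuron(mp$params, sh, mp$drive, 500)
  clipped <- which(tr2$values == mp$params$v_peak + 2)
  expect_gt(length(clipped), 0)
  after <- clipped + 1L
  after <- after[after <= length(tr2$values)]
  expect_true(all(tr2$values[after] == mp$params$c - 3))
})

test_that("transfer magnitude matches its closed form", {
  tp <- transfer_params(tau_OP = 10, K_OP = 3, tau_m = 0)
  expect_equal(transfer_magnitude(tp, 0), 3)                 # DC gain
  expect_equal(transfer_magnitude(tp, 1 / 10), 3 / sqrt(2))  # half-power
  t0 <- transfer_params(0, -2, 0)
  expect_equal(transfer_magnitude(t0, c(0, 1, 100)), rep(2, 3))
})

test_that("discrete filter tracks the analytic magnitude within 2%", {
  tp <- transfer_params(tau_OP = 10, K_OP = 0.5, tau_m = 4)
  dt <- 0.25
  for (omega in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    n <- max(4000, ceiling(30 * 2 * pi / omega / dt))
    x <- make_sine_trace(omega, dt, n)
    y <- apply_transfer(x, tp)
    # steady-state amplitude from the last third of the trace
    tail_i <- seq(floor(2 * n / 3), n)
    gain <- (max(y$values[tail_i]) - min(y$values[tail_i])) / 2
    expect_equal(gain, transfer_magnitude(tp, omega), tolerance = 0.02)
  }
})

test_that("filter preserves DC, passivity and the K_OP = 0 annihilation", {
  tp <- transfer_params(tau_OP = 7, K_OP = 2.5, tau_m = 3)
  const <- trace(rep(4, 2000), dt = 0.25)
  y <- apply_transfer(const, tp)
  expect_equal(tail(y$values, 1), 2.5 * 4, tolerance = 1e-3)
  # passivity: sinusoid gain never exceeds |K| (2% slack), random draws
  set.seed(42)
  for (k in 1:5) {
    omega <- runif(1, 0.01, 1)
    x <- make_sine_trace(omega, 0.25, 8000)
    y <- apply_transfer(x, tp)
    g <- (max(y$values[4000:8000]) - min(y$values[4000:8000])) / 2
    expect_lte(g, abs(tp$K_OP) * 1.02)
  }
  z <- apply_transfer(const, transfer_params(5, 0, 5))
  expect_true(all(z$values == 0))
})

test_that("binding equilibrium solves mass action within physical bounds", {
  expect_equal(binding_equilibrium(binding_params(1, 1, 1, 0)), 0)
  expect_equal(binding_equilibrium(binding_params(1, 0, 1, 2)), 1)
  # numeric-root oracle for P = O = Kd = 1
  f <- function(po) 1 * (1 - po) * (1 - po) - 1 * po
  root <- uniroot(f, c(0, 1), tol = 1e-12)$root
  expect_equal(binding_equilibrium(binding_params(1, 1, 1, 1)), root,
               tolerance = 1e-9)
  expect_equal(root, (3 - sqrt(5)) / 2, tolerance = 1e-9)
  expect_error(binding_equilibrium(binding_params(0, 0, 1, 1)), "undefined")
  # property: [PO] in [0, min(P, O)] over random draws
  set.seed(7)
  for (k in 1:50) {
    bp <- binding_params(runif(1, 0.01, 10), runif(1, 0.01, 10),
                         runif(1, 0, 5), runif(1, 0, 5))
    po <- binding_equilibrium(bp)
    expect_gte(po, 0)
    expect_lte(po, min(bp$P_tot, bp$O_tot) + 1e-12)
  }
})

test_that("field perturbation is the linear closure", {
  bp <- binding_params(1, 1, 1, 1, alpha_E = 2.5, E0 = -1)
  expect_equal(field_perturbation(bp, 0), -1)
  expect_equal(field_perturbation(binding_params(1, 1, 1, 1, 0, -1), 10), -1)
  expect_equal(field_perturbation(bp, 4) - bp$E0,
               2 * (field_perturbation(bp, 2) - bp$E0))
})

test_that("Boltzmann gating hits its analytic landmarks and is monotone", {
  gp <- gating_params(z = 2, V_half = -20, thermal_voltage = 25.7)
  expect_equal(popen(-20, gp), 0.5)
  expect_equal(popen(-20 + 25.7 * log(3) / 2, gp), 0.75, tolerance = 1e-12)
  expect_lt(abs(popen(-20 + 20 * 25.7 / 2, gp) - 1), 1e-8)
  v <- seq(-120, 80, by = 0.5)
  expect_true(all(diff(popen(v, gp)) > 0))
  gneg <- gating_params(z = -1.5, V_half = 0)
  expect_true(all(diff(popen(v, gneg)) < 0))
})

test_that("membrane model relaxes with the closed-form time constant", {
  # g_gate = 0, start at E_leak: exactly constant
  mp0 <- membrane_params(Cm_mem = 1, g_leak = 0.1, E_leak = -65)
  tr0 <- simulate_membrane(mp0, 100, 0.05)
  expect_true(all(tr0$values == -65))
  # leak-only relaxation half-life within 1% of ln2 * Cm/g
  tau <- 10  # Cm 1, g_leak 0.1
  mp <- membrane_params(1, 0.1, E_leak = -65, V0 = -55)
  tr <- simulate_membrane(mp, 100, dt = tau / 200)
  tt <- trace_times(tr)
  dev <- abs(tr$values - (-65))
  t_half <- tt[which(dev <= 5)[1]]
  expect_equal(t_half, log(2) * tau, tolerance = 0.01)
  # doubling Cm halves the first Euler step at identical state
  d1 <- simulate_membrane(membrane_params(1, 0.1, -65, V0 = -55), 1, 0.5)
  d2 <- simulate_membrane(membrane_params(2, 0.1, -65, V0 = -55), 1, 0.5)
  expect_equal(d1$values[2] - d1$values[1],
               2 * (d2$values[2] - d2$values[1]))
  # gross Euler instability overflows and is reported as divergence
  expect_error(simulate_membrane(membrane_params(1, 1e6, -65, V0 = 0),
                                 400, 1),
               "divergence")
})

test_that("reaction-diffusion conserves, decouples and enforces stability", {
  # zero reaction, no flux: per-step nodal sum conserved
  set.seed(11)
  rp <- rd_params(D = 0.2, dx = 1, dt = 1, n_nodes = 30,
                  reaction = NULL, init = rnorm(30))
  field <- simulate_rd(rp, 100)
  sums <- colSums(field)
  expect_lt(max(abs(sums - sums[1])) / max(1, abs(sums[1])), 1e-10)
  # uniform init stays uniform
  ru <- rd_params(0.3, 1, 1, 10, reaction = NULL, init = 2)
  fu <- simulate_rd(ru, 50)
  expect_true(all(fu == 2))
  # D = 0 decouples into the single-node ODE
  f <- function(V) V * (1 - V) * (V - 0.1)
  rd0 <- rd_params(0, 1, 0.01, 5, reaction = f,
                   init = c(0.05, 0.2, 0.5, 0.9, 0.3))
  fieldd <- simulate_rd(rd0, 5)
  v <- c(0.05, 0.2, 0.5, 0.9, 0.3)
  for (k in seq_len(ncol(fieldd) - 1)) v <- v + 0.01 * f(v)
  expect_equal(fieldd[, ncol(fieldd)], v, tolerance = 1e-12)
  # stability bound is enforced with the bound in the message
  expect_error(simulate_rd(rd_params(1, 1, 1, 10), 10), "1/2")
})
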