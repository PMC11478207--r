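---
title: "Methods: stimulus simulation, modulation models and signal comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus simulation, modulation models and signal comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsignal)
```

This vignette documents the models behind `opsignal`, the numerical
choices made where the underlying science left them open, and — most
importantly for anyone relying on the test suite — exactly what the
synthetic-data validation does and does not establish.

## 1. The stimulus model

The stimulus side is the Izhikevich spiking neuron,

$$\frac{dv}{dt} = 0.04v^2 + 5v + 140 - u + I, \qquad
  \frac{du}{dt} = a(bv - u),$$

with the after-spike rule: when $v \ge v_{peak}$ (30 mV by default)
the emitted sample is clipped at $v_{peak}$ and the state resets to
$(c,\, u + d)$. Integration is forward Euler at `dt = 0.25` ms, the
discretisation this model was published with and the de-facto standard
for it; the reset *replaces* the Euler update on its step, so the
sample following every clipped one is exactly $c$ — a convention worth
fixing precisely because tests rely on it. Units: $v$, $c$ in mV, time
in ms, $I$, $u$ in the model's dimensionless current units; the
simulator performs no conversion between model current units and the
voltage actually applied by a waveform generator, since that scaling
is a property of the instrument, not the model.

Two numerical consequences worth knowing:

- At $b = 0.2$, $I = 0$, $(v, u) = (-70, -14)$ both derivatives are
  exactly zero in floating point, so the trace is exactly constant —
  the suite uses this as a bit-level integrator check.
- The quadratic term gives finite-time escape: once $v$ clears the
  nullcline no finite threshold can prevent a reset. Raising the spike
  threshold therefore *thins* firing but cannot abolish it; a claim of
  "zero spikes at a high threshold" is not attainable in this model
  and the tests assert the true (thinning) behaviour instead.

### Firing-regime presets

The five stimulation regimes are shipped as data
(`make_mode_preset()`), using the canonical reference
parameterisations, since the study of the recordings prints none:

| mode | a | b | c | d | drive |
|---|---|---|---|---|---|
| accommodation | 0.02 | 1 | −55 | 4 | ramp 1/25 per ms, off at 200 ms; $u_0 = -16$ |
| chattering | 0.02 | 0.2 | −50 | 2 | step 10 from 10 ms |
| induced | 0.03 | 0.25 | −60 | 4 | −15 pulse, 20–25 ms |
| phasic | 0.02 | 0.25 | −65 | 6 | step 0.5 from 20 ms |
| tonic | 0.02 | 0.2 | −65 | 6 | step 14 from 10 ms |

Assumptions made here, explicitly: "induced"/"triggered" spiking is
interpreted as the rebound-spike configuration (a spike elicited after
a brief hyperpolarising pulse), the more common reading; and the
accommodation preset integrates the *same* two equations as every
other mode. The textbook accommodation demonstration instead rewrites
the recovery equation around a shifted voltage origin; reproducing
that would change the model mid-pipeline, so here accommodation means
"the canonical accommodation parameter set under the fixed model",
which fires adaptively under its ramp. `DriveSpec` carries an optional
`t_off` so the ramp protocol can be expressed as pure preset data.

## 2. The modulation models

The omeprazole–proteinoid complex is modelled as modifying the neuron
three ways (`simulate_op_neuron()`): an added conductance and
capacitance rescale,
$C_m \dot v = 0.04v^2 + 5v + 140 - u + I - g_{OP}(v - E_{OP})$;
recovery attenuation, $\dot u = a(bv - u) - k_{OP}u$; and shifted
threshold/reset, firing at $30 + \Delta V_{OP}$ into
$(c - \Delta c_{OP},\, u + d + \Delta d_{OP})$, with the sub-threshold
equations running unchanged otherwise. Setting every modulation term
to zero (with $C_m = 1$) reproduces the base simulator sample for
sample below $10^{-9}$ mV — the suite's reduction identity.

The frequency-domain filtering action is
$$|H_{OP}(\omega)| = \frac{|K_{OP}|}
  {\sqrt{1 + (\omega\tau_{OP})^2}\sqrt{1 + (\omega\tau_m)^2}},$$
realised in discrete time (`apply_transfer()`) as two cascaded exact
first-order exponential-smoothing stages, each with pole
$e^{-dt/\tau}$ and unit DC gain, followed by the gain $K_{OP}$. The
two poles are treated as a cascade (the product form above) rather
than a fitted empirical response — no parameter values exist to fit.
This realisation is unconditionally stable for any $\tau \ge 0$,
passes constants through at exactly $K_{OP}$ (stages initialise at the
first sample), and matches the analytic magnitude within 2 % for
$\omega\,dt \lesssim 0.25$, which the acceptance suite checks over a
frequency grid. Being causal, it delays: its group delay is
$\approx \tau_{OP} + \tau_m$ at DC, which matters for the synthetic
presets below.

The spike-generation mechanism toys are deliberately minimal closures
of pieces whose functional forms are not otherwise constrained:

- **Binding** (`binding_equilibrium()`): mass action
  $P + O \rightleftharpoons PO$ solved at equilibrium via the stable
  root of $k_{on}(P_{tot}-x)(O_{tot}-x) = k_{off}x$; the physical root
  is clamped into $[0, \min(P_{tot}, O_{tot})]$.
- **Field perturbation** (`field_perturbation()`):
  $E = E_0 + \alpha_E \cdot [PO]$ — the simplest monotone coupling,
  flagged as an assumption; $\alpha_E$ is user-set.
- **Gating** (`popen()`): Boltzmann,
  $1/(1 + e^{-z(V - V_{1/2})/V_T})$ with the thermal voltage
  $V_T = kT/e$ expressed in mV (25.7 at 298 K) so all gating
  arithmetic stays in one unit system.
- **Membrane** (`simulate_membrane()`): the ionic-current sum is
  decomposed as leak plus one Boltzmann-gated current — the minimal
  model consistent with a gating narrative. Leak-only relaxation gives
  the closed-form half-life $\ln 2 \cdot C_m/g_{leak}$ used as its
  oracle.
- **Propagation** (`simulate_rd()`): 1-D
  $\partial_t V = D\nabla^2 V + f(V)$, explicit FTCS with
  zero-gradient ghost nodes (no flux), the stability bound
  $D\,dt/dx^2 \le 1/2$ enforced with an informative error. $f$ is
  pluggable; the default cubic $V(1-V)(V-0.1)$ is the standard
  excitable nonlinearity supporting front propagation. With zero
  reaction the discrete no-flux Laplacian telescopes, so the nodal sum
  is conserved to rounding — a sharp correctness probe.

## 3. The comparison engine

`compare()` aligns two traces (equal `dt` required; commensurate grids
truncated to their overlapping window — the alignment rule is a
package decision, stated here because recordings rarely document
theirs) and reports:

- mean, sample sd ($n-1$), min, max of both traces, and
  $\Delta\bar V = \bar V_{in} - \bar V_{out}$;
- signed CV $= \sigma/\mu \times 100$ on the **raw** values (a
  session's printed CV is consistent with raw mean and sd, not with a
  normalised signal), erroring when $|\mu|$ is within $10^{-12}$ of
  zero relative to $\sigma$;
- SNR $= 20\log_{10}(\mathrm{RMS_{signal}}/\mathrm{RMS_{noise}})$.
  No recording documents its noise estimate, so the default estimator
  is visible and parameterised: noise = residual of a centred moving
  average (default window 51 samples, shrinking at the edges), with an
  explicit-noise-trace override;
- Pearson $r$, RMSE, and the maximum absolute difference with the
  time of its first occurrence (ties to the earliest);
- the cross-correlation lag, and the two-sample KS test.

### The lag estimator

Both series are demeaned and the lag
$\tau^* = \arg\max_\tau \hat c(\tau)$ is searched over
$[-\mathrm{max\_lag}, +\mathrm{max\_lag}]$ (default half the span),
with the sign convention that $\tau^* < 0$ means **the output leads
the input**. Ties break to the smallest $|\tau|$, then the negative
one. The sums are computed by zero-padded FFT and verified against a
brute-force loop in the tests.

One design choice deserves its own paragraph. $\hat c(\tau)$ is
normalised by the **overlap count** $n - |\tau|$ (the "unbiased"
estimator), not by $n$ (the "biased" one), and the reason is
identifiability, not variance folklore. The stimuli here are spike
trains, often nearly periodic; for a periodic input, every lag one
period apart from the truth is a near-perfect alias, and the biased
estimator's implicit $\propto (n - |\tau|)$ taper then *systematically*
selects the alias nearest zero whenever the true lag is large — in
testing, a −1231 ms injected lead on a tonic stimulus was aliased to a
few samples. The overlap normalisation removes that taper, and the
alias is then broken by whatever aperiodicity the data carries. The
classical cost — variance inflation as the overlap shrinks — is
immaterial at the default `max_lag` (overlap never below half the
trace). The estimator's resolution is one sample; sub-sample
interpolation is deliberately not attempted.

A related reporting note: lead/lag figures are meaningful only in ms
given the trace's `dt`, and reports carry both `lag_ms` and
`lag_samples`, because published summaries of such experiments have
mixed the two units.

### The KS test

$D = \sup_x |F_1(x) - F_2(x)|$ is computed exactly over the pooled
sample points (sorted-rank counting, so it is exact and $O(n\log n)$),
and the p-value uses the asymptotic Kolmogorov series at effective
size $n_1 n_2/(n_1+n_2)$, truncated at 100 terms (truncation error
$< 10^{-8}$ for $n \ge 10$); $H$ is the rejection indicator at
$\alpha = 0.05$. The suite checks $D$ against brute-force ECDF
enumeration on 200 random pairs and against the reference
implementation in `stats` — which is used only as a cross-check, never
as the implementation.

Q-Q pairs use the shared probability grid `seq(0, 1, length.out = n_q)`
with the linear-interpolation quantile rule (R type 7), stated because
Q-Q conventions differ: with `n_q` equal to the common sample length
the pairs are exactly the two sorted samples.

## 4. The synthetic world

`generate_response()` emulates a recorded proteinoid response with
known ground truth:

$$y = \mathrm{gain}\cdot\mathrm{lowpass}\big(\mathrm{shift}(x - \bar x,\ \mathrm{lag})\big) + \mathrm{offset} + \varepsilon,
\qquad \varepsilon \sim N(0, \mathrm{noise\_sd}^2).$$

The gain compresses the stimulus's *fluctuations about its mean*, so
the output baseline equals `offset` regardless of the stimulus's own
(strongly negative) baseline — this is what the recordings show: a
small positive output mean under a −40 to −60 mV input mean. The lag
is an integer-sample shift (wrap or hold edges; wrap keeps the
demeaned signal at exactly zero mean, making recovery targets exact),
and the noise is white Gaussian, seeded, with the caller's RNG state
restored afterwards.

Per-mode presets copy their lead/lag and offset from the recorded
sessions' summary characteristics (accommodation −306 ms / 0.60 mV,
chattering −1981 / 0.48, induced +1590 / 0.34, phasic −359 / 0.54,
tonic −1231 / 0.80), set gain to the recorded output-to-input sd ratio
(0.023–0.040), and use `noise_sd` = 0.2 mV, placing the output sd in
the recorded 0.3–0.6 mV range. Presets deliberately set
`lowpass_tau = 0`: a causal low-pass adds its group delay on top of
the injected lag, which would make "recover the injected lag to one
sample" false by construction; smoothing remains available as a
generator option for users emulating the recordings' waveforms more
closely.

`scenario()` assembles a session: the mode's waveform is played as
**repeated stimulation sweeps** separated by rest gaps jittered
uniformly on 50–250 ms (seeded). The jitter is not decoration — it is
what makes the ground truth identifiable. A single continuous run
fails two ways: phasic/induced modes produce exactly one spike in the
whole record, and when the output *leads*, that lone landmark's
counterpart falls outside any linear correlation window; tonic and
chattering runs are exactly periodic, so the true lag is
indistinguishable from aliases one period away. An aperiodic
sweep-onset process — the jittered inter-trial interval of classical
latency estimation — solves both, and stands in for the drift and
trial-to-trial variability that makes real recordings aperiodic.

**What a green suite establishes, and what it does not.** The recovery
tests establish that the pipeline is *self-consistent*: the estimator
inverts the generator across all five modes, 20 seeds each, to one
sample in lag and three standard errors in baseline. They do not
establish anything about real proteinoid recordings: the generator is
linear, its noise white and Gaussian, its lag a pure shift, whereas
real responses are nonstationary, their noise coloured, their
"anticipation" possibly an artefact of windowing — the generator can
produce either reading by construction and makes no claim. Metrics on
recorded sessions additionally depend on conventions (SNR noise
estimator, alignment rule) that recordings leave unspecified; where
those conventions matter, this package's choices are the ones stated
above, and reproductions of published summary numbers from deposited
raw data should be expected to agree only up to those conventions. The
worked desk checks the suite does assert — the mean-difference
(−48.17 mV) and SNR-gain (0.5 dB) arithmetic, and the CV implied by a
session's printed mean and sd (−32.16 against a published −32.17
computed from unrounded data) — are arithmetic identities on printed
summary values, not reproductions of the recordings.

## 5. Degenerate inputs and edge policies

- Traces require ≥ 2 finite samples and uniform `dt` (the CSV reader
  enforces monotone time and ≤ 1 % interval deviation from the median,
  converting a seconds dialect to ms on read; `t0` may be negative for
  stimulus-aligned records).
- Zero-variance traces: correlation errors; CV errors on a ~0 mean;
  SNR errors on zero noise RMS; the KS test handles constants (D = 0
  or 1).
- `max_lag` must be smaller than the trace span; `compare()` defaults
  it to half the overlap.
- The synthetic generator rejects |lag| beyond half the input span;
  integer-sample rounding of the lag is by design (recovery targets
  stay exact).
- Simulators check state finiteness every step and report the step
  and state on divergence; the membrane and RD models are the ones
  that can genuinely diverge (Euler instability), and the RD stability
  bound is checked up front.

## 6. Known limitations

- Forward Euler throughout: adequate for the published discretisation
  and the tested `dt`, not for stiff exploration far outside it
  (halving `dt` moves preset spike counts by at most one, which the
  suite checks).
- The lag estimator reports one global lag; time-varying delays are
  out of scope.
- Mechanism parameters ($g_{OP}$, $k_{OP}$, $\tau_{OP}$, …) are not
  fitted to any recording — the models exist to be exercised, and no
  published parameter values exist to fit against.
- 1-D reaction–diffusion only; no network topology is extracted from
  imaging.
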