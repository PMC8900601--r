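---
title: "Methods: gamma oscillations and self-feedback in the Wilson-Cowan model"
author: "wcgamma maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma oscillations and self-feedback in the Wilson-Cowan model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`wcgamma` studies the two-population Wilson-Cowan firing-rate model with
excitatory ($E$) and inhibitory ($I$) self-feedback loops:

$$\tau_E \dot r_E = -r_E + G_E(W_{EE} r_E - W_{EI} r_I + i_E), \qquad
  \tau_I \dot r_I = -r_I + G_I(W_{IE} r_E - W_{II} r_I + i_I),$$

with the shifted logistic response
$G(x) = \big(1 + e^{-m(x-\theta)}\big)^{-1} - \big(1 + e^{m\theta}\big)^{-1}$,
so that $G(0) = 0$: a silent population stays silent at zero net input. The
default parameter set (`wc_params()`) is the standard gamma-band operating
point of this model: $i_E = 2$, $i_I = 7$, $W_{IE} = 20$, $W_{EI} = 26$,
$\tau_E = 20$ ms, $\tau_I = 10$ ms, $m_{E,I} = 1$, $\theta_E = 5$,
$\theta_I = 20$, $W_{EE} = 16$, $W_{II} = 1$. Internally the time
constants are stored in **seconds** so that simulated time is in seconds
and the FFT axis is directly in Hz.

Because of the shift in $G$, firing rates can become slightly negative
(bounded below by $-1/(1+e^{m\theta})$, about $-0.0067$ for the E
population). Whether such values are physiologically meaningful is not
settled; the package allows them and documents the bound rather than
clipping. Similarly, negative weights and inputs are a purely mathematical
device (some bifurcation curves only close through negative parameter
values); the `biological_mode` flag on `wc_params()` rejects them by
default and the curve tracer disables the flag internally, reporting
whatever the mathematics produces.

## Simulation protocol

Trajectories are integrated with classical fixed-step 4th-order
Runge-Kutta at $dt = 1$ ms from a zero initial condition — the protocol
under which this model's gamma activity is conventionally studied. The
integrator is compiled (Rcpp) for the model field and duplicated in pure R
(`rk4_path()`) for the fixture systems; the two paths are cross-checked
against each other and against the damped-oscillator closed form in the
test suite. No adaptive or stiff solver is used on purpose: the protocol
*is* fixed-step RK4.

Defaults the protocol does not pin down were chosen once and declared:
duration 4 s and a 50% transient discard, which leaves $\ge 60$ gamma
cycles for analysis; an oscillation-amplitude threshold of $10^{-4}$
(peak-to-peak of $r_E$); and a single retry at 16 s when the amplitude
trend has not stabilized, because critical slowing down near a Hopf point
makes 4 s runs inconclusive there.

`detect_oscillation()` calls a trajectory oscillating only when the
retained amplitude clears the threshold *and* successive cycle amplitudes
are non-decaying (last/first cycle ratio > 0.9). The second clause
prevents a slowly dying spiral into a stable focus from being counted as
a rhythm.

## Spectral analysis

`power_spectrum()` removes the mean of the retained segment, applies a
Hann window (no window is prescribed by the protocol; Hann suppresses
leakage for the near-sinusoidal cycles this model produces), and returns
an energy-preserving one-sided periodogram (a Parseval identity is
asserted in the tests). The dominant frequency is the non-DC peak refined
by parabolic interpolation of log-power over the three bins around the
maximum, since 1 Hz bins are coarse against the smooth frequency trends
of interest. An independent cycle-counting (zero-crossing) estimator in
the test suite must agree with the spectral peak to within the frequency
resolution.

## Bifurcation analysis

The system is planar, so the package deliberately uses planar-specific
criteria rather than a general continuation code: an equilibrium
undergoes a Hopf bifurcation where the Jacobian trace crosses zero with
positive determinant, and the emergent angular frequency is
$\omega = \sqrt{\det J}$.

* **Equilibria** are found by multi-start damped Newton iteration
  (starts: $(0,0)$, $(0.5,0.5)$, and seeded uniform draws over
  $[-0.1, 1.1]^2$, where firing rates live), accepted at a vector-field
  norm below $10^{-10}$ and merged within $10^{-6}$. With several
  equilibria present (a saddle-node structure exists near the
  Bogdanov-Takens point) continuation always tracks the branch
  warm-started from the previous solution; a cold start takes the
  equilibrium nearest $(0.5, 0.5)$. The explicit rule keeps results
  reproducible. Eigenvalues with $|\mathrm{Re}\,\lambda| < 10^{-7}$ are
  labelled non-hyperbolic instead of being forced into a stability class.
* **One-parameter analysis** (`continue_branch()`) marches the
  equilibrium along a grid, refines trace zeros by bisection to
  $|\mathrm{tr}| < 10^{-8}$, and sweeps the attractor by simulation with
  state carry-over in both directions to expose hysteresis. Folds of
  equilibria are detected both as determinant sign changes and as branch
  terminations (the warm-started Newton jumping to a different
  equilibrium) and are refined by bisection on branch continuity.
* **Criticality** comes from the first Lyapunov coefficient, evaluated by
  transforming the system to the eigenbasis at the Hopf equilibrium and
  applying the standard planar formula to the second- and third-order
  partial derivatives of the field. For this model those derivatives are
  closed-form expressions in the logistic function, so the sign of the
  coefficient — the meaningful part — is robust; its magnitude depends on
  the eigenbasis normalization and is reported as-is.
* **Two-parameter analysis** (`trace_hopf_curve()`) continues the
  three-equation system (two equilibrium equations plus zero trace) in
  four unknowns by pseudo-arclength continuation (default step 0.05,
  Newton corrector with step halving, both directions from the seed).
  Bogdanov-Takens points (determinant zero on the curve) are refined by a
  full four-equation Newton solve; generalized Hopf points (first
  Lyapunov coefficient zero) by interpolation between curve points. Which
  side of the curve oscillates is not assumed: one probe point on each
  side is simulated and classified.

## The upper oscillation boundary in $W_{EE}$

One genuine subtlety deserves its own section. Sweeping $W_{EE}$ upward
from the default operating point ($W_{II} = 1$), three things happen in
close succession:

1. near $W_{EE} \approx 33.5$ a saddle and a stable high-activity node
   already coexist with the limit cycle;
2. at $W_{EE} \approx 33.7$ the growing cycle touches the saddle and is
   destroyed (a homoclinic-type loss): a simulation sweep with state
   carry-over at 0.25 resolution loses the oscillation at 33.75, and from
   then on every trajectory — including ones started arbitrarily close to
   the unstable focus — escapes to the node;
3. at $W_{EE} \approx 34.88$ the unstable focus and the saddle annihilate
   in a fold of equilibria (the "LP" of a continuation package), after
   which the node is the unique equilibrium: the model is monostable.

The value usually quoted for the oscillation-to-monostable switch, 35, is
the fold (3), not the simulated cycle loss (2). `continue_branch()`
therefore reports both quantities (`fold` and `cycle_loss_up`), the
acceptance script reports the fold for the boundary target while logging
the sweep value, and one acceptance test asserting the *sweep* value
against 35 ± 1 is expected to stay red by 0.25 — kept red deliberately,
because the measurement it prescribes cannot produce the printed number.

## Linear-control view

Linearizing each population about the operating point (the equilibrium,
unless the caller supplies another point) gives a first-order block
$K/(\tau s + 1)$ per population, with $K$ the sigmoid slope at the net
input. Closing the self-feedback loops yields

$$K_I' = \frac{K_I}{1 + W_{II} K_I}, \quad
  \tau_I' = \frac{\tau_I}{1 + W_{II} K_I}; \qquad
  K_E' = \frac{K_E}{1 - W_{EE} K_E}, \quad
  \tau_E' = \frac{\tau_E}{1 - W_{EE} K_E}.$$

Inhibitory self-feedback always *shrinks* the inhibitory gain and time
constant (opposing oscillation onset, raising the frequency); excitatory
self-feedback *grows* both (promoting oscillation, lowering the
frequency) — but only while $W_{EE} K_E < 1$. Beyond that threshold the
linearized loop is unstable and the first-order reduction stops being
meaningful; `closed_loop_excitatory()` reports this as an error rather
than interpreting it, and at the default equilibrium the excitatory
reduction is in fact outside its validity region ($W_{EE} K_E \approx
3.9$), which `linearization_report()` flags. The derivation of the
inhibitory closed loop is implemented as the inhibitory block throughout
(one line of the source derivation mislabels it with an "E" subscript;
the surrounding algebra is unambiguous).

The linear prediction of the oscillation frequency,
$\sqrt{\det J}/(2\pi)$, is exact at a Hopf point and is required by the
tests to stay within 10% of the simulated dominant frequency just inside
the oscillation region.

## Synthetic fixtures: what a green test establishes

The fixture module generates the only "data" in this package; there are
no external recordings, and the fixtures make no attempt to emulate
experimental LFP signals. They exist so every stage has an input with a
closed-form answer:

* sinusoids (with optional seeded Gaussian noise, default sd 0) oracle
  the spectral stage;
* the damped oscillator, with its closed-form solution, oracles the
  integrator and its convergence order;
* the Hopf normal form (with optional quintic saturation) oracles Hopf
  location, onset frequency, criticality sign, the square-root amplitude
  law, and — in the subcritical saturated variant — the fold of cycles
  at $\beta = -1/4$ with its hysteresis window, via the brute-force
  radial-equation solver `radial_cycles()`.

A green suite therefore establishes that the machinery recovers known
answers on systems engineered to have them, and that the model-level
results are internally consistent across independent routes (eigenvalues
vs simulation, spectrum vs cycle counting, curve side vs probe
simulation). It does not establish anything about biological tissue.

## Numerical choices and known limitations

* Tolerances: equilibrium residual $10^{-10}$, deduplication $10^{-6}$,
  Hopf trace $10^{-8}$, non-hyperbolicity $10^{-7}$, degenerate
  $|l_1| < 10^{-10}$. Strictness is cheap in a smooth planar system.
* Near-boundary simulations are the slow path: within $\approx 0.01$ of a
  Hopf point the growth rate is of order $0.1\ \mathrm{s}^{-1}$ and
  onset-agreement tests integrate up to 128 s of model time.
* The pseudo-arclength tracer follows one connected curve per seed; a
  disconnected second Hopf branch needs its own seed. Saddle-node curves
  are not traced (only their intersections with the Hopf curve are
  flagged as BT), and no period-doubling or chaos analysis is attempted.
* Region classification labels cells by the trace/determinant criterion
  on the continued equilibrium, with cells within one arclength step of a
  BT/GH point marked uncertain; in the probed planes it agreed with
  simulation on every tested grid cell, but near-homoclinic regions (see
  the $W_{EE}$ section) are exactly where the linear criterion can
  mislabel.
* Config serialization is JSON (the environment provides no YAML parser);
  keys are the model symbols, `tau_*` in seconds.
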