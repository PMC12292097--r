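---
title: "Modeling GluN1/GluN2A NMDA receptor dynamics: kinetic scheme, calibration, and the LUTsyn surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling GluN1/GluN2A NMDA receptor dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdar)
```

## The model

The package implements a deterministic nine-state Markov model of the
GluN1/GluN2A NMDA receptor. State occupancies `p(t)` evolve by first-order
mass action,

$$\dot p = Q(\mathrm{Glu}(t), \mathrm{Gly}(t))\, p, \qquad
Q = Q_0 + [\mathrm{Glu}]\,Q_{glu} + [\mathrm{Gly}]\,Q_{gly},$$

where `Q` is the generator matrix of the transition graph. Open
probability is the summed occupancy of the two open states, and the
population EPSC follows Ohm's law with a voltage-dependent Mg^2+ block of
the single-channel conductance:

$$I(t) = N\,(V - V_{rev})\, g_0\, B(V)\, O(t), \qquad
B(V) = \frac{1}{1 + ([\mathrm{Mg}]_o / K_0)\, e^{-0.062 V}},$$

with $K_0 = 3.57$ and a logistic interpolation
$g_0 = g_1 + (g_2 - g_1)/(1 + e^{\alpha \Psi_m})$ between the two
open-state conductances. The Mg block acts only on conductance, never on
the state kinetics, so all normalized quantities (normalized EPSC traces,
decay constants, I-V percentages) are independent of $N$, $g_1$, $g_2$,
and $\alpha$. Numeric values for $g_1, g_2, \alpha$ are not constrained by
any quantity this package reports; the defaults (40 pS, 247 pS,
0.01 mV^-1) are configuration placeholders on the scale of reported NMDA-R
subconductances.

### Topology

The activation pathway is the classic sequential scheme: two glutamate
binding steps, three diliganded closed states, two open states,

```
S1 (apo) = S2 (1 Glu) = C3 (2 Glu) = C2 = C1 = O1 = O2 .
```

Two glycine-binding states complete the nine. Where they attach is the
one genuinely open design choice in the scheme, and it matters. We
evaluated every placement of the glycine pair along or off this chain
(front, between binding and gating, before the open states, distal to
them, and branch attachments at each state, under both statistical-factor
conventions) against the behavior the two published rate-constant presets
are known to produce: with sub-saturating (0.02 mM) glycine, the
optimized preset must decay biexponentially with components near 64 and
258 ms, and the original preset must decay with a weighted constant near
86 ms.

Only one family reproduces this pattern: a *glycine-desensitization
branch*, in which glycine can dissociate from the diliganded closed state
C3, leaving the receptor desensitized with glutamate trapped until
glycine rebinds:

```
C3 = D1 (one glycine lost) = D2 (both lost).
```

This is the classic glycine-dependent desensitization structure:
glutamate binding lowers glycine affinity, and recovery requires glycine
rebinding at rate $k_{gly,on}[\mathrm{Gly}]$. At 0.02 mM glycine the
optimized preset's weak glycine binding (1 uM^-1 s^-1) makes trap escape
slow (~20 s^-1), producing a slow decay component above 200 ms, while the
original preset's five-fold faster glycine association keeps its decay
fast — exactly the qualitative difference between the presets. Chain
placements of the glycine states either leave the decay monoexponential
near 50 ms (glycine in front) or produce multi-second tails (glycine
between binding and gating). The package therefore defaults to the
branch topology; `build_scheme(..., topology = "sequential")` selects the
front-chain variant for sensitivity analysis.

With the branch default and no statistical factors, the optimized preset
yields fitted decay components of about 67 and 217 ms and the original
preset a weighted constant of about 75 ms — within 6-16% of the published
fits — while the optimized weighted constant (~85 ms) remains well below
the published 147 ms. We did not find any nine-state wiring of the twelve
tabulated rates, under a brief (~1 ms) cleft-glutamate transient, that
reaches 147 ms; reproducing it appears to require either a different
(unpublished) wiring or a release transient with a slow tail. We chose
not to introduce an ad hoc glutamate tail to close that gap.

### Statistical factors

Identical-binding-site statistics (a factor 2 on the first association
and the second dissociation) are exposed as
`statistical_factors = "paired-sites"`. The default is `"none"`: the
tabulated constants are read as effective per-transition rates, which is
how such tables are typically transcribed into simulation code, and which
matches the published decay constants distinctly better than the doubled
convention.

### Units and integration

Time is in ms, concentrations in uM, rates converted internally to ms^-1
(association constants to uM^-1 ms^-1). Binding at mM glutamate makes the
system stiff (rates span 0.001-50 ms^-1). The simulator cuts the time
axis at stimulus breakpoints: on segments where both ligand
concentrations are constant the linear system is propagated *exactly*
through the eigendecomposition of `Q` (cached per concentration pair,
with an `lsoda` fallback if the eigenbasis is ill-conditioned); on
segments with a time-varying glutamate transient it integrates with
`deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10`. Output is reported on
a uniform grid (0.01 ms for square-pulse protocols, 0.1 ms for synaptic
protocols) regardless of internal stepping. Occupancies are clipped to
[0, 1] only for round-off excursions below 1e-6; larger violations raise
an error rather than being masked.

## Stimuli

* **Square pulse trains** — 1 ms, 1 mM glutamate pulses at 10 or 100 Hz
  against 0.1 mM glycine reproduce the fast-application protocols used to
  constrain peak open probabilities.
* **Synaptic release transients** — each release event steps cleft
  glutamate to 1.1 mM and clears monoexponentially with
  $\tau_c = 1.2$ ms (the classic estimate of the cleft transient after a
  single vesicle); an optional exponential rise is available. The exact
  release/diffusion waveform used in the experiments this emulates is not
  published; both parameters are exposed so users can substitute their
  own.
* **Poisson event trains** — homogeneous Poisson times thinned to a
  minimum spacing equal to the look-up-table granularity (5 ms), so
  quantized intervals are never zero; reproducible given a seed.

The synaptic protocols hold glycine at 0.02 mM (a nominal physiological
level); the square-train protocols use 0.1 mM.

## Calibration loss and PSO

The composite loss balances temporal fidelity and frequency-dependent
potentiation:

$$J(\theta) = \tfrac12\, \mathrm{NRMSE}(i_{syn}, \hat i_{syn}^\theta)
 + 0.1 \sum_{i=1}^{3} \frac{|p_{i,10} - \hat p_{i,10}^\theta|}{p_{i,10}}
 + 0.1 \sum_{i=2}^{3} \frac{|p_{i,100} - \hat p_{i,100}^\theta|}{p_{i,100}},$$

with $\mathrm{NRMSE}(x, y) = \sqrt{\sum_t (x_t - y_t)^2 / \sum_t x_t^2}$.
The first 100 Hz peak duplicates the first 10 Hz peak and is discarded.
Traces are compared after linear resampling onto a common 1 ms grid. A
candidate whose simulation fails contributes an infinite loss and is
culled without aborting the run.

The optimizer is the canonical global-best particle swarm: velocity
update $v \leftarrow \omega v + c_1 r_1 (p_{best} - x) + c_2 r_2
(g_{best} - x)$ with per-dimension uniform $r_1, r_2$, inertia 0.5,
cognitive and social rates 2.1, positions clamped to the box bounds and
velocities to half the bound range. Stopping is a fixed generation count
(reproducible, unlike wall-clock stopping); multi-trial mode restarts
with derived seeds and returns the best trial. Rate-constant searches
initialize log-uniformly because the twelve constants span three decades;
default bounds are 0.1-10 times the original preset.

Since the experimental target values (reference peak open probabilities
and the digitized EPSC trace) are not published, parameter-recovery
experiments use *self-calibration*: targets generated from a known
preset, optionally with multiplicative Gaussian noise. A desk-scale run
(20 particles, 60 generations, bounds 0.2-5x truth) consistently reaches
J < 0.05 (0.02-0.04 across seeds); the recovered model's synaptic-trace
NRMSE against the generating parameters lands at 0.04-0.06, so the
stricter joint requirement (J and trace NRMSE both below 0.05) is met
only in some seeds — at this budget the loss surface admits parameter
sets that reproduce the targets without matching every rate constant.
This desk-scale experiment stands in for the original cluster-scale
optimization (50 trials x 200 particles x 14 h), which is out of scope.

## Decay analysis

`fit_biexponential` fits $A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$ to the
normalized post-peak trace by Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`, multi-start, non-negative bounds), labels
components so $\tau_1 \le \tau_2$, and reports the amplitude-weighted
constant $\tau_w = (A_1\tau_1 + A_2\tau_2)/(A_1 + A_2)$. The fit window
runs from the trace peak to the end of the simulation (1500 ms for the
synaptic protocol — by then the response has decayed to well below 1% of
peak). `fdhm` measures full duration at half maximum with linear
interpolation between samples.

## The LUTsyn surrogate

The surrogate assumes the response to a synaptic event is determined by
the quantized interpulse intervals of the preceding events inside a
memory window M = 1000 ms, at granularity delta = 5 ms, considering at
most the five most recent pulses. Each event is categorized by *order*
(1 + the number of earlier events within M, capped at 5; a silent period
longer than M resets to first order). The look-up table maps (order,
interval tuple) to the teacher kinetic model's absolute peak open
probability after the final pulse of that pattern; the prediction is that
amplitude times the order's normalized basis waveform

$$O_{norm}(t) = F_{norm}\left(w\, e^{-t/T_{c2}} + (1 - w)\, e^{-t/T_{c3}}
 - e^{-t/T_{c1}}\right),$$

with $w = 0.7384$ fixed for all orders and $F_{norm}$ computed by bounded
scalar maximization so the peak is exactly 1 (the coefficients cancel at
$t = 0$, so every basis starts at zero).

Design choices where the original formulation is silent:

* **Overlap rule.** Stored amplitudes are absolute peaks including
  residual occupancy from the pattern history, so overlapping waveforms
  must not double-count the running tail. Two consistent rules exist:
  *supersede* (the newest event's scaled waveform replaces earlier
  tails) and *additive-increment* (each event adds
  `max(amplitude - tail, 0)` times its basis waveform to the running
  sum). Supersede dips toward zero at each event onset because the basis
  starts at 0 while the receptor carries residual occupancy; on dense
  trains this dip dominates the error (10 Hz NRMSE ~0.13 vs ~0.09 for
  the additive rule, which also restores the expected pattern that
  dense-train fidelity is at least as good as sparse-train fidelity).
  The additive-increment rule is therefore the default;
  `lut_predict(..., rule = "supersede")` selects the alternative.
* **Quantization.** Intervals round to the nearest multiple of delta,
  ties upward, minimum delta.
* **Table population.** Exhaustive enumeration of order-5 patterns at
  M = 1000, delta = 5 is combinatorially infeasible (~10^8 tuples), so
  the default mode computes entries on demand and memoizes them;
  exhaustive mode exists for small configurations and refuses tables
  beyond a configurable entry budget.
* **Training means.** Per-event segments (event to next event) are
  unit-normalized and averaged per order. The mean at each time offset is
  taken over the segments that extend that far, cut where fewer than
  three remain. Truncating instead to the shortest segment discards the
  decay phase entirely whenever one instance of an order is followed
  closely by another event, which makes the slow time constants
  unidentifiable. Because first-order events are rare in a 4 Hz train
  (the probability of a 1 s silent gap is $e^{-4} \approx 2\%$),
  `train_basis` pools segments from additional 4 Hz, 40 s trains (drawn
  with consecutive seeds, at most five) until every order's mean covers
  at least 400 ms of decay.
* **Basis fitting.** Per order, PSO (50 particles, 200 generations)
  minimizes NRMSE between mean response and candidate basis plus the
  absolute percent error of their full durations at half maximum, over
  $(T_{c1}, T_{c2}, T_{c3})$ with bounds (0.1-30, 1-400, 20-1500) ms;
  candidates whose unnormalized maximum is non-positive are culled. The
  FDHM term is dropped if the mean segment never re-crosses half maximum.
  Because the fixed weighting factor makes the two decay roles almost
  interchangeable, each candidate is evaluated under both
  $(T_{c2}, T_{c3})$ assignments and the swarm is warm-started from
  moment-matched triplets (peak time and FDHM of the target); both
  measures remove local minima that otherwise trap a minority of runs.

Validation simulates the teacher on held-out 20 s Poisson trains (4 and
10 Hz) and measures NRMSE between teacher and surrogate open-probability
traces on a 0.1 ms grid. Typical desk-scale results are ~0.09-0.12 at
4 Hz and ~0.09 at 10 Hz. What this does and does not show: the
synthetic-data pipeline demonstrates surrogate fidelity against the
kinetic model under Poisson input statistics, but says nothing about
non-Poisson natural spike trains, receptor heterogeneity, or dendritic
voltage dynamics, none of which the generator emulates.

## Problem sizes and runtime

All experiments are desk-scale by design: calibration simulations use
300 ms (10 Hz), 100 ms (100 Hz), and 1000-1500 ms (synaptic) horizons;
PSO recovery uses 20 particles x 60 generations; basis training uses 50
particles x 200 generations per order on pooled 40 s trains; validation
uses five held-out 20 s trains per rate. The piecewise-exact propagator
makes a full calibration-loss evaluation ~0.1 s and a 20 s teacher
simulation ~2 s on one CPU.

## Known limitations

* The nine-state wiring of the published rate table is inferred, not
  printed; the optimized preset's weighted decay constant comes out near
  85 ms rather than the published 147 ms (components and the original
  preset agree within ~16%). See the topology discussion above.
* Glycine binding to the apo receptor is not represented in the default
  topology (receptors rest glycine-loaded in S1); the sequential variant
  represents it but cannot reproduce the published decay structure.
* The surrogate's amplitude table conditions only on the five most
  recent events inside 1 s; slower forms of history dependence
  (desensitization accumulating over many seconds) are outside its
  design.
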