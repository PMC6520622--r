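---
title: "Methods: simulating and analyzing precision-grip lifts of bipartite objects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing precision-grip lifts of bipartite objects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heftr)
```

## Scope and coordinate conventions

`heftr` analyzes two-digit precision-grip lifts of cuboid objects whose
halves may differ in apparent material and in physical mass, recorded by
one six-axis force/torque sensor per digit. Everything runs in one
right-handed frame: x along the object's long side (normal to the grip
surfaces), y along the short side, z vertical; the origin is the
geometric center. Internally all quantities are SI (N, N·m, m, kg, s);
the reporting layer converts torques to N·mm, matching how such data are
usually tabulated. After sign alignment, positive torque about y means a
rotation toward the heavier-*looking* side, so a contrast-type
anticipation (gripping as if the heavy-looking side were heavy when it is
not) shows up as a negative initial torque.

Counterbalanced presentations are handled by a 180° relabeling about z
(`align_to_common_frame()`), which negates the x- and y-components of
forces and moments and the pad offsets. The relabeling is an involution
and preserves per-sample vector norms; both properties are tested.

## Object model

Each half is modeled as a point mass at ±L/4 from the center, equivalent
to a uniform mass distribution within the half. This gives the two exact
conversions used throughout:

* CoM displacement from half masses: `d = (m2 − m1)(L/4)/(m1 + m2)`;
* half-mass difference from a CoM displacement: `Δm = d·M/(L/4)`.

These are exact inverses (round-trip tested to 1e-12 relative). The
sensor handle is modeled as centered at x = 0, so it adds to the lifted
weight but never to the half asymmetry. For the canonical 400-g, 10-cm
object, a 0.8-cm displacement corresponds to a 128-g difference. The
published description of that example gives the displacement as
"0.82 mm", which is dimensionally inconsistent with 128 g under this
model (it would imply ≈13 g); the package documents the discrepancy and
uses the self-consistent 0.8-cm reading rather than silently altering
the formula.

The density catalog defaults to granite 2700, oak 700, styrofoam
50 kg/m³. These are ordinary handbook densities chosen once as plausible
values for the depicted materials — visual expectation magnitudes, not
measured quantities — and are configurable.

## Net torque about the center of mass

The torque is the four-term sum of cross-products about the CoM: each
digit's force acting at its center of pressure, plus the weight of each
half acting at ±L/4. Two implementation details matter:

* **Handle term.** About the *true* assembly CoM the summed gravity
  torque of all parts is identically zero. With equal half masses the
  CoM is the geometric center and the handle term vanishes, reproducing
  the textbook four-term sum exactly; for shifted-CoM objects the
  (centered) handle acquires a lever arm, and the package includes its
  weight term so that static holds close exactly rather than to within a
  few N·mm.
* **CoP route.** The digit term uses the documented center-of-pressure
  inversion `z_c = (M_y + d·F_z)/F_x`, which is numerically unstable
  without firm contact. Below a configurable normal-force floor (0.1 N
  default; the 0.01-N onset threshold is too low to stabilize a
  division) the algebraically identical moment-transport form
  `M_y + x_com·F_z` is used, so the torque series is defined at every
  sample while the CoP validity mask is still reported.

## The synthetic lift generator

No quantitative description of real force trajectories is available to
the generator, so its trace shape is a deliberate, simple stand-in with
exact bookkeeping rather than an empirical model:

* **Loading ramp**: a C² smoothstep over `loading_duration` (default
  0.4 s after a 0.3-s quiet baseline). It is exactly 0 before onset and
  exactly 1 after, which makes ground-truth event indices well defined.
* **Liftoff settle**: a decaying sinusoid (default 8% overshoot, 6 Hz,
  τ = 50 ms) whose envelope is truncated to exactly zero once below
  1e-12 of the weight force. This gives the detector a genuine LF peak
  and a dip below the weight force, and makes the subsequent hold
  satisfy ΣLF = Mg and net τ_y = 0 to better than 1e-9 (tested over 200
  trials).
* **Hold**: 3 s, matching the standard paradigm; sampling 1,000 Hz.
* **Anticipatory torque** is injected by asymmetric load-force sharing
  between the digits — one of the several strategies a lifter could use
  (raising one CoP or one grip force would do too); load-force sharing
  was chosen because it leaves GF and CoP clean for testing their
  extractors. The gravitational imbalance of unequal halves is
  compensated progressively during loading (`correction = "ramp"`) or
  only after liftoff (`"none"`), the latter reproducing the textbook
  24.5 N·mm initial torque for a 100-g imbalance.
* **Noise** is additive white Gaussian per channel (defaults 0; tests
  use up to 0.02 N force and 2e-4 N·m moment SD). White noise is the
  simplest model sufficient to stress the detectors; real sensor noise
  is colored and drifts, which is one reason passing tests here do not
  certify performance on real recordings.
* **Design generation** enforces the block constraint (each object once
  per block of `n_objects`), keeps orientation constant within and
  counterbalanced across participants, and derives every random draw
  hierarchically (participant, trial) from one integer seed, so
  identical seeds give bit-identical sessions.

The rating observer mixes visual expectation and sensed mass,
`Ψ = w·E + (1 − w)·m + ε` with `w ∈ [0, 1]` (pre-lift ratings use
`w = 1`); a contrast-mode observer is repelled from the expectation,
`Ψ = m − w·(E − m) + ε`. The CoM-pointing task reports the balance point
of the two half percepts clipped to [0, L]; whole-object ratings sum the
halves. The default rating noise SD (0.02 kg-equivalent) makes a
49-participant session recover `w` by regression to well within ±0.05.
An optional divisive context-anchoring gain exists but defaults to off:
it reflects a discussion-level speculation about rating-scale anchoring,
not an established procedure.

## Event detection and dependent variables

* **Loading onset**: first sample where GF of ≥1 digit and LF of ≥1
  digit exceed 0.01 N while |τ_y| exceeds 1.5 N·mm (both thresholds
  configurable). On 200 noisy synthetic lifts the detected onset is
  within 5 ms of ground truth in ≥95% of trials (tested).
* **Loading end**: the published rule says "after the initial peak"
  without naming the signal; this package reads it as the first local
  maximum of *total LF* after onset, because liftoff itself is defined
  on LF. If the weight force was reached, the end is the first
  subsequent sample below the weight force; if the object was never
  lifted, the fallback is the first sample below the median total LF
  (median taken from onset onward). The fallback branch is exercised by
  a constructed no-liftoff trace with an analytically known median.
* **First torque extremum**: first strict interior local extremum of the
  50-Hz-filtered τ_y inside the loading window, ties on plateaus broken
  to the first index. A monotone window raises a typed `NoExtremum`
  condition carrying the window-endpoint value; the endpoint is never
  silently substituted, because doing so would bias peak-torque
  distributions toward window edges.
* **Peak force**: the landmark chain (Gaussian smooth σ = 30 ms →
  derivative → first time ≥70% of max derivative → first subsequent
  *derivative* zero-crossing → first local max/min of the smoothed
  signal in that window → max of the *original* signal between them).
  The published wording "the signal became negative" is read as the
  derivative becoming negative: a force that crosses zero is physically
  meaningless there, while the derivative crossing zero is exactly a
  peak. When a landmark is absent (ramp onto a plateau) the window end
  stands in, which returns the plateau level. The procedure can never
  return a value outside the range of the original signal (tested).
* **Peak rates**: maximum of the central-difference derivative of the
  zero-phase-filtered signal at the native rate.
* **Holding torque**: median over the hold window — robust to brief
  spikes by construction (tested against a 50-sample spike).

## Filtering

Torque and rate signals use a fourth-order low-pass Butterworth at 50 Hz
applied forward and backward (zero net phase, DC gain 1). Coefficients
come from `signal::butter`; the forward-backward pass is implemented in
the package so its edge handling is explicit: the signal is extended by
odd reflection (3 × the filter length per end) and each pass starts at
the steady state of its first sample, which removes startup transients —
a constant input is returned unchanged to ~1e-13 and a band-limited
input shows a cross-correlation lag of exactly 0 samples. Attenuation at
4× the cutoff exceeds 99.6% (squared single-pass bound 1/(1+4⁸)).
The Gaussian smoother in the peak procedure truncates its kernel at 4σ
and uses the same reflection padding.

## Statistics

* **z-scores** use the sample SD (n−1) by default — the dominant
  convention; a population-SD option exists since the original
  description does not specify one.
* **ANOVA**: balanced within-subject (optionally one between factor)
  designs are aggregated to participant × cell means and fit through
  `car::Anova` on a multivariate linear model (sum-to-zero contrasts,
  type-III), with Greenhouse-Geisser ε and Mauchly's test extracted from
  the same fit. The correction is applied when Mauchly's p < 0.05
  (`"always"` and `"never"` are available), since "where necessary" was
  published without a criterion; two-level factors have ε = 1 and are
  never altered. F and df agree with a from-scratch sums-of-squares
  oracle to 1e-8, and the default pipeline's type-I error over 2,000
  exchangeable-normal null simulations stays within [0.04, 0.06]
  (both tested).
* **t-tests**: two-sample comparisons default to Welch
  (Welch–Satterthwaite fractional df) — the convention implied by
  published fractional df; everything is two-sided; p-values are floored
  at 1e-16; a zero-variance one-sample case is flagged as an infinite
  statistic rather than an error.
* **Bonferroni**: α/m reported at 4 decimals (0.0167, 0.0083, 0.025 for
  m = 3, 6, 2 at α = 0.05).
* **JZS Bayes factor**: the one-sample BF01 under a zero-centered Cauchy
  prior on effect size (scale r = √2/2, the common tool default; the
  scale used in the original analyses is not recorded, so published BF
  values are not treated as reproduction targets). The g-prior integral
  is evaluated by adaptive quadrature and agrees with an independent
  noncentral-t quadrature oracle to 1e-6 relative (tested).

## The competing-priors observer

Each density hypothesis k (genuine materials; a veneer over a heavier
"covered" core; a hollow light fake) carries a prior π_k and Gaussian
predictive distributions per sensory channel (total mass; half-mass
difference). Posteriors are computed in log space —
`posterior_k ∝ π_k · Π_c N(x_c; μ_kc, √(σ_kc² + σ_c²))` — so extreme
separations renormalize instead of producing NaN; ties break toward the
higher-prior hypothesis for determinism. The percept is the
precision-weighted mean of the winning hypothesis's prediction and the
measurement. With a single hypothesis this reduces exactly to standard
Bayesian shrinkage, which is why a single-prior observer can never
produce a contrast effect: its percept is trapped between expectation
and measurement. Hypothesis *switching* is what buys the contrast — as
the measurement crosses a decision boundary the selected hypothesis
changes and the percept jumps discontinuously (tested).

The shipped `certified_regime()` fixes all numeric parameters: priors
0.70/0.25/0.05, genuine predictive SDs 0.05 kg, covered core
N(0.70, 0.10) kg, hollow core N(0.10, 0.08) kg, and per-regime channel
reliabilities (mass SD 0.02 kg; distribution SD 0.25 kg when the halves
are judged, 0.04 kg when bipartite objects are judged as wholes). The
original account quantifies none of these, and explicitly treats the
relative influence of the two sensory estimates as task-dependent; the
numbers here are regime *choices*, selected by grid search to certify
the qualitative pattern — classic (negative) illusion for uniform-object
mass judgments, inverted (positive) for bipartite distribution
judgments, ≈0 for bipartite whole-object judgments — and frozen. The
module makes qualitative sign predictions only; fitting the observer to
behavioral data is out of scope.

```{r regimes}
predict_all_regimes()
```

## Problem sizes and determinism

The test suite simulates at the paradigm's native scale where that is
cheap (1,000 Hz traces, 3-s holds, 49-participant rating sessions, 100
session replicates, 200-trial physics and detection batteries, 2,000
ANOVA null simulations) and uses fixed seeds throughout; every stochastic
quantity in the package derives hierarchically from a single integer
seed. Trace-level analyses in the pipeline examples use shorter holds or
lower rates only where the test is about bookkeeping rather than signal
content.

## Known limitations

* The generator's trace shape is a stand-in; its realism is untested by
  design, and passing detector tests on it does not certify detector
  performance on real, colored-noise, drifting recordings.
* Slip, friction, object tilt dynamics, and grip-aperture kinematics are
  not modeled; torque bookkeeping is quasi-static.
* The observer module predicts signs, not magnitudes, and its parameters
  are certified choices, not fits.
* Only balanced, complete ANOVA designs are supported; missing cells are
  a typed error rather than an estimation problem.
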