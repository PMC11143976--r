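---
title: "Monitoring neuromuscular fatigue with the countermovement jump: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring neuromuscular fatigue with the countermovement jump: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmjfatigue)
```

## The problem

The countermovement jump (CMJ) is a standard field test of lower-limb
neuromuscular function: the athlete stands still on a force plate, squats
rapidly, and jumps as high as possible with hands on hips. Because maximal
voluntary force production degrades under fatigue, repeated CMJ testing
around a demanding exercise bout (here, the emulated protocol is a maximal
400 m sprint, with sessions at baseline and 3 min, 10 min, 1 h and 24 h
afterwards) can track both the size of the decrement and its recovery
time-course. Summary variables (jump height, peak power) can miss changes in
*how* the jump is performed, so the pipeline also compares whole
time-normalized force and power curves between sessions with
one-dimensional statistical parametric mapping (SPM).

`cmjfatigue` implements the full chain: signal segmentation, variable
extraction, session statistics, curve-level inference — plus a physically
consistent waveform generator so that every stage can be validated against
known ground truth without access to raw laboratory recordings.

## From force to motion

The only measured signal is vertical ground-reaction force \(F(t)\) sampled
uniformly (nominally 1000 Hz). With body mass \(m\) determined from the
quiet-standing weighing window (first 1.0 s by default; the window SD must
stay below 3% of its mean or the trial is rejected as "not still"), Newton's
second law gives the centre-of-mass (COM) net acceleration
\(a(t) = F(t)/m - g\), and cumulative trapezoidal integration from movement
onset yields velocity, displacement, and power per kilogram
\(P = (F/m)\,v\). We use \(g = 9.81\ \mathrm{m/s^2}\); every function
exposes a `gravity` argument.

Landmarks:

* **Onset** — first sample at which \(|F - BW|\) exceeds 5 quiet-standing
  SDs, backtracked to the first sample of that departure (the sample after
  the last one within 1 SD). The 5 SD / 1 SD rule is standard force-plate
  practice; both multipliers are configurable.
* **Minimum-velocity instant** — argmin of \(v\) between onset and take-off.
* **End of braking** — first upward zero crossing of \(v\) after the
  minimum. This is the eccentric/concentric boundary: the reported boundary
  time is linearly interpolated between samples, while phase windows snap to
  the later sample.
* **Take-off** — first sample after onset with \(F < 10\) N sustained for at
  least 10 ms. Landing (for the flight-time cross-check) is detected
  symmetrically.

Impulse–momentum identities anchor the numerics: the per-kg net impulse over
the concentric phase equals take-off velocity, and the net impulse from the
velocity minimum to the end of braking equals the magnitude of the velocity
minimum. Impulse integrals use the interpolated end-of-braking instant,
where velocity is zero by definition, so these identities hold to
integration tolerance on every trial.

## The session variables

Ten variables are computed per trial (all force/impulse/power quantities
normalized to body mass), then averaged over the session's three trials:
jump height from peak concentric velocity \(JH = v_{peak}^2/2g\) (take-off
velocity and flight-time variants are also reported), peak force, peak
power, eccentric (braking) and concentric impulse, eccentric and concentric
mean power, phase durations, and the concentric:eccentric duration ratio.

Three definitional choices deserve note, because the field's terminology is
loose:

* **Eccentric impulse** is the braking net impulse (minimum-velocity instant
  to end of braking), which equals \(|v_{min}|\). A literal net impulse over
  the whole eccentric phase is identically zero (velocity starts and ends
  the phase at zero), and a gross impulse \(\int F\,dt\) is an order of
  magnitude larger than the values this quantity is reported at in practice
  (≈1.2–1.4 Ns/kg); the braking net impulse is the only reading consistent
  with both.
* **Eccentric mean power** is reported as a magnitude: COM power is negative
  throughout the descent, while the quantity is conventionally printed
  positive. A signed option is available (`eccentric_power = "signed"`).
* **Duration ratio** is computed as ConDur/EccDur. With typical values
  (EccDur ≈ 0.35 s, ConDur ≈ 0.25 s) this is ≈0.7 and *increases* under
  fatigue as the concentric phase lengthens relatively — matching how the
  indicator is reported and interpreted; the reciprocal would behave
  oppositely.

Percent change against baseline is \(100\,(x - x_{base})/x_{base}\),
presented to one decimal.

## Time-normalized curves

Force (N/kg) and power (W/kg) curves are normalized so the eccentric phase
maps to 0–50% and the concentric phase to 50–100% of movement time: linear
interpolation at \(Q/2 + 1\) evenly spaced time fractions per phase,
concatenated at the shared 50% node (end of braking). The default is
\(Q = 100\), i.e. 101 nodes, the convention used throughout the 1D-SPM
community. Curves are normalized per trial and then averaged per participant
("normalize first, then average"), consistent with sessions being
represented by trial means.

## Session statistics

Each variable is analyzed with a one-way repeated-measures ANOVA across the
five conditions: the within-subject decomposition with
\(F = MS_{cond}/MS_{err}\) on df \((k-1,\ (k-1)(n-1)) = (4, 36)\) for
\(n = 10\), \(k = 5\). Sphericity is tested with Mauchly's W (chi-squared
approximation including the second-order Box series term, mirroring the
reference implementation in base R's `mauchly.test` so the two agree to
machine precision); when rejected at \(\alpha = 0.05\), both degrees of
freedom are multiplied by the Greenhouse–Geisser \(\hat\varepsilon\).
Note that the between-groups df \((4, 45)\) sometimes printed alongside such
designs is inconsistent with the within-subject model: the identity
\(F = \frac{\eta_p^2}{1-\eta_p^2}\cdot\frac{df_{err}}{df_{eff}}\) closes
(within rounding) only with \(df = (4, 36)\), which is what this package
reports.

Post hoc inference is Bonferroni over all 10 condition pairs (paired
t-tests, p-values multiplied by 10 and capped at 1). Effect sizes are
partial \(\eta^2 = SS_{cond}/(SS_{cond}+SS_{err})\), labelled by the
thresholds 0.04 (small), 0.25 (moderate), 0.64 (large), lower bounds
inclusive.

## SPM on the curves

For each fatigue condition versus baseline, and for both force and power
curves, a paired t-statistic is computed at every node from the
participant-level difference fields. Family-wise control over the 101
correlated tests comes from random field theory:

* **Smoothness.** The FWHM of the residual (centred difference) fields is
  estimated from their normalized squared gradients:
  per-node resel density \(\sqrt{v/(4\ln 2)}\) with
  \(v(q) = \sum_i \dot r_i(q)^2 / \sum_i r_i(q)^2\), FWHM = 1/mean density.
  Central differences in the interior, one-sided at the ends. On fields
  constructed with known FWHM 12 the estimator recovers the truth within a
  few percent on average (validated by simulation in the test suite).
* **Threshold.** The resel count is (number of unmasked nodes − 1)/FWHM, and
  the critical value \(t^*\) solves
  \(\alpha_{tail} = P(T > u) + R\,\frac{\sqrt{4\ln 2}}{2\pi}
  (1 + u^2/\nu)^{-(\nu-1)/2}\),
  the expected-Euler-characteristic approximation for a smooth 1D t-field
  (point-probability term plus resel term), by monotone root finding.
  Inference is two-tailed by default (\(\alpha_{tail} = \alpha/2\)): the
  contrast direction is not pre-declared. As the resel count approaches
  zero the threshold reduces exactly to the uncorrected t quantile.
* **Clusters.** Maximal contiguous supra-threshold runs of \(|t|\); their
  endpoints are refined to fractional percent by interpolating the
  threshold crossings and reported to one decimal. Cluster p-values use the
  standard extent approximation for smooth fields: with expected cluster
  count \(E[m]\) (the EEC), expected supra-threshold volume
  \(E[N] = R\,P(T>u)\), and
  \(\beta = (\Gamma(3/2)E[m]/E[N])^2\), the probability of a cluster of
  extent \(k\) resels is \(e^{-\beta k^2}\) and
  \(p = 1 - \exp(-2\,E[m]\,e^{-\beta k^2})\) (two-tailed). At threshold the
  cluster p equals the family-wise \(\alpha\) in the zero-extent limit, so
  reported cluster p-values always lie in \((0, \alpha]\).

Validity of the whole inference chain is established by direct simulation —
the ground truth an analytical approximation must answer to: on 2000 smooth
Gaussian null fields (FWHM 12, 101 nodes, n = 10) the proportion of
datasets with any supra-threshold cluster lies within the binomial 95% CI
of the nominal 0.05 — both with the true smoothness plugged in and with the
full estimated-smoothness chain.
Zero-variance nodes are masked: excluded from the t-curve, the smoothness
estimate and the resel count.

## The synthetic-data generator

The generator works at the level of COM velocity, not force, because a
velocity-level construction makes Newtonian self-consistency automatic:
force is obtained as \(F = m(g + \dot v)\), so the analysis pipeline's
integration inverts the generator by construction.

One jump is a piecewise-polynomial velocity profile on
\([0, T_{ecc} + T_{con}]\):

* **Unweighting** (onset to the velocity minimum at 65% of the eccentric
  phase): acceleration is a raised-cosine trapezoid bump (taper 0.2)
  integrating to \(-v_{down}\). The flat-topped pulse keeps peak downward
  acceleration at 1.25× the mean, leaving a safety margin below free fall
  (plate force cannot be negative) at realistic depths.
* **Braking** (minimum to end of braking): cubic Hermite from \(-v_{down}\)
  to 0 with end slope \(s_2 = 1.5\,v_{down}/T_{brake}\) (the
  `braking_slope_factor` must stay in (0, 3] for monotonicity).
* **Concentric**: a quartic with five constraints — continuity of velocity
  and acceleration at the boundary, take-off velocity \(v_{to}\) at the end,
  acceleration exactly \(-g\) at take-off (zero plate force), and a
  stationary acceleration point at the fraction `concentric_shape` of the
  phase, which skews where force peaks.

Around the movement, the trial gets a quiet-standing segment at body weight,
a ballistic flight of duration \(2v_{to}/g\), a half-sine landing pulse
sized to absorb the landing momentum, and additive white Gaussian noise
(default SD 5 N, small against body weight, matching broadband plate noise),
clamped at zero.

Defaults describe the emulated study population of male collegiate
sprinters: body mass 65.7 kg, eccentric/concentric durations
0.35 s / 0.25 s, downward velocity minimum 1.35 m/s, take-off velocity
3.08 m/s, 1000 Hz. These reproduce the targeted baseline means closely —
concentric impulse 3.08 Ns/kg and the phase durations essentially exactly,
peak power ≈ 65 W/kg, duration ratio ≈ 0.72, jump height ≈ 51 cm from peak
velocity (the peak-velocity definition sits a few percent above the
take-off-velocity value of 48.4 cm because velocity peaks before the
terminal free-fall deceleration). One published inconsistency is worth
recording: a baseline peak force of ≈17.3 N/kg cannot coexist with a
concentric impulse of 3.08 Ns/kg over 0.25 s (which forces a *mean* total
force of ≈22 N/kg); the generator honors the impulse, durations and jump
height, and realizes peak force near 27 N/kg (≈2.1 body weights, typical of
jumps this high).

**Fatigue effects** act through two channels: multiplicative scales on the
phase durations and take-off velocity, and a fractional force cut applied
over a window of normalized time (default 50–75%, the early concentric
phase, rectangular so the cut is exactly the stated fraction). The default
condition effects put the entire concentric deficit into the windowed cut —
mirroring the observation that fatigue concentrates force loss just after
the eccentric/concentric transition — with the cut sized so the realized
take-off-velocity decrements are ≈19%, 10%, 5% and 3% at 3 min, 10 min, 1 h
and 24 h (the windowed cut reduces take-off velocity by ≈1.08× its
fraction), and duration scales that shorten the eccentric and lengthen the
concentric phase. Because the window is concentric, eccentric-phase
variables are unaffected by design; the effect parameterization deliberately
contains no eccentric channel.

**Cohorts.** Between- and within-subject variability enter as lognormal
multipliers on durations and velocities (keeping them positive); body mass
is Gaussian. Parameter draws are rejection-sampled into the physically
feasible region — plate force must keep a ≈1 m/s² margin above zero
everywhere except the final 50 ms before take-off, where it legitimately
decays to zero — because profiles that graze zero force mid-movement are
physically extreme and defeat threshold-based flight detection. Extremely
rare stubborn draws are progressively shrunk toward the population centre.
RPE (Borg 6–20) is drawn per session with a participant-level correlation
of 0.5, rounded and clamped to the scale.

What the generator does *not* emulate: multi-axis forces, filtering
artefacts, anticipatory sway before onset, non-Gaussian plate noise,
landing mechanics beyond a momentum-consistent pulse, or any eccentric-phase
fatigue response. Passing tests therefore demonstrate that the pipeline's
numerics and inference behave correctly on waveforms with CMJ morphology
and known truth — not that any specific physiological claim holds in real
athletes.

## Numerical choices and degenerate inputs

* Trapezoidal integration, no filtering by default (at 1000 Hz, filtering is
  unnecessary and would bias impulses); reintegration of a generated
  profile recovers per-sample velocity to ≈3×10⁻⁵ m/s (the O(h²) error at
  1 kHz) and take-off velocity to <10⁻³ m/s.
* Take-off thresholding fires where force first drops below 10 N, as much
  as ~2 ms before the analytic zero; this biases take-off velocity by up to
  ≈0.02 m/s. Jump height from *peak* velocity is immune, which is one
  argument for the peak-velocity default.
* Onset/boundary detection errors: no threshold crossing → "no movement";
  no negative velocity → "no countermovement"; no upward crossing →
  "aborted jump"; no sustained sub-threshold force → "no flight". All are
  typed conditions (`cmjfatigue_error` subclasses).
* Zero-variance ANOVA matrices and k = 2 sphericity are handled explicitly
  (error and ε = 1 respectively). Cluster p-values use `expm1` so extreme
  extents never underflow to exactly zero.
* Simulation sizes in the test suite (2000 null replicates for error-rate
  calibration, 200 for deficit-localization power, 500 for smoothness
  recovery, 50 for oracle equivalence) were chosen so binomial confidence
  intervals are tight enough to be informative while the whole suite stays
  comfortably fast.

## Known limitations

* Onset/take-off threshold values in published studies are rarely reported;
  index-level agreement with any specific laboratory's analysis cannot be
  guaranteed (the thresholds are configurable).
* The RFT threshold uses the EEC approximation with independently estimated
  smoothness; at very small n or very rough fields the familywise error can
  drift a few tenths of a percent from nominal (the calibration tests bound
  this at the study's design point).
* The generator's fatigue model is deliberately low-dimensional (four
  parameters per condition); it reproduces session-mean patterns, not
  individual-athlete heterogeneity of recovery.
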