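# cmjfatigue

Force-plate analysis of the countermovement jump (CMJ) for monitoring
neuromuscular fatigue in athletes.

A CMJ performed on a force plate yields a single vertical
ground-reaction-force time series per trial. From it, this package derives
centre-of-mass kinematics by the impulse–momentum method
(`a = F/m − g`, integrated from movement onset), segments the jump into its
eccentric phase (onset → end of braking, where the downward centre-of-mass
velocity returns to zero) and concentric phase (end of braking → take-off),
and computes the standard per-trial variables: jump height from peak
velocity (`JH = v²/2g`), peak force and power, phase net impulses, phase
mean powers, phase durations and their ratio — all normalized to body mass,
averaged over the trials of a testing session.

Sessions (e.g. baseline and 3 min, 10 min, 1 h, 24 h after a fatiguing
effort) are then compared two ways:

* **Per variable** — one-way repeated-measures ANOVA
  (`F = MS_cond/MS_err`, df `(k−1, (k−1)(n−1))`) with Mauchly's sphericity
  test and the Greenhouse–Geisser correction, Bonferroni post hoc paired
  tests, and partial η² effect sizes classified at 0.04/0.25/0.64.
* **Per curve** — force- and power-time curves time-normalized to 0–50%
  (eccentric) and 50–100% (concentric), compared with one-dimensional
  statistical parametric mapping: a paired t-statistic at each of 101
  nodes, residual smoothness (FWHM) estimated from field gradients, the
  family-wise critical threshold `t*` from the random-field-theory
  expected-Euler-characteristic approximation, and supra-threshold clusters
  with extent-based p-values.

Because raw laboratory recordings are rarely shareable, the package also
contains a physically consistent synthetic CMJ generator: jumps are built at
the level of centre-of-mass velocity (so `F = m(g + dv/dt)` inverts exactly
under the analysis pipeline), with cohort-level between/within-subject
variability and configurable fatigue effects (phase-duration scaling plus a
windowed early-concentric force cut). Every stage of the pipeline is
validated against this generator's ground truth.

## Worked example

Analyze a single (here synthetic) trial:

```r
library(cmjfatigue)

tr <- simulate_trial(jump_profile_params(),
                     participant = "P01", condition = "baseline", trial = 1)
an <- analyze_trial(tr)     # weighing -> onset -> integration -> segmentation
round(an$variables[c("jh_cm", "pf_nkg", "pp_wkg", "coni_nskg",
                     "ecci_nskg", "eccdur_s", "condur_s", "duration_ratio")], 2)
#>   jh_cm pf_nkg pp_wkg coni_nskg ecci_nskg eccdur_s condur_s duration_ratio
#> 1 52.08  27.06  64.33      3.08      1.35     0.35     0.25           0.72
```

The jump height (52 cm), concentric impulse (3.08 Ns/kg — exactly the
take-off velocity, by impulse–momentum), braking impulse (1.35 Ns/kg — the
downward velocity minimum) and phase durations read directly off the
segmentation.

Run a whole simulated fatigue study (10 participants × 5 sessions × 3
trials) and inspect the report:

```r
report <- run_study(study_config(seed = 42))
report
#> <study_report> 10 participants x 5 conditions, 150 trials
#> Main effects (repeated-measures ANOVA):
#>   rpe             F(4.00, 36.00) =  80.45  p = 1.92e-17 eta2 = 0.90 (large)
#>   jh_cm           F(4.00, 36.00) = 270.26  p = 2.59e-26 eta2 = 0.97 (large)
#>   ...
#>   ecci_nskg       F(4.00, 36.00) =   0.49  p = 0.741    eta2 = 0.05 (small)
#>   conmp_wkg       F(4.00, 36.00) = 337.64  p = 5.33e-28 eta2 = 0.97 (large)
#>   duration_ratio  F(4.00, 36.00) =  25.16  p = 5.33e-10 eta2 = 0.74 (large)
#> SPM: 8 of 8 comparisons with supra-threshold clusters

report$spm[["force.24hr"]]
#> SPM paired t-test: df = 9, FWHM = 5.8 nodes, resels = 17.10
#>   t* = 4.915 (alpha = 0.05, two-tailed)
#>   cluster 1: 65.4-74.9% (peak t = -9.21, p = 0.0000)
```

The pattern is the one the simulated fatigue model injects: concentric-phase
variables (jump height, concentric impulse and mean power) show large
session effects, eccentric-phase variables do not, the concentric:eccentric
duration ratio rises, and the force-curve deficit localizes to the early
concentric phase (the 50–75% window of normalized time) — still detectable
24 h after the effort.

`make_report_tables(report, "out_dir")` writes the session-comparison table
(means ± SD with pairwise significance letters, F, η²), the percent-change
table, and the SPM cluster table as CSV. A thin command-line wrapper for
simulation and manifest-based analysis is installed at
`inst/scripts/run_cmj_study.R`.

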