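---
title: "Posturography methods in posturolab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posturography methods in posturolab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturolab)
```

`posturolab` turns dual force-plate recordings of standing balance into the
standard static and dynamic outcome set and compares groups
nonparametrically. This vignette documents the models, the operational
definitions behind each outcome, the tunable parameters, and the design
choices made where the methodology is genuinely underdetermined — together
with what the synthetic-data tests do and do not establish about real
recordings.

## Signal model

Each trial carries, per plate, a vertical force series `Fz` (N) and a CoP
coordinate pair (mm) at a sampling rate read from the file header (the
generator default is 120 Hz, typical of commercial plates). The combined
center of pressure is the per-sample force-weighted mean of the two plates'
CoPs. This weighting is the standard two-plate combination; its limiting
behaviour is exactly what step analysis needs, because a fully unloaded
plate contributes nothing and the combined CoP collapses onto the stance
foot. Both plates unloaded simultaneously is treated as a signal gap
(impossible in a standing protocol) and raises an error rather than
propagating nonsense.

Scalar displacement is the Euclidean distance from a reference point. The
reference is a deliberate choice, recorded in every output: the window mean
for quiet stance, and the mean of the 5 s pre-perturbation window for
perturbation segments. Both choices make displacement stationary around
zero offset before anything interesting happens, so a perturbation's
maximal displacement is measured from the participant's own baseline.

CoP velocity is the absolute time derivative of scalar displacement,
estimated by a symmetric central difference with one-sided ends and no
pre-smoothing (smoothing belongs to the envelope stage, where its corner
frequency is explicit). Defining velocity on the scalar displacement rather
than as 2D path speed matters: a CoP circling its reference at constant
radius has near-zero scalar velocity but path speed `r·ω`. Both definitions
are exposed (`cop_velocity()`, `cop_path_speed()`); the scalar derivative
is the reported outcome, and a test pins this distinction down with the
circular counterexample.

## Static sway

Two outcomes per quiet-stance condition, both on the middle 20 s of the
30 s trial (samples in `[5 s, 25 s)`, half-open):

* **95% ellipse area.** The covariance-based 95% prediction ellipse: with
  `Σ` the sample covariance of (AP, ML), the area is
  `π · χ²₀.₉₅,₂ · √det(Σ)` with `χ²₀.₉₅,₂ = 5.9915`. This is the de-facto
  standard construction in posturography; a convex-hull-trimming
  alternative exists but is not implemented. The constant is flagged in
  output metadata so downstream users know which 95% construction they are
  looking at. For bivariate-normal sway the ellipse contains 95% of
  samples in expectation — the test suite verifies containment and the
  closed-form area on 10⁵ draws.
* **Mean velocity.** The arithmetic mean of the absolute scalar velocity
  over the same window.

Attaching the same window to both outcomes (the area could arguably use
the full 30 s) avoids asymmetric windowing artifacts when the two are
combined into dual-task costs.

## Perturbation responses

Dynamic trials are segmented per perturbation from 5 s before to 4.5 s
after onset. The pre-window defines the displacement reference and the
steady-state band; a segment whose window is truncated by trial bounds is
flagged discarded ("technical") and excluded from aggregation, mirroring
the small discard fraction typical of these protocols.

**Envelope.** The velocity signal is low-passed at 10 Hz (2nd-order
Butterworth, applied forward and backward for zero phase, with
odd-reflection padding to suppress edge transients), then a piecewise-linear
envelope is interpolated through its successive local maxima, endpoints
anchored. The envelope construction is a design choice — published figures
of this kind show a peak envelope without stating the algorithm — and both
the corner frequency and the construction are config-exposed.

**Recovery time.** "Return to a steady state" is operationalized as: band =
mean + 2·SD of the envelope over the 5 s pre-window; recovery is the first
post-onset instant at which the envelope stays inside the band for at
least 0.5 s continuously. The 2 SD multiplier and the dwell are parameters
(`recovery_band_k`, `recovery_dwell_s`). The dwell prevents premature
triggering in the valley between oscillation lobes; the band makes the
criterion scale-invariant (gain applied to the whole velocity signal
cancels). If the envelope never settles within 4.5 s the value is censored
at 4.5 s and flagged; at generator defaults the censoring rate is below
5%. On the analytic exponential-envelope model (amplitude 20σ over a
baseline of SD σ, τ = 0.5 s) the detector lands at the closed-form band
crossing `τ·ln(A/2σ) ≈ 1.15 s` within the stated tolerance.

**Other outcomes.** `cop_max` is the maximal displacement over the
post-onset window only (the pre-window would otherwise contaminate the
maximum); mean recovery velocity averages from onset to the recovery
instant (a defensible alternative would start at the first envelope peak;
onset is chosen and documented). Pre-perturbation standing sway applies
the static outcomes to the 5 s pre-window.

## Step detection

A compensatory step is a maximal interval where exactly one plate's force
stays at or below 5 N (plates never read exactly zero) for at least 50 ms,
whose CoP after reloading differs from before unloading by at least 20 mm.
The duration rule is applied as `n_samples / fs ≥ 0.05 s`, so the boundary
is exact at any sampling rate (6 samples at 120 Hz). Unloading intervals
separated by under 30 ms are merged first — contact chatter at touchdown
otherwise splits one step into several. The 20 mm landing-offset clause
operationalizes "the base of support changed": the original methodology
confirmed steps on video, which a signal-only pipeline cannot do, so a
pure weight shift (unloading without repositioning) is rejected by the
offset threshold instead. All four thresholds are config-exposed.
Strategy classification is mechanical: 0 steps → in-place, 1 → single
step, ≥2 → multiple steps; step total displacement applies the distance
equation to each landing offset and sums.

## Dual-task costs

`DTC = 100·(single − dual)/single`, applied metric-wise per participant
within eyes condition — negative values mean the dual task inflated the
metric, the usual direction for sway outcomes. Cognitive costs apply the
same form to counting rates (counts/min) between contexts: reference vs
sway, reference vs perturbation, sway vs perturbation. The three are
algebraically linked (`cdtc_sway_vs_pert = 100·(p − s)/(100 − s)`), which
the tests assert. The perturbation-context rate divides total correct
counts by the trial time actually analyzed, since that duration varies by
participant.

## Group statistics

Outliers are removed once (never iterated) per metric per group: a value
is dropped iff it lies beyond 1.5·IQR from the median, with
linear-interpolation quartiles (`stats::quantile` type 7). Removal counts
are carried into the report like table footnotes. Group comparison is a
two-sided Mann-Whitney U: exact null when the combined sample is ≤16 and
tie-free, tie-corrected normal approximation (no continuity correction)
otherwise; the method used is recorded per row. The exact branch is
checked against an exhaustive permutation enumeration over every tie-free
rank configuration up to combined n = 10. Multiple-step episode frequency
is compared on a 2×2 participant table (any multiple-step episode vs none,
among participants who stepped at all); because small-table χ² variants
disagree, the plain χ², Yates-corrected, and Fisher exact p are all
reported and none is privileged. Following the source methodology, no
multiple-testing correction is applied to the primary p-values; a
Benjamini-Hochberg column is emitted alongside for transparency.

## The synthetic cohort generator

The generator produces data with the statistical structure the pipeline
assumes, so every stage can be tested against known ground truth.

**Sway** is a 2D Ornstein-Uhlenbeck process (mean reversion `k` 1/s, drive
`σ` mm/√s, exact discretization, stationary start; per-axis stationary
variance `σ²/(2k)`), band-limited at `bandwidth_hz`, plus white positional
jitter. The OU variance sets the ellipse area; the jitter sets mean
velocity almost independently — exactly the two dials the rigidity
phenotype needs (smaller area *and* higher velocity in the clinical
group). Defaults (control `k = 7`, `σ = 17`, jitter 0.05 mm; clinical
`k = 8.7`, jitter 0.16 mm; band 1.2 Hz) were calibrated once so that
control eyes-open outputs sit near the scales healthy adults produce on
this protocol (area ≈ 150 mm², velocity ≈ 12 mm/s, recovery ≈ 1.5–2 s,
reference counting rate 17.5/min) with clinical-to-control ratios of
≈0.7 (area), ≈1.3 (velocity) and ≈0.76 (recovery time constant). Eyes
closed, dual task, and pre-perturbation anticipation act as multiplicative
factors on `σ` and jitter (anticipation doubles `σ`, quadrupling prior
standing area relative to quiet sway). The mean-reversion rate was placed
high enough that a 20 s window contains many independent sway cycles;
together with modest between-participant multipliers (log-normal, sdlog
0.10–0.35) this keeps the configured group contrasts statistically
detectable at the study's 12 vs 11 sample size. The generator therefore
reproduces group *contrasts and scales*, not the full between-participant
variance of real cohorts — real data are substantially more heterogeneous,
and a power statement on these synthetic cohorts does not transfer to
human studies.

**Perturbations** superpose, at each onset, a damped postural oscillation
(1.2 Hz) under a double-exponential amplitude envelope (rise 0.1 s,
group-specific recovery constant), normalized so the displacement peak
equals the configured amplitude (140 mm translations, 110 mm tilts). A
pure double-exponential displacement pulse was considered and rejected:
its velocity has a single swing, so a peak-interpolated envelope
degenerates to a straight line across the segment and the recovery instant
becomes meaningless; the oscillatory kernel gives the velocity envelope
the train of decaying peaks seen in real responses. Onsets follow the
protocol timing: first at 6 s, then a 5 s platform return plus a uniform
9–15 s interval; 8 perturbations per trial (each translation/tilt ×
direction once, random order).

**Ground-truth recovery** is recorded per event by running the package's
own detector on a composite signal: the generated (noisy) pre-window —
which defines the band exactly as the detector will see it — followed by
the noise-free kernel alone. The truth is thus "what the detector would
report without post-onset sway noise", and the recovery-consistency
property (median detection error within ±0.15 s over ~200 segments)
measures exactly the effect of that noise.

**Steps** are injected with configurable probabilities (step probability
≈0.37 per perturbation in both groups; multiple-step probability given a
step 0.60 vs 0.03, strongly elevated in the clinical group). During a
step, one plate's force drops to zero for 100–250 ms and its CoP relands
with a 40–90 mm offset along the perturbation axis; stance is restored
when the platform returns. The stepping plate's *dynamic* CoP component is
held constant from shortly before lift-off to shortly after touchdown
(then ramped back over 0.2 s): a stepping foot does not track the body
swing — the stance foot does the balancing — and without this hold the
kernel oscillation leaks into the measured landing offset and can cancel
it below the 20 mm clause.

**Counting records** are Poisson at group- and context-specific rates
(reference means 17.5 vs 11.9 counts/min, between-participant SD 3.6;
sway contexts slightly above reference, perturbation contexts below, so
the cognitive costs come out negative for sway and positive for
perturbations).

All randomness flows from one master seed through named substreams (per
participant, trial, and purpose), so identical configurations are
bit-identical regardless of evaluation order.

## Numerical choices and degenerate inputs

* Quartiles: linear interpolation (type 7); the outlier band uses a small
  absolute tolerance (1e-12) so boundary values are kept.
* A trajectory with singular covariance (all points identical, or
  collinear) has ellipse area 0 with a warning rather than an error.
* The envelope low-pass is skipped when the corner is at or above Nyquist;
  filtfilt inputs are odd-reflection padded (3/f_c worth of samples).
* The 50 ms step boundary compares `n/fs` against 0.05 with a 1e-9 slack,
  so exact-boundary counts are detected at any rate.
* Unreadable or malformed trial files fail fast with the offending row;
  within a cohort run, a failing trial is logged and skipped (fail-soft per
  trial, fail-fast per cohort schema), and every analysis parameter is
  echoed into the run outputs.

## Problem sizes in the shipped analyses

The analysis scripts and the acceptance script use one full-protocol
cohort (12 vs 11 participants; four sway conditions and two 8-perturbation
trials each) plus a 50-replicate detection study on the reduced design
(eyes-open sway and one no-dual-task perturbation trial per participant —
the conditions carrying the tested contrasts); the test suite's replicate
study uses 100 such cohorts. These sizes give stable medians and detection
rates while keeping a complete run in the minutes range on a single core.

## Known limitations

* The generator is not a biomechanical model: no inverted-pendulum
  dynamics, no foot geometry, no EMG/kinematics; plate CoPs are
  constructed to be consistent with the target combined trajectory rather
  than derived from limb mechanics.
* Velocity scales run somewhat above typical healthy eyes-open values
  because the sway band extends to 1.2 Hz to keep single-window area
  estimates stable; contrasts, not absolute velocities, are the calibrated
  quantities.
* The steady-state criterion (band multiplier, dwell) and the envelope
  algorithm are operational definitions; alternative published choices
  would shift absolute recovery times while preserving group contrasts.
* Serial-subtraction correctness is reduced to a correct-count tally; no
  model of error patterns or task prioritization is attempted.
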