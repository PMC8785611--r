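# posturolab

Force-plate posturography for standing-balance studies: static sway,
perturbation recovery, compensatory stepping, and dual-task costs, with the
nonparametric group statistics used in small clinical cohorts.

`posturolab` is written for balance researchers who record quiet stance and
platform-perturbation trials on two force plates (one per foot) and need the
standard computerized outcome set:

- **Weighted CoP trajectory.** Per-sample vertical-force weighting of the two
  plates' centers of pressure,
  `CoP = (Fz_L·CoP_L + Fz_R·CoP_R) / (Fz_L + Fz_R)`, in anterior-posterior
  (AP) and medial-lateral (ML) axes; during single support the combined CoP
  is the loaded plate's CoP. Scalar displacement is the distance equation
  `D = √(D_AP² + D_ML²)` from a reference point, and CoP velocity is the
  time derivative of `D` (not the 2D path speed — `cop_path_speed()` gives
  the alternative).
- **Static sway** (30 s quiet stance, middle 20 s analyzed): the 95%
  prediction-ellipse area `π · χ²₀.₉₅,₂ · √det(Σ)` from the 2×2 sample
  covariance Σ of (AP, ML), and the mean absolute CoP velocity.
- **Perturbation responses** (segments from 5 s before to 4.5 s after each
  platform translation/tilt): recovery time from a peak envelope over the
  velocity signal (recovery = first dwell of ≥0.5 s inside the baseline
  band, mean + 2 SD of the pre-perturbation envelope), maximal CoP
  displacement, and mean velocity during recovery.
- **Compensatory steps**: ≥50 ms of (near-)zero load on one plate with a
  ≥20 mm CoP landing offset (a changed base of support); responses are
  classified in-place / single-step / multiple-steps.
- **Dual-task costs**: `DTC = 100·(single − dual)/single` on balance
  metrics, and the cognitive analogues on serial-subtraction counting rates
  (reference vs sway vs perturbation contexts).
- **Group statistics**: single-pass outlier removal (beyond 1.5 IQR from the
  median, linear-interpolation quartiles), two-sided Mann-Whitney U (exact
  for small tie-free samples), and 2×2 χ²/Yates/Fisher for step-episode
  frequencies.

Because raw recordings from clinical balance studies are rarely shareable,
the package ships a seeded synthetic cohort generator
(`simulate_cohort()`): band-limited Ornstein-Uhlenbeck sway plus white
positional jitter, damped-oscillation perturbation kernels with analytic
ground truth, injected stepping, dual-task inflation, and Poisson counting
records, with a configurable "rigidity" phenotype (smaller ellipse, higher
velocity, faster recovery, more multiple-step episodes) in the clinical
group.

## Worked example

```r
library(posturolab)

cfg <- default_generator_config(seed = 1)     # 12 clinical vs 11 control
sway <- simulate_sway(cfg, "control", "EO_NoDT", seed = 42)
sway_metrics(sway$trial)
#> <sway_metrics: area 170.9 mm^2, velocity 13.29 mm/s over [5, 25) s (n = 2400)>

pert <- simulate_perturbation_trial(cfg, "PD", seed = 42)
seg <- segment_perturbation(pert$trial, pert$trial$events[1, ])
recovery_time(seg)$recovery_s
#> [1] 1.4
```

The sway line says a healthy-like eyes-open trial covers about 171 mm² with
a mean CoP speed of 13.3 mm/s over the middle 20 s; the clinical-group
perturbation is recovered in 1.4 s (the velocity envelope re-enters its
pre-perturbation band and stays there for at least half a second).

The full workflow lives in `analysis/`:

1. `01_simulate_cohort.R` — simulate the cohort, write trial CSVs
   (to `scratch/`, they are bulky) and ground truth.
2. `02_analyze_cohort.R` — run the file-based pipeline
   (`run_analysis()`), producing the tidy cohort table and the group
   report (CSV/JSON/markdown) under `results/analysis/`.
3. `03_stepping_and_recovery.R` — strategy breakdown, multiple-step 2×2
   tests, per-type recovery, ground-truth comparison.
4. `04_replicate_study.R` — 50 replicate cohorts: how often each configured
   group contrast is detected at p < .05.

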