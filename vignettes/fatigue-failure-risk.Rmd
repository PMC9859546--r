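---
title: "Fatigue-failure ergonomic risk assessment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fatigue-failure ergonomic risk assessment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mate)
```

## The problem

Work-related musculoskeletal disorders arise from the *combination* of
loading magnitude and task repetition. Classic ergonomic scales (the revised
NIOSH lifting equation, RULA, REBA) score a posture or a lift largely from
its peak demand; fatigue-failure theory instead treats tissue like any
engineering material: at a load expressed as a percentage of ultimate stress
S, the material survives at most N cycles, the familiar S-N curve. This
package evaluates the outputs of a musculoskeletal simulation — muscle
activations and joint contact forces over a trial — against tissue-specific
fatigue-failure thresholds for three anatomical regions, and also computes
the classic scales so the two philosophies can be compared on the same task.

The package does **not** run the musculoskeletal simulation itself (no
model scaling, inverse kinematics/dynamics, or muscle-force optimization);
it consumes exported activation and contact-force time series in the
OpenSim storage dialect or CSV.

## The three risk layers

### Muscles: maximal acceptable effort

The duty cycle DC is the fraction of working time spent executing the
movement: a 6 s task performed five times per minute occupies 30 s of every
minute, DC = 50%. The maximal acceptable effort is

$$\mathrm{MAE} = 1 - \left(\mathrm{DC} - \tfrac{1}{28800}\right)^{0.24},$$

the activation fraction sustainable at that duty cycle; the offset
1/28800 makes a single maximal exertion in an 8 h shift (28 800 s)
acceptable at full effort. A functional muscle group (agonists sharing a
primary action) is at risk when at least `ceiling(n/2)` of its n agonists
have a *peak* activation strictly above the MAE — the quorum reading makes
single-muscle groups behave sensibly, and "exceeds" is implemented as a
strict inequality so the boundary is testable. Peaks are raw maxima; no
smoothing is applied by default (an optional moving-average window exists
for noisy field data).

```{r}
sched <- task_schedule(6, 3, 120, handled_mass = 10)
c(dc = duty_cycle(sched), mae = mae(duty_cycle(sched)))
```

### Hip: cartilage endurance limit

Hip cartilage shows an endurance limit: stresses below it never produce
failure regardless of repetition. The stored canonical value is the
endurance force, 9434 N, over an average femoral head area of 1610 mm²;
the stress form (5.86 MPa, about 30% of cartilage ultimate stress) is
derived from those two at four significant figures, because
5.86 × 1610 = 9434.6 shows the printed stress was rounded *from* the force.
Peak hip contact force divided by the area gives peak stress (N/mm² = MPa);
only a stress strictly above the limit flags the hip, independent of cycle
count.

### Spine: vertebral fatigue-failure probability

Vertebral ultimate compressive strength (UCS) is modelled as
$(c_0 + c_{sex}[male] - c_{age}\,\mathrm{age}/10) \times (b_0 + b_1\,\mathrm{BMI})$
in kN, with the BMI area factor clipped to [0.5, 1.5]. The failure
probability at a relative load (% of UCS) and a cycle count
(repetitions/min × duration) is interpolated from an S-N probability table —
linear in load, linear in log10 cycles, because S-N behaviour is log-linear
in cycles. Loads below the table's lowest level are the endurance region
(probability 0); loads above its highest clamp to the top row; zero cycles
means no loading. A failure probability strictly above the calibrated 10%
cutoff classifies the task as high risk for low-back pain.

Neither the UCS regression nor the probability table has a single canonical
published parameterisation that we could redistribute, so **both are
configuration data**: the package ships synthetic defaults
(`inst/extdata/ucs_model_synthetic.yaml`,
`inst/extdata/fatigue_table_synthetic.csv`, each documenting its generating
rule) whose values sit in the range of published lumbar-strength and
cadaveric-fatigue data, and every numerical test in the package runs on
explicit fixture values rather than on the defaults. Users with measured
tables load them with `read_fatigue_table()` / `read_ucs_model()`.

Cumulative damage across *different* tasks in a shift is deliberately
unsupported: each task is assessed on its own schedule, and no
rest/recovery healing model is included.

```{r}
subject <- subject_profile(age = 21, sex = "male", mass = 71.4, height = 1.75)
ultimate_compressive_strength(subject)
failure_probability(61, 360)
```

### Threshold calibration

Given labeled tasks (failure probability + observed low/high-risk label),
`calibrate()` sweeps candidate cutoffs at midpoints between adjacent
distinct probabilities (plus 0 and 1). Because the decision rule is a
strict `>`, accuracy is piecewise constant between observations, so the
midpoint grid is *exact*: no achievable confusion matrix is missed. Ties on
overall accuracy are broken toward higher sensitivity (fewer missed
high-risk tasks — the protective choice), then the lowest threshold. Both
the strict `>` and `>=` tie conventions are switchable (`ties_high`)
because the convention used in the original calibration dataset is not
recorded.

## Synthetic data

`generate_trace()` builds each channel as baseline + Gaussian bump + seeded
white noise. The risk layers consume only per-channel peaks and the
schedule, so exact peak control matters and kinematic realism does not:
passing tests therefore demonstrate correct threshold logic, not that the
package validates simulated biomechanics. Real model outputs differ in ways
the generator does not emulate — correlated multi-joint dynamics, task-phase
structure, optimizer chatter — so conclusions about real tasks still depend
on the quality of the upstream musculoskeletal simulation.
`generate_calibration_set()` emulates a labeled task table with a planted
probability boundary and independent label flips; with flip rate q the best
achievable (Bayes) accuracy is 1 − q, which anchors the recovery tests.

## Numerical choices and degenerate inputs

* Units are fixed by convention (s, N, kg, min, MPa); no auto-detection —
  silent unit guessing is the dominant failure mode in biomechanics I/O.
* Activations are accepted up to 1.5 (optimizer overshoot above 1 warns;
  larger values indicate a wrong channel mapping and are rejected).
* Motion-storage files may be tab- or comma-delimited, with or without an
  `endheader` block; any strictly increasing time base is accepted since
  exporters differ in sampling.
* `max_cycles_before_risk()` bisects the integer cycle axis between the
  table's cycle extremes; an exhaustive-scan oracle pins its behaviour in
  the tests, including the two degenerate ends (never at risk → table
  maximum; at risk from the first tabulated cycle → 0).
* An RWL of 0 (e.g. overhead work above vertical reach) makes the lifting
  index undefined; it is reported as `Inf` with `rwl_defined = FALSE`
  rather than 0, which would read as "no risk".
* `sex` defaults to `"female"`, the protective choice (lower vertebral
  strength), consistent with how the classic scales are calibrated.
* Missing channels mark a region "not assessed" in the report instead of
  failing the run; explicitly named channels that are absent still error.

## Problem sizes in the test-suite and acceptance runs

The property suites use tables of ~4×5 random monotone grids, traces of a
few hundred samples, 100-seed calibration replicates at n = 148 tasks, and
a 10 000-replicate Monte-Carlo check of the generator's noise amplitude —
sizes chosen because every property they exercise is scale-free, so larger
inputs would add runtime without adding evidence.

## Known limitations

* No cumulative damage across tasks, no recovery modelling.
* Femoral head area is a population average, not subject-specific.
* The shipped UCS/fatigue defaults are synthetic stand-ins, not measured
  reference data; region verdicts under the defaults are illustrative.
* RULA/REBA descriptors must already be worksheet categories; the package
  does not derive them from joint kinematics.
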