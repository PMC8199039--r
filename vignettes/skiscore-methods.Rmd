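---
title: "Scoring alpine-ski motion quality from boot-mounted IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring alpine-ski motion quality from boot-mounted IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skiscore)
```

## The problem

Recreational wearable systems count things — turns, runs, kilometres — but
say little about *how well* a movement was performed. skiscore implements a
normative scoring chain for alpine skiing built on two boot-cuff inertial
measurement units (3-axis accelerometer at ±16 g, 3-axis gyroscope at
±1000 deg/s, streamed at a nominal 54 Hz) and a 1 Hz GNSS speed track. The
idea is to learn what the waveforms of a small *gold-standard* cohort of
elite skiers look like, turn by turn, and to score new turns by how far
their waveforms sit from that reference distribution.

The processing chain follows the activity-recognition-chain pattern:
segmentation → enrichment → classification, extended with a scoring step.

## Turn segmentation

Skiing is well described by a pendulum model: the legs roll from one edge
set to the other once per turn, so the roll-axis gyroscope (boot Z channel)
shows one dominant extremum of alternating sign at every edge change.
`detect_turn_boundaries()` low-pass filters the roll rate (zero-phase
2nd-order Butterworth, default cutoff 2 Hz), collects local extrema whose
absolute filtered value reaches `min_prominence_dps` (default 15 deg/s,
measured from the zero baseline the cyclic signal oscillates about), and
forces consecutive boundaries to alternate in sign with at least
`min_period_s` (default 0.6 s) between them; the larger-magnitude extremum
wins any conflict. A turn spans one extremum to the next, so a pure
roll-rate sinusoid of period 2 s over 20 s yields 20 boundaries and 19
turns, each a 1 s half-cycle. No thresholds for this step are published for
the original system; the defaults here were chosen once from the physics
(recreational turns last roughly 1–3 s and peak roll rates reach tens of
deg/s) and are all exposed in `ski_config()`.

Two exclusion rules then remove turns where the skier is accelerating or
braking: the first and last detected turn of every run are dropped, and
among the remaining interior turns any turn whose mean speed falls strictly
below `median - MAD` of the interior mean speeds is dropped, where MAD is
the *raw* median absolute deviation (no 1.4826 consistency constant) — a
literal reading of "one median absolute deviation below the median". The
rule is applied after removing the first/last turns, so the statistics
describe the interior of the run. With all interior speeds equal the MAD is
zero and the strict inequality removes nothing.

## Enrichment

Each retained turn is described by four variables, each linearly
interpolated onto 101 points spanning 0–100 % of turn duration
(`time_normalize()`; endpoints preserved exactly):

* **Edge angle** (degrees) — boot roll magnitude relative to gravity from a
  complementary filter fusing the integrated roll-rate gyro with the
  accelerometer roll `atan2(ax, ay)`; gyro weight `alpha = 0.98` at 54 Hz, a
  conventional choice giving a ~1 s accelerometer time constant. The filter
  state is initialised from the accelerometer so static postures are tracked
  immediately. The outside boot of each turn is used by default (a left turn
  loads the right ski); `enrich.edge_boot = "mean"` averages both boots.
  This is a documented simplified stand-in for the validated proprietary
  estimator of the original system, as is every enrichment below.
* **Edge-angle symmetry** (degrees) — the signed pointwise difference
  between the current turn's edge-angle profile and the neighbouring
  opposite-direction turn's profile (the following turn for the first scored
  turn; zero-filled and flagged when no opposite-direction turn exists).
  "Symmetry" could also be read as left-vs-right boot within one turn; the
  turn-to-turn reading is implemented because the source system describes
  left–right *turn* differences.
* **Radial force** (multiples of body weight) — `v · |ω_yaw| / g` pointwise,
  with speed linearly interpolated from the 1 Hz GNSS track onto the IMU
  timestamps and yaw rate from the vertical (Y) gyro channel. Body mass
  cancels in body-weight units; the 75 kg default only feeds an optional
  newton-scale output.
* **Speed** (m/s) — the interpolated GNSS speed itself. Only its magnitude
  is informative at 1 Hz; the PCA below discovers that on its own.

## Classification

Turn **size** uses the estimated radius `r = v̄ / ω̄`: large above 12 m,
small below 8 m, medium in the closed band [8, 12] m (the published class
definitions give "~8 m" for medium, so a deterministic boundary had to be
fixed; doubling speed and yaw rate together leaves the class unchanged). A
config switch can instead honour a run-level intended size. Turn **style**
is taken verbatim from external labels when provided — the original system
uses a separately validated classifier — and otherwise from a deliberately
naive built-in rule: carving if the mean edge angle reaches 30° and the
radial-force waveform is single-peaked (by topographic peak prominence),
else drifting. The built-in rule is a demonstration stand-in and never emits
the non-parallel or snowplow classes.

## The reference model

For every (style, size) cell with at least `min_ref_turns` reference turns
(default 10, matching the protocol's "at least ten consecutive turns" per
run) and for each of the four variables, the n × 101 matrix of reference
turns is centered and decomposed by SVD (`fit_variable_pca()`). Three
quantities per variable are retained, exactly what needs to be persisted to
score new data:

* the 101-point mean curve,
* the first three right singular vectors (loading rows, orthonormal,
  sign-fixed so each loading's largest-magnitude element is positive),
* each component's fraction of *total* variance, and the standard deviation
  (n − 1 denominator) of the n reference PC scores.

Exactly three components are kept: across variables the first three PCs
explain well over 85 % of reference variance, and the three directions have
a consistent physical reading — signal magnitude, timing of the peak, and
single-versus-double peak shape. SVD on the centered matrix is used rather
than an eigendecomposition of the covariance for numerical stability; the
test suite asserts their equivalence on small matrices against a brute-force
`eigen(cov(x))` oracle. Rank-deficient cells are fitted with the available
components; trailing components get zero loadings and zero variance fraction
and are flagged, and scoring treats them as neutral (Z = 0).

Variance fractions are taken against the total variance of all components.
The published worked example is internally inconsistent on this point (a
perfect bin of 4 on PCs explaining 70/22/5 % is quoted as contributing
2.78/0.88/0.34): under the raw-fraction reading 4 × 0.22 = 0.88 holds
exactly, so that reading is adopted; the percentage normalization below
absorbs the fact that the three fractions do not sum to 1.

Models persist to human-readable JSON with an explicit schema version
(`save_model()` / `load_model()`); loading re-validates orthonormality,
ordering and completeness, and round-trips preserve every number to full
double precision.

## Scoring

A new turn is never refitted. Each variable vector is centered by the
reference mean and projected onto the loading rows; the absolute Z-score of
each PC score against the reference score SD is binned:

| absolute Z | bin |
|---|---|
| [0, 0.75) | 4 |
| [0.75, 1.5) | 3 |
| [1.5, 3) | 2 |
| [3, ∞) | 1 |

The published rule uses strict inequalities on both sides, leaving the
boundary values undefined; boundaries are assigned to the lower bin here, a
conservative convention. Bins are weighted by their variance fractions and
summed within each variable, the four sub-scores are expressed as a
percentage of the attainable maximum `4 · Σ varfrac` summed over variables,
and the percentage is mapped into the style band: carving 7–10, drifting
3–6, linear in the percentage. Because the worst bin is 1 rather than 0, the
percentage floor is 25 and the effective bands are [7.75, 10] and
[3.75, 6]. Snowplow and snowplow-steering turns are assigned the constants 1
and 2 and are otherwise unscored; non-parallel turns have no published band
and are scored in the drifting band with an `off_band` flag. Deviations of
+δ and −δ along a loading score identically — the algorithm measures
similarity to the reference, not "more is better".

Run summaries report both the mean and the median of the final scores, since
run-level comparisons are made with both central tendencies in practice.

## Synthetic data: what it emulates and what it does not

No public dataset exists for this system, so `generate_turn_curves()`,
`generate_cohort()` and `generate_raw_run()` produce seeded synthetic inputs
with the statistical structure the model assumes:

* three orthogonal variability modes per variable — a Gaussian-bump
  magnitude mode, its derivative as a timing mode and a Mexican-hat
  single-vs-double-peak mode — with Normal coefficients of decreasing SD,
  plus white sensor noise. Modes are scaled to **unit peak amplitude**, so
  mode SDs are per-point peak deviations in natural units; under a unit-norm
  convention a per-sample noise floor of 10 % of the first mode SD would
  swamp the spectrum once spread over 101 samples, which no real waveform
  set shows.
* defaults chosen once as field-realistic: edge-angle mode SDs (8, 3, 1.5)°
  with 0.8° noise, symmetry (3, 1.5, 0.8)° with 0.3°, radial force
  (0.30, 0.12, 0.06) BW with 0.03 BW, speed (1.5, 0.5, 0.25) m/s with
  0.15 m/s — each noise SD is 10 % of the variable's first mode SD. Mean
  curves are bell-shaped for edge angle (peak 58° carving, 28° drifting —
  expert carving reaches such angles, and the separation lets the naive
  30°-threshold style rule work on generated turns) and radial force
  (≈ 0.7–1.2 BW by size), near-constant for speed (7/10/13 m/s for
  small/medium/large) and zero for symmetry.
* raw runs realise the pendulum model directly: piecewise-sinusoidal boot
  roll with alternating sign (peak 40°, so roll-rate pulses of ≈ 63 deg/s at
  a 2 s turn period), accelerometer channels consistent with that roll, yaw
  rate set by the size's speed and radius, GNSS speed at 1 Hz with an
  optional slow drift, and an optional injected slow turn to exercise the
  exclusion rule. Ground-truth boundary times, directions and mean speeds
  are attached for oracle tests.
* a scalar `skill_offset` shifts every mode-coefficient draw by that many
  mode SDs, emulating a population that differs systematically from the
  reference; offset 3 produces clearly lower scores, the package's analogue
  of an expert-versus-beginner contrast.

What the generator deliberately does **not** emulate: ski–snow interaction,
terrain, style-dependent waveform families beyond the mean-curve shifts,
packet loss, GNSS error, or cross-correlation between variables (each
variable draws independent coefficients). Passing the package's statistical
tests therefore shows that the chain recovers structure it is designed for —
not that it would reach any particular accuracy on real slopes; the
published system-level accuracies cannot be reproduced without the original
recordings, which are not deposited.

## Problem sizes and numerical choices

The statistical tests and the acceptance script use 200 turns per cell —
comfortably above the 10-turn minimum and enough for stable eigenstructure —
and 60 seeded replicates for the segmentation-reliability property. All
tolerances in the tests mirror the contracts: 1e-12 for arithmetic
identities, 1e-8 for decomposition equivalences, |cosine| ≥ 0.95 for mode
recovery, p < 0.01 for the skill-separation check. Degenerate inputs are
handled explicitly: all-equal speeds (MAD 0) remove nothing, constant
variable matrices fit as rank 0, straight glides classify as large with a
flag, and turns whose (style, size) cell is missing from the model come back
as unscorable results with a reason rather than errors.

## Known limitations

* Every enrichment is a simplified stand-in for a validated proprietary
  algorithm; absolute values (e.g. edge angle during aggressive skidding,
  when the accelerometer reference is corrupted by centripetal acceleration)
  carry that caveat.
* The naive style rule is a demonstration; real pipelines should pass
  external labels.
* The scoring scale rewards similarity to the chosen reference cohort. A
  reference of intermediate skiers would yield equally confident but
  differently meaning scores; picking the cohort is a modelling decision the
  package cannot make for the user.
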