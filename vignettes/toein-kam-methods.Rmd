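---
title: "Synthesizing toe-in gait and predicting KAM reduction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing toe-in gait and predicting KAM reduction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toeinkam)
```

## The problem

Medial knee osteoarthritis is aggravated by high joint loading during
walking. The external knee adduction moment (KAM) — the frontal-plane moment
the ground reaction force (GRF) exerts about the knee — is the standard
non-invasive surrogate of medial-compartment load, reported normalized to
body weight times height (%BW\*HT). Walking with the toes rotated inward
(toe-in gait) shifts the knee joint center (KJC) medially and the foot
center of pressure (FCP) laterally during early stance; both shifts shorten
the frontal-plane lever arm of the GRF and reduce the first of the KAM's two
stance-phase peaks.

Patients respond heterogeneously, and determining who benefits currently
requires a full instrumented gait analysis. This package implements a
workflow that (i) learns how the KJC and FCP trajectories change per degree
of toe-in from a cohort measured in both gaits, (ii) applies those learned
offset patterns to new subjects' *baseline-only* gait to synthesize toe-in
trials and the resulting KAM, and (iii) fits a linear model that predicts
first-peak KAM reduction from six features obtainable in a clinic: height,
weight, walking speed, static frontal-plane knee alignment, habitual foot
progression angle (FPA), and the target toe-in angle.

Because datasets containing both gaits for the same subjects are not
publicly available, the package includes a cohort simulator with a known
ground-truth response, and every stage is validated against that oracle.

## Conventions

Lab axes are X = mediolateral (positive toward the subject's right),
Y = anterior–posterior (positive along the walking direction),
Z = vertical up. The canonical side is the **left** leg, so medial = +X;
right-leg trials are mirrored (X negated) before any learning or synthesis.
FPA is the horizontal-plane angle between the walking direction and the
calcaneus→2nd-metatarsal-head vector, **toe-out positive**; the per-step
toe-in angle is θ = (subject's mean baseline FPA) − (step FPA), so θ > 0
means toeing in relative to habit. Positions are carried in mm, forces in N;
positions are converted to meters only inside the KAM computation. Valgus
(knock-kneed) static alignment is positive.

## Per-trial processing

Plate signals (GRF and COP — both originate from the force plate and are
treated identically) are low-pass filtered with a fourth-order zero-lag
Butterworth filter at 15 Hz. The implementation wraps `signal::butter`
coefficients in a forward–backward pass with odd-reflection padding and
steady-state initial conditions, so a constant signal is preserved exactly
and symmetric features keep their location — properties the tests assert
against the filter's transfer function. Marker channels are used as
recorded; the spline fit downstream provides their smoothing. Marker gaps of
at most 10 frames are filled by linear interpolation; a step whose stance
contains a longer gap is dropped.

Stance phases are rising/falling crossings of a 20 N vertical-GRF threshold
(the common treadmill convention; the detection rule is a package choice)
with a 5-frame debounce; partial phases touching the record edges and
phases outside 0.2–2.0 s are discarded, and steps whose stance sees more
than 20 N on the *other* belt's plate are rejected as not landing cleanly.
Each retained stance is resampled to 101 points (0–100% inclusive, so
"first half of stance" is exactly samples 1–51) by linear interpolation,
which avoids overshoot near the heel-strike transient.

The pelvis center is the centroid of the four iliac-crest markers; the KJC
is the femoral-epicondyle midpoint (with a configurable medial-offset
fallback when the medial marker is missing); both estimator choices are
package conventions exposed in the API. The per-step FPA is computed from
the foot markers averaged over 15–40% stance — the foot-flat window — since
the within-stance sampling instant is otherwise arbitrary.

## Learning the offset patterns

For each subject measured in both conditions, every toe-in step's four
pelvis-relative channels (KJC and FCP, mediolateral and anterior–posterior)
are expressed as offsets from that subject's mean baseline trajectory.
Steps are pooled across subjects (equal weight per step) into 1° bins,
k = 1..10, with bin k collecting θ ∈ [k − 0.5, k + 0.5) — the natural
round-to-nearest reading of "1° bins from 1° to 10°"; steps outside
[0.5, 10.5) are excluded. Bin averages are smoothed by least-squares basis
splines of order 12 (degree 11) on an open knot vector with no interior
knots — the smallest basis at which the residual against the raw bin mean
stops improving when the order is swept over 3–20; both the order and the
interior-knot count remain configurable. A bin empty across the whole
cohort is filled by linear inter-/extrapolation in the bin label from the
two nearest non-empty bins; for a response linear in θ this reconstruction
is exact, and the bin is flagged in the library's provenance.

Synthesis adds the curve for the requested integer angle to a new subject's
mean baseline channels. The mediolateral offsets are applied to the
lab-frame KJC and COP as well (the pelvis trajectory is taken as unchanged
by the intervention, and patterns modify only the ML/AP channels, so the
vertical lever-arm coordinate stays at baseline). GRF channels are copied
bit-for-bit: GRF magnitude does not change with toe-in, and the tests
assert the pass-through exactly. Angles outside the library's bins are
refused rather than extrapolated.

## KAM and its summaries

The quasi-static lever-arm estimate is used throughout: with
r = COP − KJC (m, lab frame), the adduction-positive frontal-plane moment
for the canonical left leg is

KAM = r_x F_z − r_z F_x,

i.e. the anterior–posterior component of r × F, sign-flipped so the moment
is positive when the GRF line passes medial to the knee. Both the
vertical-force and the mediolateral-shear term are included by default
(`include_shear_term` switches to the vertical-only variant, since
published lever-arm implementations differ). Moments are normalized as
100·M/(m·g·h) with g = 9.81 m/s². The first/second peaks are maxima over
0–50% and 50–100% of stance, and the impulse is the trapezoidal time
integral over the stance duration.

## The predictor

Synthesizing each subject at every angle 1–10° yields one entry per
subject × angle whose response is the first-peak reduction. Subjects —
never rows — are shuffled and partitioned 80/10/10 into train/validation/
test, so no subject's cycles appear in two sets. Features are z-scored with
training means/SDs only (the tests include a leakage guard), and ordinary
least squares with intercept is fit via `stats::lm`; standard errors come
from the residual variance and normal-equations inverse, with two-sided
t-tests on n − p − 1 degrees of freedom and no multiple-testing correction.
The validation split is reserved for configuration sweeps (spline order,
feature subsets); the reported metrics come from train and test. Evaluation
reports the MAE (±SD of absolute errors), both R² conventions (coefficient
of determination of the predictions, and R² of the best-fit line through
the actual-vs-predicted scatter — published figures often use the latter),
and the mean signed error with the convention actual − predicted,
aggregated per subject across angles and summarized with a t-based 95% CI.
Single-feature models (e.g. toe-in angle only) use the same interface.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates, per subject: clinical features drawn from a
recreational-adult cohort (height 171.6 ± 8.9 cm, weight 70.2 ± 12.4 kg,
walking speed 1.25 ± 0.15 m/s — a typical self-selected treadmill speed —
valgus 0 ± 3°, baseline FPA 3.97 ± 4.91°); a vertical GRF built from a
smooth trough base plus two Gaussian bumps, peaking near 1.1 BW at 25%/75%
stance with a 0.75 BW midstance trough; heel-to-toe COP progression; and
lab-frame KJC/COP geometry placed so the GRF line passes ~45 mm medial to
the knee at the first peak, giving baseline first-peak KAM near 3 %BW\*HT
with the first peak above the second — the adult pattern. The toe-in
response is linear in θ with early-stance-weighted slopes of +1.2 mm/°
(KJC medial) and −2.0 mm/° (FCP lateral); per-step θ is jittered (σ = 1°)
around subject targets that cycle the integers 1–10°, guaranteeing the
1–10° bins are populated the way the learning stage expects; position
channels carry 1 mm sample noise. `simulate_trial()` produces full-rate
(100/1000 Hz) marker + force recordings with analytically known
threshold-crossing event times for validating I/O, filtering and detection.

The simulator is deliberately *not* biofidelic: the response is exactly
linear and shared across subjects, GRF is step-noise-free and identical
between conditions, soft-tissue artifact and marker-placement variability
are absent, and the AP-direction errors that dominate real trajectory RMSEs
are not reproduced. Passing the recovery tests therefore demonstrates that
the estimators are correct and self-consistent — not that real cohorts
would yield errors this small. On real data, trajectory RMSEs an order of
magnitude larger are expected.

`simulate_feature_response()` bypasses the mechanics entirely and draws
responses exactly linear in the raw features (toe-in dominant by default),
providing the coefficient-recovery and CI-coverage oracle for the
predictor.

## Numerical choices and degenerate inputs

Spline fitting uses `splines::splineDesign` with `lm.fit`; the order-12
Bernstein-type basis on 101 points is well-conditioned (condition number
about 2×10³). Curve evaluation reproduces a constant to < 1e-6 mm.
Standardization refuses zero-variance features, and rank-deficient designs
raise a collinearity error naming the offending columns rather than
silently dropping them. A stance shorter than 10 frames, an empty cycle
list, an angle outside the library, a missing pattern bin, and artifact
version mismatches all raise typed errors (`toeinkam_value_error`,
`toeinkam_integrity_error`, `toeinkam_version_error`, ...) that the CLI maps
to documented exit codes. All randomness flows through explicit integer
seeds; rerunning any stage with the same configuration is bit-reproducible,
which the tests assert on the serialized artifacts.

Problem sizes used in the validation suite mirror the study design the
package targets: a 12-subject × 10-step pattern cohort, a 138-subject
baseline cohort synthesized at angles 1–10° (1380 entries), and
leave-one-out cross-validation over the pattern cohort. These sizes run the
whole pipeline in seconds.

## Known limitations

- The lever-arm KAM is quasi-static; link-segment inverse dynamics is out
  of scope (the two agree to ~5% on percent-change assessments of FPA
  interventions, which is the quantity of interest here).
- Patterns are pooled across subjects; per-subject response models and
  toe-out patterns (which target the second peak) are not implemented.
- Offsets are re-applied in the lab frame under a stationary-pelvis
  assumption; if an intervention altered pelvis sway substantially, the
  lab-frame transfer would bias the synthetic lever arm.
- The mediolateral-shear term's presence in the lever arm is configurable
  because published implementations are ambiguous; results in this package
  default to including it.
- Marker-gap handling is linear interpolation only; no kinematic gap
  filling is attempted.
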