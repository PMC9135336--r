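# toeinkam

Synthesizing toe-in gait from baseline walking and predicting knee
adduction moment (KAM) reduction from minimal clinical data.

## The problem

Medial knee osteoarthritis progresses under high joint loading. The
external knee adduction moment — the frontal-plane moment of the ground
reaction force (GRF) about the knee, normalized to percent body weight
times height (%BW\*HT) — is the standard surrogate of medial-compartment
load. Toe-in gait retraining reduces the first of the KAM's two
stance-phase peaks by moving the knee joint center (KJC) medially and the
foot center of pressure (FCP) laterally in early stance, which shortens
the GRF's lever arm. But responses vary between patients, and finding out
who benefits normally requires an instrumented gait lab.

`toeinkam` is for biomechanists and clinical-gait researchers who want to:

1. **learn** per-degree offset patterns of the pelvis-relative KJC/FCP
   trajectories between baseline and toe-in walking from a cohort measured
   in both gaits (1° bins from 1° to 10°, smoothed with order-12 basis
   splines, validated by leave-one-out cross-validation);
2. **synthesize** toe-in gait — and the resulting KAM — for subjects who
   only ever walked at baseline, by adding the learned offsets to their
   mean baseline trajectories while keeping their GRF unchanged;
3. **predict** the first-peak KAM reduction for a new patient from six
   clinical features: height, weight, walking speed, static knee alignment
   (valgus positive), habitual foot progression angle, and the target
   toe-in angle, using a standardized linear model trained on the
   synthetic entries.

The KAM is computed with the quasi-static **lever-arm method**: with
`r = COP − KJC` in the lab frame (meters) and adduction positive for the
canonical left leg,

```
KAM = r_x F_z − r_z F_x        [N·m],   %BW*HT = 100 · KAM / (m g h)
```

Since no public dataset pairs baseline and toe-in gait for the same
subjects, the package ships a treadmill-gait simulator with a known,
linear-in-angle ground-truth response; every stage of the pipeline is
validated against that oracle (see the methods vignette,
`vignettes/toein-kam-methods.Rmd`).

## Worked example

Learn patterns from a simulated 12-subject ground-truth cohort, synthesize
toe-in gait for a simulated 138-subject baseline-only cohort, and train
the predictor:

```r
library(toeinkam)

pattern_cohort <- simulate_cohort(sim_config(), seed = 1)
lib <- learn_patterns(pattern_cohort)
lib
#> <pattern_library> 4 channels x 10 bins (order-12 B-splines, 0 interior knots)
#>   learned from 12 subjects, 120 toe-in steps
#>   steps per bin: 1:24 2:14 3:13 4:7 5:8 6:11 7:9 8:10 9:12 10:12

clinic <- simulate_cohort(sim_config(n_subjects = 138), seed = 2,
                          with_toe_in = FALSE)
entries <- synthesize_cohort(clinic, lib)
entries
#> <synthetic_entries> 1380 entries (138 subjects x 10 angles)
#>   mean first-peak reduction 1.020 %BW*HT (range 0.140 to 1.711)

features <- split_by_subject(build_feature_table(entries, clinic), seed = 3)
fit <- fit_kam_model(features)
summary(fit)
#> Standardized linear model of first-peak KAM reduction (%BW*HT)
#> n = 1100, residual sigma = 0.1151 on 1093 df
#>
#> (Intercept)  1.0211
#>                      estimate   std_error  t_value p_value
#> height            -5.0028e-02  3.5720e-03 -14.0055  <2e-16 ***
#> weight            -3.6971e-05  3.5123e-03  -0.0105  0.9916
#> walking_speed      7.7847e-05  3.5054e-03   0.0222  0.9823
#> static_valgus_deg  1.4168e-03  3.5036e-03   0.4044  0.6860
#> baseline_fpa_deg  -9.0078e-06  3.5480e-03  -0.0025  0.9980
#> toe_in_deg         4.5913e-01  3.4721e-03 132.2349  <2e-16 ***

ev <- evaluate_predictions(fit, features[features$split == "test", ])
sprintf("test MAE %.3f %%BW*HT, R2 %.2f", ev$mae, ev$r2_fit)
#> "test MAE 0.098 %BW*HT, R2 0.94"

predict(fit, data.frame(height = 1.70, weight = 82, walking_speed = 1.2,
                        static_valgus_deg = -2, baseline_fpa_deg = 5,
                        toe_in_deg = 6))
#> 1.112947   # predicted first-peak reduction, %BW*HT
```

Reading the output: each entry is one subject at one toe-in angle; its
response is the drop in the first KAM peak from that subject's baseline
(1.02 %BW\*HT on average here — the simulator's response slopes are
deliberately strong). On the standardized scale the toe-in angle dominates
the fit (β = 0.459), as it should when the underlying response is linear
in the angle; a patient walking at 6° toe-in is predicted to shed about
1.1 %BW\*HT off their first peak. On real cohorts, expect smaller
reductions and weaker fits — the simulator omits soft-tissue artifact and
between-subject response heterogeneity (see the vignette).

Leave-one-out cross-validation of a pattern library:

```r
loocv_evaluate(pattern_cohort)
#> <loocv_report> 12 subjects
#>   kjc_ml_rmse_mm            0.495 (+/- 0.056)
#>   ...
#>   first_peak_mae_pbwht      0.068 (+/- 0.051)
```

A thin command-line wrapper with subcommands `simulate`, `learn-patterns`,
`loocv`, `synthesize`, `train`, `predict`, `evaluate` and `run-all` lives
at `inst/cli/toeinkam.R` (after installation:
`system.file("cli", "toeinkam.R", package = "toeinkam")`).

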