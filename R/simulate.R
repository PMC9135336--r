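# Synthetic treadmill-gait cohorts with known ground truth.
#
# The generator emulates the study conditions the pipeline is designed for:
# split-belt treadmill walking with a double-hump vertical GRF (peaks about
# 1.1 BW at 25%/75% stance, trough about 0.75 BW), heel-to-toe COP
# progression, pelvis-relative KJC/FCP trajectories of physiologic
# magnitude, and a toe-in response that shifts the knee joint center
# medially and the foot center of pressure laterally in early stance,
# linearly in the toe-in angle: delta_c(theta, t) = theta * g_c(t).

#' Simulation configuration
#'
#' Defaults describe a ground-truth-style cohort: 12 subjects, 10 steps per
#' condition, subject toe-in targets cycling the integers 1..10 degrees (so
#' the 1--10 degree bins are all populated), 1 mm step noise on position
#' channels, 1 degree per-step FPA jitter, and clinical feature
#' distributions following a recreational-adult cohort (height 171.6 +/-
#' 8.9 cm, weight 70.2 +/- 12.4 kg).
#'
#' @param n_subjects number of subjects.
#' @param steps_per_condition steps per subject per condition.
#' @param noise_mm per-sample Gaussian noise SD on position channels (mm).
#' @param fpa_jitter_deg per-step SD of the FPA / toe-in angle (degrees).
#' @param grf_peak_frac,grf_trough_frac vertical GRF peaks and midstance
#'   trough as fractions of body weight.
#' @param kjc_ml_slope,fcp_ml_slope,kjc_ap_slope,fcp_ap_slope ground-truth
#'   toe-in response slopes (mm per degree) applied with the early-stance
#'   weight; positive X is medial for the canonical left leg, so the
#'   defaults medialize the knee (+1.2) and lateralize the foot center of
#'   pressure (-2.0).
#' @param height_m_mean,height_m_sd,weight_kg_mean,weight_kg_sd,speed_mps_mean,speed_mps_sd,valgus_deg_mean,valgus_deg_sd,baseline_fpa_mean,baseline_fpa_sd
#'   clinical feature distributions.
#' @param stance_s_mean,stance_s_sd stance duration distribution (s).
#' @param marker_rate,force_rate sampling rates (Hz) for full-rate trials.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12L, steps_per_condition = 10L,
                       noise_mm = 1, fpa_jitter_deg = 1,
                       grf_peak_frac = 1.1, grf_trough_frac = 0.75,
                       kjc_ml_slope = 1.2, fcp_ml_slope = -2.0,
                       kjc_ap_slope = -0.8, fcp_ap_slope = -1.5,
                       height_m_mean = 1.716, height_m_sd = 0.089,
                       weight_kg_mean = 70.2, weight_kg_sd = 12.4,
                       speed_mps_mean = 1.25, speed_mps_sd = 0.15,
                       valgus_deg_mean = 0, valgus_deg_sd = 3,
                       baseline_fpa_mean = 3.97, baseline_fpa_sd = 4.91,
                       stance_s_mean = 0.7, stance_s_sd = 0.04,
                       marker_rate = 100, force_rate = 1000) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# early-stance weighting of the toe-in response (peaked at 25% stance)
early_stance_weight <- function(t_frac) exp(-((t_frac - 0.25) / 0.18)^2)

#' Ground-truth offset shapes of a configuration
#'
#' The tabulated 101-point response shapes `g_c(t)` (mm per degree of
#' toe-in) implied by the configuration's slopes -- the oracle against
#' which learned offset curves are compared.
#'
#' @param config a [sim_config()].
#' @return Named list of four length-101 vectors (`KJC_ML`, `KJC_AP`,
#'   `FCP_ML`, `FCP_AP`).
#' @export
truth_shapes <- function(config) {
  w <- early_stance_weight(seq(0, 1, length.out = N_STANCE_SAMPLES))
  list(KJC_ML = config$kjc_ml_slope * w,
       KJC_AP = config$kjc_ap_slope * w,
       FCP_ML = config$fcp_ml_slope * w,
       FCP_AP = config$fcp_ap_slope * w)
}

rnorm_clip <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

# vertical GRF shape (fraction of BW) over stance fraction t in [0, 1]:
# smooth trough base plus two Gaussian bumps at 25% and 75% stance
grf_v_shape <- function(t_frac, peak_frac, trough_frac) {
  h <- peak_frac - trough_frac * sin(pi * 0.25)
  pmax(0, trough_frac * sin(pi * t_frac) +
            h * (exp(-((t_frac - 0.25) / 0.09)^2) +
                 exp(-((t_frac - 0.75) / 0.09)^2)))
}

# deterministic per-subject baseline channel shapes over 101 stance points.
# Returns the lab-frame building blocks; pelvis-relative channels are
# derived as lab - pelvis so the two stay consistent.
baseline_shapes <- function(config, height_m, weight_kg) {
  t <- seq(0, 1, length.out = N_STANCE_SAMPLES)
  bw <- weight_kg * GRAVITY
  knee_z <- 0.28 * height_m * 1000
  list(
    t = t,
    pelvis_ml = -20 * sin(pi * t),
    pelvis_ap = 10 * sin(2 * pi * t),
    kjc_lab_ml = -110 + 8 * sin(pi * t),
    kjc_lab_ap = -120 + 300 * t,
    kjc_lab_z = knee_z + 10 * sin(2 * pi * t),
    cop_lab_ml = -65 + 10 * (t - 0.5),
    cop_lab_ap = -130 + 270 * t,
    cop_lab_z = rep(0, N_STANCE_SAMPLES),
    grf_ml = 0.02 * bw * sin(2 * pi * t),
    grf_ap = -0.15 * bw * sin(2 * pi * t),
    grf_v = bw * grf_v_shape(t, config$grf_peak_frac, config$grf_trough_frac)
  )
}

# one simulated stance cycle; theta = NA for baseline steps
sim_cycle <- function(config, shapes, truth, subject_id, condition, step_index,
                      baseline_fpa, theta, duration_s) {
  nz <- function() stats::rnorm(N_STANCE_SAMPLES, 0, config$noise_mm)
  off <- if (is.na(theta)) lapply(truth, function(g) 0 * g)
         else lapply(truth, function(g) theta * g)
  kjc_ml <- shapes$kjc_lab_ml + off$KJC_ML + nz()
  kjc_ap <- shapes$kjc_lab_ap + off$KJC_AP + nz()
  cop_ml <- shapes$cop_lab_ml + off$FCP_ML + nz()
  cop_ap <- shapes$cop_lab_ap + off$FCP_AP + nz()
  channels <- list(
    KJC_ML = kjc_ml - shapes$pelvis_ml,
    KJC_AP = kjc_ap - shapes$pelvis_ap,
    FCP_ML = cop_ml - shapes$pelvis_ml,
    FCP_AP = cop_ap - shapes$pelvis_ap,
    KJC_LAB_ML = kjc_ml, KJC_LAB_Z = shapes$kjc_lab_z,
    COP_LAB_ML = cop_ml, COP_LAB_Z = shapes$cop_lab_z,
    GRF_ML = shapes$grf_ml, GRF_AP = shapes$grf_ap, GRF_V = shapes$grf_v
  )
  fpa <- if (is.na(theta)) baseline_fpa else baseline_fpa - theta
  stance_cycle(subject_id = subject_id, condition = condition,
               step_index = step_index, channels = channels, fpa_deg = fpa,
               rel_toe_in_deg = if (is.na(theta)) NA_real_ else theta,
               duration_s = duration_s)
}

#' Simulate a gait cohort with known ground truth
#'
#' Samples clinical features per subject, builds baseline stance cycles
#' from the deterministic per-subject shapes plus step noise, and builds
#' toe-in cycles by adding `theta * g_c(t)` (plus noise) to the baseline
#' channels, with the per-step toe-in angle `theta` jittered around the
#' subject's target and truncated to `[0.5, 10.5)`. GRF channels are
#' identical between conditions (toe-in does not change GRF magnitude).
#' Baseline per-step FPA is jittered around the subject's habitual angle,
#' so the realized baseline-mean FPA (the reference toe-in is defined
#' against) varies as it would in practice.
#'
#' @param config a [sim_config()].
#' @param seed integer seed fixing the whole cohort.
#' @param with_toe_in generate toe-in cycles? (`FALSE` for baseline-only
#'   cohorts such as the synthesis target cohort.)
#' @return List of [subject_record]; attribute `truth` holds the response
#'   shapes ([truth_shapes()]) and the per-subject target angles.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L,
                            with_toe_in = TRUE) {
  set.seed(seed)
  n <- config$n_subjects
  truth <- truth_shapes(config)
  heights <- rnorm_clip(n, config$height_m_mean, config$height_m_sd, 1.40, 2.10)
  weights <- rnorm_clip(n, config$weight_kg_mean, config$weight_kg_sd, 40, 130)
  speeds  <- rnorm_clip(n, config$speed_mps_mean, config$speed_mps_sd, 0.7, 2.0)
  valgus  <- stats::rnorm(n, config$valgus_deg_mean, config$valgus_deg_sd)
  fpas    <- rnorm_clip(n, config$baseline_fpa_mean, config$baseline_fpa_sd, -12, 20)
  targets <- ((seq_len(n) - 1L) %% 10L) + 1L

  cohort <- vector("list", n)
  for (s in seq_len(n)) {
    shapes <- baseline_shapes(config, heights[s], weights[s])
    dur <- rnorm_clip(1, config$stance_s_mean, config$stance_s_sd, 0.4, 1.2)
    nst <- config$steps_per_condition
    base_fpa_steps <- fpas[s] + stats::rnorm(nst, 0, config$fpa_jitter_deg)
    baseline <- lapply(seq_len(nst), function(k)
      sim_cycle(config, shapes, truth, sprintf("S%03d", s), "baseline", k,
                base_fpa_steps[k], NA_real_,
                dur + stats::rnorm(1, 0, 0.01)))
    toe_in <- list()
    if (with_toe_in) {
      thetas <- rnorm_clip(nst, targets[s], config$fpa_jitter_deg, 0.5, 10.5 - 1e-9)
      toe_in <- lapply(seq_len(nst), function(k)
        sim_cycle(config, shapes, truth, sprintf("S%03d", s), "toe_in", k,
                  fpas[s], thetas[k], dur + stats::rnorm(1, 0, 0.01)))
    }
    # tag baseline cycles with the realized baseline-mean FPA
    base_mean_fpa <- mean(vapply(baseline, `[[`, 0, "fpa_deg"))
    baseline <- lapply(baseline, function(cy) {
      cy$rel_toe_in_deg <- NA_real_
      cy
    })
    cohort[[s]] <- subject_record(
      subject_id = sprintf("S%03d", s), height = heights[s],
      weight = weights[s], walking_speed = speeds[s],
      static_valgus_deg = valgus[s], baseline_fpa_deg = base_mean_fpa,
      baseline_cycles = baseline, toe_in_cycles = toe_in
    )
  }
  attr(cohort, "truth") <- list(shapes = truth, targets = targets,
                                config = config)
  cohort
}

#' Simulate one full-rate treadmill trial
#'
#' Generates a [gait_trial] with marker series at `marker_rate` and force
#' series at `force_rate`, alternating stance (known heel-strike/toe-off
#' times) and swing, with the other belt's plate loaded only during our
#' swing. Used to exercise the file I/O, filtering, stance detection and
#' cycle-extraction chain against known event times.
#'
#' @param config a [sim_config()].
#' @param subject_id identifier.
#' @param condition `"baseline"` or `"toe_in"`.
#' @param n_steps number of stance phases.
#' @param seed RNG seed.
#' @param height,weight,walking_speed,fpa_deg subject parameters; `fpa_deg`
#'   is the (constant) foot progression angle of the trial.
#' @return A [gait_trial]; attribute `events` holds the true heel-strike
#'   and toe-off times (s).
#' @export
simulate_trial <- function(config = sim_config(), subject_id = "S001",
                           condition = "baseline", n_steps = 5L, seed = 1L,
                           height = 1.72, weight = 70, walking_speed = 1.25,
                           fpa_deg = 4) {
  set.seed(seed)
  stance <- config$stance_s_mean
  swing <- 0.45
  lead <- 0.30  # quiet lead-in/out so no stance touches the record edges
  total <- lead + n_steps * (stance + swing) + lead
  ft <- seq(0, total, by = 1 / config$force_rate)
  mt <- seq(0, total, by = 1 / config$marker_rate)
  nf <- length(ft); nm <- length(mt)
  shapes <- baseline_shapes(config, height, weight)
  bw <- weight * GRAVITY

  hs_times <- lead + (seq_len(n_steps) - 1L) * (stance + swing)
  to_times <- hs_times + stance

  # stance fraction at each time (NA outside stance)
  stance_frac <- function(tt) {
    fr <- rep(NA_real_, length(tt))
    for (k in seq_len(n_steps)) {
      inside <- tt >= hs_times[k] & tt <= to_times[k]
      fr[inside] <- (tt[inside] - hs_times[k]) / stance
    }
    fr
  }
  interp_shape <- function(values, fr, fill = 0) {
    out <- rep(fill, length(fr))
    ok <- !is.na(fr)
    out[ok] <- stats::approx(seq(0, 1, length.out = N_STANCE_SAMPLES),
                             values, xout = fr[ok])$y
    out
  }
  ffr <- stance_frac(ft); mfr <- stance_frac(mt)
  grf <- cbind(interp_shape(shapes$grf_ml, ffr),
               interp_shape(shapes$grf_ap, ffr),
               interp_shape(shapes$grf_v, ffr))
  cop <- cbind(interp_shape(shapes$cop_lab_ml, ffr),
               interp_shape(shapes$cop_lab_ap, ffr),
               interp_shape(shapes$cop_lab_z, ffr))
  # other plate loaded between our steps (opposite belt), zero during stance
  other <- rep(0, nf)
  mid_sw <- to_times[-n_steps] + swing / 2
  for (ms in c(lead / 2, mid_sw))
    other <- other + 0.9 * bw * exp(-((ft - ms) / 0.08)^2)
  other[!is.na(ffr)] <- 0

  # markers: smooth lab trajectories; swing bridges between stances
  pel_ml <- interp_shape(shapes$pelvis_ml, mfr)
  pel_ap <- interp_shape(shapes$pelvis_ap, mfr)
  pel_z <- rep(0.55 * height * 1000, nm)
  kjc_ml <- interp_shape(shapes$kjc_lab_ml, mfr, fill = shapes$kjc_lab_ml[1L])
  kjc_ap <- interp_shape(shapes$kjc_lab_ap, mfr, fill = shapes$kjc_lab_ap[1L])
  kjc_z <- interp_shape(shapes$kjc_lab_z, mfr, fill = shapes$kjc_lab_z[1L])
  noise <- function() stats::rnorm(nm, 0, config$noise_mm)

  mkmat <- function(x, y, z) cbind(x + noise(), y + noise(), z + noise())
  v <- c(-sin(fpa_deg * pi / 180), cos(fpa_deg * pi / 180), 0) * 140
  calc <- c(-80, -60, 30)
  markers <- list(
    CALC = mkmat(rep(calc[1], nm), rep(calc[2], nm), rep(calc[3], nm)),
    MET2 = mkmat(rep(calc[1] + v[1], nm), rep(calc[2] + v[2], nm),
                 rep(calc[3] + v[3], nm)),
    LASI = mkmat(pel_ml - 110, pel_ap + 60, pel_z),
    RASI = mkmat(pel_ml + 110, pel_ap + 60, pel_z),
    LPSI = mkmat(pel_ml - 110, pel_ap - 60, pel_z),
    RPSI = mkmat(pel_ml + 110, pel_ap - 60, pel_z),
    LEPI = mkmat(kjc_ml - 40, kjc_ap, kjc_z),
    MEPI = mkmat(kjc_ml + 40, kjc_ap, kjc_z),
    LMAL = mkmat(rep(-100, nm), rep(0, nm), rep(80, nm)),
    HJC = mkmat(pel_ml - 90, pel_ap, pel_z - 20)
  )
  out <- gait_trial(subject_id = subject_id, condition = condition,
                    side = "left", markers = markers, grf = grf, cop = cop,
                    other_plate_fz = other, marker_rate = config$marker_rate,
                    force_rate = config$force_rate, height = height,
                    weight = weight, walking_speed = walking_speed)
  # detectable event times: where the continuous vertical-GRF shape crosses
  # the 20 N contact threshold (root-found, independent of any sampling)
  shape_n <- function(fr) bw * grf_v_shape(fr, config$grf_peak_frac,
                                           config$grf_trough_frac) - 20
  fr_on <- stats::uniroot(shape_n, c(1e-6, 0.25), tol = 1e-10)$root
  fr_off <- stats::uniroot(shape_n, c(0.75, 1 - 1e-6), tol = 1e-10)$root
  attr(out, "events") <- data.frame(
    heel_strike_s = hs_times, toe_off_s = to_times,
    detect_hs_s = hs_times + fr_on * stance,
    detect_to_s = hs_times + fr_off * stance)
  out
}

#' Simulate a feature table with a known linear response
#'
#' Direct oracle for the predictor: clinical features are sampled per
#' subject, each subject contributes one row per toe-in angle 1..10, and
#' the response is exactly linear in the raw features,
#' `y = beta0 + X beta_raw + eps`. The default raw-scale coefficients are
#' chosen so the toe-in angle dominates, valgus and weight contribute
#' negatively, and the rest are weak.
#'
#' @param n_subjects number of subjects (10 rows each).
#' @param seed RNG seed.
#' @param config feature distributions ([sim_config()]).
#' @param beta0 intercept (%BW*HT).
#' @param beta_raw named raw-scale coefficients for the six features.
#' @param sigma_y response noise SD (%BW*HT).
#' @return Feature table as from [build_feature_table()]; attribute
#'   `truth` records `beta0`, `beta_raw` and `sigma_y`.
#' @export
simulate_feature_response <- function(n_subjects = 138L, seed = 1L,
                                      config = sim_config(),
                                      beta0 = 0.1,
                                      beta_raw = c(height = -0.05,
                                                   weight = -0.0012,
                                                   walking_speed = 0.02,
                                                   static_valgus_deg = -0.005,
                                                   baseline_fpa_deg = -0.001,
                                                   toe_in_deg = 0.10),
                                      sigma_y = 0.05) {
  set.seed(seed)
  n <- n_subjects
  feats <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    height = rnorm_clip(n, config$height_m_mean, config$height_m_sd, 1.40, 2.10),
    weight = rnorm_clip(n, config$weight_kg_mean, config$weight_kg_sd, 40, 130),
    walking_speed = rnorm_clip(n, config$speed_mps_mean, config$speed_mps_sd, 0.7, 2.0),
    static_valgus_deg = stats::rnorm(n, config$valgus_deg_mean, config$valgus_deg_sd),
    baseline_fpa_deg = rnorm_clip(n, config$baseline_fpa_mean,
                                  config$baseline_fpa_sd, -12, 20)
  )
  rows <- merge(feats, data.frame(toe_in_deg = 1:10))
  rows <- rows[order(rows$subject_id, rows$toe_in_deg), ]
  rownames(rows) <- NULL
  X <- as.matrix(rows[, KAM_FEATURES])
  rows$reduction <- beta0 + as.numeric(X %*% beta_raw[KAM_FEATURES]) +
    stats::rnorm(nrow(rows), 0, sigma_y)
  attr(rows, "truth") <- list(beta0 = beta0, beta_raw = beta_raw,
                              sigma_y = sigma_y)
  rows
}
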