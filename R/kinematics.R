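# Frame conventions and marker-derived quantities.
#
# Lab axes: X = mediolateral (positive toward the subject's right),
# Y = anterior-posterior (positive = walking direction), Z = vertical up.
# Canonical side is LEFT, so medial = +X for the instrumented leg; right-leg
# trials are mirrored (X negated) before any learning or synthesis.

#' Mirror a trial into the canonical left-leg frame
#'
#' Left-side trials are returned unchanged. Right-side trials have every X
#' coordinate (markers, COP) and the X force component negated, and the side
#' relabeled `"left"`. Applying the operation twice on a left-relabelled
#' record is the identity.
#'
#' @param record a [gait_trial].
#' @return A [gait_trial] in the canonical frame.
#' @export
mirror_to_canonical <- function(record) {
  stopifnot(inherits(record, "gait_trial"))
  if (identical(record$side, "left")) return(record)
  if (!identical(record$side, "right")) abort_value("unknown side")
  record$markers <- lapply(record$markers, function(m) { m[, 1L] <- -m[, 1L]; m })
  record$grf[, 1L] <- -record$grf[, 1L]
  record$cop[, 1L] <- -record$cop[, 1L]
  record$side <- "left"
  record
}

#' Pelvis center from the four iliac-crest markers
#'
#' The centroid of the left/right anterior and posterior superior iliac
#' spine markers.
#'
#' @param lasi,rasi,lpsi,rpsi 3-vectors (mm).
#' @return 3-vector (mm). `NaN` inputs propagate so the enclosing step is
#'   dropped later.
#' @export
pelvis_center <- function(lasi, rasi, lpsi, rpsi) {
  (lasi + rasi + lpsi + rpsi) / 4
}

pelvis_center_series <- function(lasi, rasi, lpsi, rpsi) {
  (lasi + rasi + lpsi + rpsi) / 4
}

#' Express a trajectory relative to the pelvis center
#'
#' Per-frame subtraction keeping only the mediolateral (X) and
#' anterior-posterior (Y) components -- the two directions in which the
#' knee-joint-center and center-of-pressure offset patterns are learned.
#'
#' @param traj n-by-3 matrix (mm, lab frame).
#' @param pelvis n-by-3 matrix of pelvis-center positions (mm).
#' @return n-by-2 matrix with columns `ML`, `AP` (mm).
#' @export
to_pelvis_relative <- function(traj, pelvis) {
  traj <- as.matrix(traj); pelvis <- as.matrix(pelvis)
  if (nrow(traj) != nrow(pelvis)) abort_value("trajectory/pelvis length mismatch")
  out <- traj[, 1:2, drop = FALSE] - pelvis[, 1:2, drop = FALSE]
  colnames(out) <- c("ML", "AP")
  out
}

#' Foot progression angle
#'
#' Signed angle in the lab horizontal plane between the walking direction
#' (+Y) and the foot's long axis (calcaneus to 2nd metatarsal head),
#' positive for toe-out: for the canonical left leg the foot vector rotates
#' toward -X when toeing out, so `fpa = atan2(-vx, vy)` in degrees.
#'
#' @param calc,met2 3-vectors (mm) in the canonical left frame.
#' @return Angle in degrees (toe-out positive, toe-in negative).
#' @export
foot_progression_angle <- function(calc, met2) {
  v <- met2 - calc
  if (v[1L]^2 + v[2L]^2 < 1e-12) abort_value("zero-length horizontal foot vector")
  atan2(-v[1L], v[2L]) * 180 / pi
}

#' Toe-in angle relative to the subject's baseline
#'
#' The per-step toe-in magnitude is the subject's mean baseline FPA minus
#' the step FPA, so positive values mean toeing in relative to that
#' subject's habitual gait.
#'
#' @param step_fpa step FPA (degrees, toe-out positive).
#' @param baseline_mean_fpa subject's mean baseline FPA (degrees).
#' @return Relative toe-in angle in degrees (positive = toe-in).
#' @export
relative_toe_in_angle <- function(step_fpa, baseline_mean_fpa) {
  baseline_mean_fpa - step_fpa
}

#' Knee joint center from the femoral epicondyle markers
#'
#' Midpoint of the lateral and medial femoral epicondyle markers. When the
#' medial marker is absent (`NULL` or all-`NA`), falls back to offsetting
#' the lateral marker medially (+X in the canonical left frame) by half the
#' knee width.
#'
#' @param lepi,mepi 3-vectors (mm).
#' @param half_width_mm medial offset used by the fallback.
#' @return 3-vector (mm), with attribute `method` = `"midpoint"` or
#'   `"offset"`.
#' @export
knee_joint_center <- function(lepi, mepi = NULL, half_width_mm = 50) {
  if (is.null(mepi) || all(is.na(mepi))) {
    out <- lepi + c(half_width_mm, 0, 0)
    attr(out, "method") <- "offset"
    return(out)
  }
  out <- (lepi + mepi) / 2
  attr(out, "method") <- "midpoint"
  out
}

knee_joint_center_series <- function(lepi, mepi) {
  (lepi + mepi) / 2
}

#' Static frontal-plane knee alignment (valgus positive)
#'
#' From a static standing trial: the angle between the shank vector
#' (lateral malleolus to lateral epicondyle) and the thigh vector (lateral
#' epicondyle to hip joint center), projected onto the frontal (X, Z)
#' plane. For the canonical left leg a knee that sits medial to the
#' ankle--hip line (knock-kneed) gives a positive, valgus, angle.
#'
#' @param lmal,lepi,hjc 3-vectors (mm) in the canonical left frame.
#' @return Angle in degrees (valgus positive, varus negative).
#' @export
static_valgus_angle <- function(lmal, lepi, hjc) {
  a <- lepi - lmal
  b <- hjc - lepi
  ax <- a[1L]; az <- a[3L]; bx <- b[1L]; bz <- b[3L]
  if (ax^2 + az^2 < 1e-12 || bx^2 + bz^2 < 1e-12)
    abort_value("zero-length projected segment vector")
  atan2(ax * bz - az * bx, ax * bx + az * bz) * 180 / pi
}
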