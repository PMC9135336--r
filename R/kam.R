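# Frontal-plane external knee moment via the quasi-static lever-arm method,
# normalization to %BW*HT, and stance-trace summaries.

#' Lever-arm knee adduction moment
#'
#' Quasi-static frontal-plane external moment about the knee: with lever
#' arm `r = cop - kjc` (meters, lab frame), the moment about the
#' anterior-posterior axis is `rx * Fz - rz * Fx`, i.e. the AP component of
#' `r x F` with the sign flipped so that adduction is positive for the
#' canonical left leg (positive when the GRF line passes medial to the
#' knee). The default includes both the vertical-force and the
#' mediolateral-shear term; set `include_shear_term = FALSE` for the
#' vertical-only approximation.
#'
#' @param kjc_lab knee joint center, 3-vector (m, lab frame).
#' @param cop_lab center of pressure, 3-vector (m, lab frame).
#' @param grf ground reaction force, 3-vector (N).
#' @param include_shear_term include the `-rz * Fx` shear term?
#' @return Moment in N·m (adduction positive).
#' @examples
#' lever_arm_kam(c(-0.05, 0, 0.45), c(0, 0, 0), c(0, 0, 700))  # 35 N*m
#' @export
lever_arm_kam <- function(kjc_lab, cop_lab, grf, include_shear_term = TRUE) {
  r <- cop_lab - kjc_lab
  m <- r[1L] * grf[3L]
  if (include_shear_term) m <- m - r[3L] * grf[1L]
  m
}

# vectorized over 101-point lab-frame channels (mm in, %BW*HT out)
kam_trace_from_channels <- function(channels, mass_kg, height_m,
                                    include_shear_term = TRUE) {
  rx <- (channels$COP_LAB_ML - channels$KJC_LAB_ML) / 1000
  rz <- (channels$COP_LAB_Z - channels$KJC_LAB_Z) / 1000
  m <- rx * channels$GRF_V
  if (include_shear_term) m <- m - rz * channels$GRF_ML
  normalize_moment(m, mass_kg, height_m)
}

#' Normalize a knee moment to %BW*HT
#'
#' `100 * moment / (mass * g * height)` with `g` = 9.81 m/s² -- the
#' standard body-weight-times-height normalization under which first-peak
#' KAM values are reported.
#'
#' @param moment moment(s) in N·m (vectorized).
#' @param mass body mass (kg).
#' @param height body height (m).
#' @return Moment in %BW*HT.
#' @examples
#' normalize_moment(35, 70, 1.70)  # about 3 %BW*HT
#' @export
normalize_moment <- function(moment, mass, height) {
  check_scalar_num(mass, "mass", lower = 1e-9)
  check_scalar_num(height, "height", lower = 1e-9)
  100 * moment / (mass * GRAVITY * height)
}

#' Summarize a KAM stance trace
#'
#' Extracts the first peak (maximum over 0--50% stance), the second peak
#' (maximum over 50--100%), and the impulse (trapezoidal time integral over
#' the stance duration).
#'
#' @param values 101-point KAM trace (%BW*HT).
#' @param duration_s stance duration (s).
#' @return An object of class `kam_trace` with fields `values`,
#'   `first_peak`, `second_peak`, `impulse`, `duration_s`.
#' @export
kam_summary <- function(values, duration_s) {
  values <- as.numeric(values)
  if (length(values) != N_STANCE_SAMPLES)
    abort_value("KAM trace must have exactly 101 samples")
  check_scalar_num(duration_s, "duration_s", lower = 0)
  dt <- duration_s / (N_STANCE_SAMPLES - 1L)
  impulse <- sum((values[-1L] + values[-N_STANCE_SAMPLES]) / 2) * dt
  structure(list(
    values = values,
    first_peak = max(values[1:51]),
    second_peak = max(values[51:101]),
    impulse = impulse,
    duration_s = duration_s
  ), class = "kam_trace")
}

#' @export
print.kam_trace <- function(x, ...) {
  cat(sprintf("<kam_trace> first peak %.3f, second peak %.3f %%BW*HT; impulse %.3f %%BW*HT*s over %.3f s\n",
              x$first_peak, x$second_peak, x$impulse, x$duration_s))
  invisible(x)
}

#' @export
plot.kam_trace <- function(x, ...) {
  graphics::plot(0:100, x$values, type = "l", xlab = "% stance",
                 ylab = "KAM (%BW*HT)", ...)
  graphics::abline(v = 50, lty = 3)
  graphics::points(c(which.max(x$values[1:51]) - 1,
                     49 + which.max(x$values[51:101])),
                   c(x$first_peak, x$second_peak), pch = 19)
  invisible(x)
}

# KAM trace of one stance cycle, as a kam_trace object
cycle_kam <- function(cycle, mass_kg, height_m, include_shear_term = TRUE) {
  kam_summary(kam_trace_from_channels(cycle$channels, mass_kg, height_m,
                                      include_shear_term),
              cycle$duration_s)
}
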