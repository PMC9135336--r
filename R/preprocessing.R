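# Force filtering, stance detection, step rejection and 101-point
# time-normalization.

#' Zero-lag Butterworth low-pass filter
#'
#' Fourth-order (by default) Butterworth low-pass applied forward and
#' backward so the net filter has zero phase lag. The signal is extended at
#' both ends by odd reflection and each pass starts from steady-state
#' initial conditions, so a constant signal passes through exactly and edge
#' transients are suppressed.
#'
#' @param x numeric signal.
#' @param rate sampling rate (Hz); must exceed twice `cutoff`.
#' @param cutoff cutoff frequency (Hz); 15 Hz is the treadmill force-plate
#'   convention used throughout the package.
#' @param order filter order for each pass.
#' @return Filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1/1000)
#' noisy <- sin(2 * pi * 2 * t) + 0.1 * sin(2 * pi * 50 * t)
#' smooth <- lowpass_filter(noisy, rate = 1000)
#' @export
lowpass_filter <- function(x, rate, cutoff = 15, order = 4) {
  check_scalar_num(rate, "rate", lower = 1e-9)
  check_scalar_num(cutoff, "cutoff", lower = 1e-9)
  if (rate <= 2 * cutoff) abort_value("rate must exceed twice the cutoff")
  n <- length(x)
  if (n <= 3L * order) abort_value("signal too short to filter")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  npad <- min(n - 1L, 3L * (order + 1L))
  xp <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  one_pass <- function(v)
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1L], order),
                              init.y = rep(v[1L], order)))
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Detect stance phases from vertical ground reaction force
#'
#' Heel strike and toe-off are the rising and falling crossings of a force
#' threshold (20 N by default, the common treadmill convention), with a
#' debounce: a crossing only counts if the signal stays on the new side for
#' at least `debounce` frames. Partial phases at the edges of the recording
#' and phases outside the physiologic duration range are discarded.
#'
#' @param grf_v vertical GRF (N), already low-pass filtered.
#' @param rate sampling rate (Hz).
#' @param threshold contact threshold (N).
#' @param debounce minimum frames on the new side of the threshold.
#' @param min_duration_s,max_duration_s admissible stance durations (s).
#' @return A data frame with columns `heel_strike_idx`, `toe_off_idx`,
#'   `duration_s` (possibly zero rows).
#' @export
detect_stance_phases <- function(grf_v, rate, threshold = 20, debounce = 5L,
                                 min_duration_s = 0.2, max_duration_s = 2.0) {
  check_scalar_num(rate, "rate", lower = 1e-9)
  n <- length(grf_v)
  on <- grf_v >= threshold
  if (!any(on))
    return(data.frame(heel_strike_idx = integer(), toe_off_idx = integer(),
                      duration_s = numeric()))
  # run-length encode contact state, then drop runs shorter than the debounce
  # by merging them into the previous run
  r <- rle(on)
  keep_len <- r$lengths
  keep_val <- r$values
  i <- 2L
  while (i <= length(keep_len)) {
    if (keep_len[i] < debounce && i < length(keep_len)) {
      # absorb the short run and the following run into the previous state
      keep_len[i - 1L] <- keep_len[i - 1L] + keep_len[i] + keep_len[i + 1L]
      keep_len <- keep_len[-c(i, i + 1L)]
      keep_val <- keep_val[-c(i, i + 1L)]
    } else i <- i + 1L
  }
  ends <- cumsum(keep_len)
  starts <- ends - keep_len + 1L
  hs <- starts[keep_val]
  to <- ends[keep_val]
  # partial phases at the edges: contact at the very first or last frame
  edge <- (hs == 1L) | (to == n)
  hs <- hs[!edge]; to <- to[!edge]
  dur <- (to - hs) / rate
  ok <- dur >= min_duration_s & dur <= max_duration_s
  data.frame(heel_strike_idx = hs[ok], toe_off_idx = to[ok], duration_s = dur[ok])
}

#' Did a step land cleanly on its own force plate?
#'
#' A step is clean when the vertical force on the *other* belt's plate stays
#' below the contact threshold for the whole stance, i.e. the foot never
#' straddled both plates.
#'
#' @param event one row of [detect_stance_phases()] output (list or
#'   single-row data frame with `heel_strike_idx`, `toe_off_idx`).
#' @param other_plate_fz vertical force series of the other plate (N).
#' @param threshold contact threshold (N).
#' @return `TRUE` if the step is clean.
#' @export
is_clean_step <- function(event, other_plate_fz, threshold = 20) {
  i0 <- event$heel_strike_idx; i1 <- event$toe_off_idx
  if (i0 < 1L || i1 > length(other_plate_fz))
    abort_value("event outside the other-plate series bounds")
  all(other_plate_fz[i0:i1] < threshold)
}

#' Resample one stance phase to 101 points
#'
#' Linearly interpolates a channel onto 101 evenly spaced points from heel
#' strike (0% stance) to toe-off (100% stance) inclusive, so sample `i + 1`
#' is exactly `i`% stance and "first half of stance" is samples 1..51.
#'
#' @param channel numeric channel sampled at the same rate as the event
#'   indices refer to.
#' @param event list/row with `heel_strike_idx` and `toe_off_idx` (may be
#'   fractional for channels resampled from another rate).
#' @return Numeric vector of length 101.
#' @export
time_normalize_stance <- function(channel, event) {
  i0 <- event$heel_strike_idx; i1 <- event$toe_off_idx
  if (i1 <= i0) abort_value("toe_off_idx must exceed heel_strike_idx")
  if ((i1 - i0) < 9) abort_value("stance too short to normalize (< 10 frames)")
  idx <- seq(i0, i1, length.out = N_STANCE_SAMPLES)
  stats::approx(x = seq_along(channel), y = channel, xout = idx,
                method = "linear", rule = 1)$y
}

# Linear interpolation over short marker gaps (NaN runs <= max_gap frames).
# Longer gaps are left as NA so the enclosing step is dropped downstream.
fill_marker_gaps <- function(m, max_gap = 10L) {
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    nas <- is.na(v)
    if (!any(nas) || all(nas)) next
    r <- rle(nas)
    pos <- cumsum(r$lengths) - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k] || r$lengths[k] > max_gap) next
      a <- pos[k] - 1L; b <- pos[k] + r$lengths[k]
      if (a < 1L || b > length(v)) next  # edge gap: leave NA
      v[pos[k]:(b - 1L)] <- v[a] + (v[b] - v[a]) * seq_len(r$lengths[k]) / (b - a)
    }
    m[, j] <- v
  }
  m
}

#' Extract step-normalized stance cycles from a raw trial
#'
#' Runs the whole per-trial chain: mirror right-side trials into the
#' canonical left frame, low-pass filter the plate signals, detect stance
#' phases on the vertical GRF, reject steps that touch the other plate or
#' contain unfilled marker gaps, and resample all channels of each clean
#' step to 101 points. Pelvis-relative knee-joint-center and
#' center-of-pressure channels and the per-step foot progression angle are
#' computed on the way.
#'
#' @param record a [gait_trial].
#' @param cutoff_hz force low-pass cutoff (Hz).
#' @param threshold_n stance detection threshold (N).
#' @param fpa_window within-stance window (fractions of stance) over which
#'   the foot markers are averaged to compute the step FPA; the default
#'   15--40% is the foot-flat portion.
#' @param max_gap_frames longest marker gap (frames) filled by linear
#'   interpolation; steps containing longer gaps are dropped.
#' @return List of [stance_cycle] (rel_toe_in_deg left `NA`; it is assigned
#'   once the subject's baseline mean FPA is known, see [make_subject_record()]).
#' @export
extract_cycles <- function(record, cutoff_hz = 15, threshold_n = 20,
                           fpa_window = c(0.15, 0.40), max_gap_frames = 10L) {
  record <- mirror_to_canonical(record)
  markers <- lapply(record$markers, fill_marker_gaps, max_gap = max_gap_frames)
  grf_f <- apply(record$grf, 2L, lowpass_filter, rate = record$force_rate,
                 cutoff = cutoff_hz)
  cop_f <- apply(record$cop, 2L, lowpass_filter, rate = record$force_rate,
                 cutoff = cutoff_hz)
  events <- detect_stance_phases(grf_f[, 3L], record$force_rate,
                                 threshold = threshold_n)
  if (!nrow(events)) return(list())

  pelvis <- pelvis_center_series(markers$LASI, markers$RASI,
                                 markers$LPSI, markers$RPSI)
  kjc <- knee_joint_center_series(markers$LEPI, markers$MEPI)
  ratio <- record$marker_rate / record$force_rate

  cycles <- list()
  for (s in seq_len(nrow(events))) {
    ev <- events[s, ]
    if (!is_clean_step(ev, record$other_plate_fz, threshold = threshold_n)) next
    # marker-frame indices (fractional) corresponding to the force-frame event
    mev <- list(heel_strike_idx = 1 + (ev$heel_strike_idx - 1) * ratio,
                toe_off_idx     = 1 + (ev$toe_off_idx - 1) * ratio)
    # unfilled marker gap anywhere in this stance: drop the step (checked on
    # the raw frames; interpolation must not bridge long gaps)
    span <- max(1L, floor(mev$heel_strike_idx)):min(nrow(kjc),
                                                    ceiling(mev$toe_off_idx))
    if (anyNA(kjc[span, ]) || anyNA(pelvis[span, ])) next
    norm_m <- function(v) time_normalize_stance(v, mev)
    norm_f <- function(v) time_normalize_stance(v, ev)

    kjc_n <- apply(kjc, 2L, norm_m)
    pel_n <- apply(pelvis, 2L, norm_m)
    cop_n <- apply(cop_f, 2L, norm_f)
    grf_n <- apply(grf_f, 2L, norm_f)

    calc_w <- colMeans(window_rows(markers$CALC, mev, fpa_window))
    met2_w <- colMeans(window_rows(markers$MET2, mev, fpa_window))
    if (anyNA(calc_w) || anyNA(met2_w)) next
    fpa <- foot_progression_angle(calc_w, met2_w)

    channels <- list(
      KJC_ML = kjc_n[, 1L] - pel_n[, 1L],
      KJC_AP = kjc_n[, 2L] - pel_n[, 2L],
      FCP_ML = cop_n[, 1L] - pel_n[, 1L],
      FCP_AP = cop_n[, 2L] - pel_n[, 2L],
      KJC_LAB_ML = kjc_n[, 1L], KJC_LAB_Z = kjc_n[, 3L],
      COP_LAB_ML = cop_n[, 1L], COP_LAB_Z = cop_n[, 3L],
      GRF_ML = grf_n[, 1L], GRF_AP = grf_n[, 2L],
      GRF_V = pmax(grf_n[, 3L], 0)
    )
    cycles[[length(cycles) + 1L]] <- stance_cycle(
      subject_id = record$subject_id, condition = record$condition,
      step_index = s, channels = channels, fpa_deg = fpa,
      duration_s = ev$duration_s
    )
  }
  cycles
}

# rows of a marker matrix inside a within-stance window given (possibly
# fractional) marker-frame event indices
window_rows <- function(m, mev, window) {
  span <- mev$toe_off_idx - mev$heel_strike_idx
  lo <- mev$heel_strike_idx + window[1L] * span
  hi <- mev$heel_strike_idx + window[2L] * span
  m[max(1L, ceiling(lo)):min(nrow(m), floor(hi)), , drop = FALSE]
}

#' Assemble a subject record from extracted cycles
#'
#' Computes the subject's mean baseline FPA, tags every cycle with its
#' toe-in angle relative to that baseline mean, and bundles the clinical
#' features into a [subject_record].
#'
#' @param subject_id identifier.
#' @param baseline_cycles,toe_in_cycles lists of [stance_cycle] from
#'   [extract_cycles()].
#' @param height,weight,walking_speed,static_valgus_deg clinical features.
#' @return A [subject_record].
#' @export
make_subject_record <- function(subject_id, baseline_cycles,
                                toe_in_cycles = list(), height, weight,
                                walking_speed, static_valgus_deg = 0) {
  if (!length(baseline_cycles)) abort_value("no baseline cycles")
  base_fpa <- mean(vapply(baseline_cycles, `[[`, 0, "fpa_deg"))
  tag <- function(cy) {
    cy$rel_toe_in_deg <- relative_toe_in_angle(cy$fpa_deg, base_fpa)
    cy
  }
  subject_record(
    subject_id = subject_id, height = height, weight = weight,
    walking_speed = walking_speed, static_valgus_deg = static_valgus_deg,
    baseline_fpa_deg = base_fpa,
    baseline_cycles = lapply(baseline_cycles, tag),
    toe_in_cycles = lapply(toe_in_cycles, tag)
  )
}
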