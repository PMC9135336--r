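# Applying a learned pattern library to baseline gait to synthesize toe-in
# trials and the resulting KAM.

#' Pointwise mean of stance cycles
#'
#' Averages every channel (and the duration and FPA tags) across a list of
#' cycles from one subject/condition.
#'
#' @param cycles non-empty list of [stance_cycle].
#' @return A [stance_cycle] whose channels are the pointwise means.
#' @export
baseline_mean_cycle <- function(cycles) {
  if (!length(cycles)) abort_value("empty cycle list")
  ch <- lapply(CYCLE_CHANNELS, function(cname)
    rowMeans(vapply(cycles, function(cy) cy$channels[[cname]], numeric(N_STANCE_SAMPLES))))
  names(ch) <- CYCLE_CHANNELS
  rel <- vapply(cycles, `[[`, 0, "rel_toe_in_deg")
  stance_cycle(
    subject_id = cycles[[1L]]$subject_id, condition = cycles[[1L]]$condition,
    step_index = 0L, channels = ch,
    fpa_deg = mean(vapply(cycles, `[[`, 0, "fpa_deg")),
    rel_toe_in_deg = if (all(is.na(rel))) NA_real_ else mean(rel, na.rm = TRUE),
    duration_s = mean(vapply(cycles, `[[`, 0, "duration_s"))
  )
}

#' Synthesize a toe-in cycle from a baseline mean cycle
#'
#' Adds the library's offset curves for the requested toe-in angle to the
#' four pelvis-relative channels. The lab-frame knee-joint-center and
#' center-of-pressure channels used for the lever-arm KAM are shifted by
#' the same mediolateral offsets (the pelvis trajectory is assumed
#' unchanged by the intervention); the vertical coordinates and all GRF
#' channels are copied from baseline unchanged, since GRF magnitude does
#' not change with toe-in gait.
#'
#' @param baseline_mean the subject's mean baseline [stance_cycle].
#' @param library a [pattern_library][learn_patterns()].
#' @param toe_in_deg integer toe-in angle; must be one of the library's
#'   bins (no extrapolation).
#' @return A synthetic toe-in [stance_cycle].
#' @export
apply_pattern <- function(baseline_mean, library, toe_in_deg) {
  if (!(toe_in_deg %in% library$bins))
    abort_integrity(sprintf("toe-in angle %s outside the library bins [%d, %d]",
                            toe_in_deg, min(library$bins), max(library$bins)))
  off <- lapply(PATTERN_CHANNELS, function(ch)
    predict(library, ch, toe_in_deg, at = 0:100))
  names(off) <- PATTERN_CHANNELS
  ch <- baseline_mean$channels
  for (cname in PATTERN_CHANNELS) ch[[cname]] <- ch[[cname]] + off[[cname]]
  ch$KJC_LAB_ML <- ch$KJC_LAB_ML + off$KJC_ML
  ch$COP_LAB_ML <- ch$COP_LAB_ML + off$FCP_ML
  out <- baseline_mean
  out$condition <- "toe_in"
  out$channels <- ch
  out$rel_toe_in_deg <- as.numeric(toe_in_deg)
  out$fpa_deg <- baseline_mean$fpa_deg - toe_in_deg
  out
}

#' Synthesize toe-in entries for a whole cohort
#'
#' For every subject, averages the baseline cycles, applies the pattern
#' library at each requested toe-in angle, computes baseline and synthetic
#' KAM with the lever-arm method, and records the first-peak reduction --
#' the response variable of the predictive model.
#'
#' @param subjects list of [subject_record] (baseline cycles required).
#' @param library a [pattern_library][learn_patterns()].
#' @param bins integer toe-in angles to synthesize (default 1..10).
#' @param include_shear_term passed to the KAM computation.
#' @return A `synthetic_entries` object: data frame with one row per
#'   subject x angle (`subject_id, toe_in_deg, baseline_first_peak,
#'   synthetic_first_peak, reduction, second_peak_change, impulse_change`,
#'   all KAM quantities in %BW*HT) and, in attribute `cycles`, the
#'   synthetic cycles keyed `subject_id.angle`.
#' @export
synthesize_cohort <- function(subjects, library, bins = 1:10,
                              include_shear_term = TRUE) {
  rows <- vector("list", length(subjects) * length(bins))
  cycles <- list()
  k <- 0L
  for (subj in subjects) {
    bm <- baseline_mean_cycle(subj$baseline_cycles)
    base_kam <- cycle_kam(bm, subj$weight, subj$height, include_shear_term)
    for (b in bins) {
      synth <- apply_pattern(bm, library, b)
      syn_kam <- cycle_kam(synth, subj$weight, subj$height, include_shear_term)
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = subj$subject_id, toe_in_deg = as.integer(b),
        baseline_first_peak = base_kam$first_peak,
        synthetic_first_peak = syn_kam$first_peak,
        reduction = base_kam$first_peak - syn_kam$first_peak,
        second_peak_change = syn_kam$second_peak - base_kam$second_peak,
        impulse_change = syn_kam$impulse - base_kam$impulse
      )
      cycles[[paste(subj$subject_id, b, sep = ".")]] <- synth
    }
  }
  entries <- do.call(rbind, rows)
  attr(entries, "cycles") <- cycles
  class(entries) <- c("synthetic_entries", "data.frame")
  entries
}

#' @export
print.synthetic_entries <- function(x, ...) {
  cat(sprintf("<synthetic_entries> %d entries (%d subjects x %d angles)\n",
              nrow(x), length(unique(x$subject_id)),
              length(unique(x$toe_in_deg))))
  cat(sprintf("  mean first-peak reduction %.3f %%BW*HT (range %.3f to %.3f)\n",
              mean(x$reduction), min(x$reduction), max(x$reduction)))
  invisible(x)
}
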