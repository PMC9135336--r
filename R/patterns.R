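# Learning per-degree-bin offset curves of pelvis-relative KJC/FCP
# trajectories between toe-in and baseline gait, smoothed with basis
# splines, and leave-one-out cross-validation of the learned library.

#' Per-step trajectory offsets from the subject's baseline mean
#'
#' The toe-in step's pelvis-relative channels minus the subject's average
#' baseline channels, pointwise over 0--100% stance. These offsets are what
#' the pattern library is learned on.
#'
#' @param toe_in_cycle a [stance_cycle] from toe-in walking.
#' @param baseline_mean the subject's mean baseline cycle
#'   ([baseline_mean_cycle()]).
#' @return Named list of four length-101 offset vectors (mm):
#'   `KJC_ML`, `KJC_AP`, `FCP_ML`, `FCP_AP`.
#' @export
compute_step_offsets <- function(toe_in_cycle, baseline_mean) {
  out <- lapply(PATTERN_CHANNELS, function(ch) {
    a <- toe_in_cycle$channels[[ch]]; b <- baseline_mean$channels[[ch]]
    if (is.null(a) || is.null(b)) abort_value(paste("missing channel", ch))
    a - b
  })
  names(out) <- PATTERN_CHANNELS
  out
}

#' Assign a relative toe-in angle to its 1-degree bin
#'
#' Bin `k` collects angles in `[k - 0.5, k + 0.5)` for `k` = 1..10
#' (rounding to the nearest degree); angles outside `[0.5, 10.5)` are
#' outside the learned range and return `NA`.
#'
#' @param theta relative toe-in angle (degrees, positive = toe-in).
#' @return Integer bin 1..10, or `NA`.
#' @export
assign_bin <- function(theta) {
  k <- floor(theta + 0.5)
  ifelse(is.finite(theta) & k >= 1 & k <= 10, as.integer(k), NA_integer_)
}

# open knot vector over [0, 100] for a B-spline of the given order with
# n_interior equally spaced interior knots
spline_knots <- function(order, n_interior = 0L) {
  interior <- if (n_interior > 0L)
    seq(0, 100, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  else numeric()
  c(rep(0, order), interior, rep(100, order))
}

# evaluate a stored offset curve at stance percents x
eval_curve <- function(curve, x = 0:100) {
  ord <- length(curve$knots) - length(curve$coefs)
  B <- splines::splineDesign(curve$knots, x, ord = ord)
  as.numeric(B %*% curve$coefs)
}

#' Fit the smoothed offset curve of one (channel, bin) cell
#'
#' Averages the step offsets pointwise across steps, then fits a
#' least-squares basis spline over 0--100% stance. The default basis is
#' order 12 (degree 11) on an open knot vector with no interior knots --
#' twelve basis functions, the smallest basis at which the residual against
#' the raw bin mean stops decreasing in the 3--20 order sweep.
#'
#' @param offsets list of length-101 offset vectors (mm) for one channel
#'   and bin.
#' @param bin_deg integer bin label (1..10).
#' @param channel one of `KJC_ML, KJC_AP, FCP_ML, FCP_AP`.
#' @param order B-spline order (= degree + 1).
#' @param n_interior_knots number of equally spaced interior knots.
#' @return An `offset_curve`: list with `channel`, `bin_deg`, `knots`,
#'   `coefs` (mm), `n_steps`.
#' @export
fit_bin_curve <- function(offsets, bin_deg, channel, order = 12,
                          n_interior_knots = 0L) {
  if (!length(offsets)) abort_value(sprintf("empty bin %d for channel %s",
                                            bin_deg, channel))
  avg <- Reduce(`+`, offsets) / length(offsets)
  knots <- spline_knots(order, n_interior_knots)
  B <- splines::splineDesign(knots, 0:100, ord = order)
  coefs <- lm.fit(B, avg)$coefficients
  structure(list(channel = channel, bin_deg = as.integer(bin_deg),
                 knots = knots, coefs = unname(coefs),
                 n_steps = length(offsets), interpolated = FALSE),
            class = "offset_curve")
}

new_pattern_library <- function(curves, spline_order, n_interior_knots,
                                bins, provenance) {
  structure(list(curves = curves, spline_order = spline_order,
                 n_interior_knots = n_interior_knots, bins = bins,
                 provenance = provenance),
            class = "pattern_library")
}

#' Learn a toe-in pattern library from a ground-truth cohort
#'
#' For every subject with both baseline and toe-in trials, computes each
#' toe-in step's offset from that subject's mean baseline trajectory
#' ([compute_step_offsets()]), labels it by the step's relative toe-in
#' angle, pools all subjects' steps into 1-degree bins from 1 to 10
#' degrees, averages within each bin, and smooths each (channel, bin)
#' average with a basis spline ([fit_bin_curve()]). Steps with angles
#' outside `[0.5, 10.5)` degrees are excluded. A bin empty across the whole
#' cohort is filled by linear inter-/extrapolation in the bin label from
#' the two nearest non-empty bins and flagged in the provenance.
#'
#' @param cohort list of [subject_record] with non-empty `toe_in_cycles`.
#' @param order B-spline order.
#' @param n_interior_knots interior knots for the spline basis.
#' @param bins integer bins to learn (default 1..10).
#' @return A `pattern_library`: S3 object holding one `offset_curve` per
#'   (channel, bin), the spline configuration, and provenance (per-bin step
#'   counts, cohort size, interpolated bins).
#' @seealso [predict.pattern_library()], [apply_pattern()],
#'   [loocv_evaluate()]
#' @export
learn_patterns <- function(cohort, order = 12, n_interior_knots = 0L,
                           bins = 1:10) {
  usable <- Filter(function(s) length(s$toe_in_cycles) > 0, cohort)
  if (!length(usable)) abort_value("no subject has toe-in cycles")
  # pool step offsets across subjects, keyed by bin
  offsets_by_bin <- lapply(bins, function(b) list())
  names(offsets_by_bin) <- as.character(bins)
  n_steps_total <- 0L
  for (subj in usable) {
    bm <- baseline_mean_cycle(subj$baseline_cycles)
    for (cy in subj$toe_in_cycles) {
      b <- assign_bin(cy$rel_toe_in_deg)
      if (is.na(b) || !(b %in% bins)) next
      off <- compute_step_offsets(cy, bm)
      key <- as.character(b)
      offsets_by_bin[[key]][[length(offsets_by_bin[[key]]) + 1L]] <- off
      n_steps_total <- n_steps_total + 1L
    }
  }
  counts <- vapply(offsets_by_bin, length, 0L)
  if (all(counts == 0L)) abort_value("no toe-in steps fall inside the 1-10 degree bins")

  curves <- lapply(PATTERN_CHANNELS, function(ch) {
    by_bin <- vector("list", length(bins))
    names(by_bin) <- as.character(bins)
    for (i in seq_along(bins)) {
      key <- as.character(bins[i])
      offs <- lapply(offsets_by_bin[[key]], `[[`, ch)
      if (length(offs))
        by_bin[[key]] <- fit_bin_curve(offs, bins[i], ch, order = order,
                                       n_interior_knots = n_interior_knots)
    }
    by_bin
  })
  names(curves) <- PATTERN_CHANNELS

  # bins empty across the whole cohort: linear inter-/extrapolation in the
  # bin label from the two nearest non-empty bins (flanking bins when they
  # exist); with a single non-empty bin its curve is copied
  empty_bins <- bins[counts == 0L]
  nonempty <- bins[counts > 0L]
  for (ch in PATTERN_CHANNELS) {
    for (b in empty_bins) {
      if (length(nonempty) == 1L) {
        cv <- curves[[ch]][[as.character(nonempty)]]
      } else {
        lower <- nonempty[nonempty < b]; upper <- nonempty[nonempty > b]
        if (length(lower) && length(upper)) {
          b0 <- max(lower); b1 <- min(upper)
        } else if (length(lower)) {
          b1 <- max(lower); b0 <- max(lower[lower < b1])
        } else {
          b0 <- min(upper); b1 <- min(upper[upper > b0])
        }
        w <- (b - b0) / (b1 - b0)
        c0 <- curves[[ch]][[as.character(b0)]]
        c1 <- curves[[ch]][[as.character(b1)]]
        cv <- c0
        cv$coefs <- (1 - w) * c0$coefs + w * c1$coefs
      }
      cv$bin_deg <- as.integer(b); cv$n_steps <- 0L; cv$interpolated <- TRUE
      curves[[ch]][[as.character(b)]] <- cv
    }
  }

  new_pattern_library(
    curves = curves, spline_order = order,
    n_interior_knots = n_interior_knots, bins = as.integer(bins),
    provenance = list(
      n_subjects = length(usable), n_steps = n_steps_total,
      steps_per_bin = as.list(counts),
      interpolated_bins = as.integer(empty_bins),
      created = "toeinkam"
    )
  )
}

#' @export
print.pattern_library <- function(x, ...) {
  cat(sprintf("<pattern_library> %d channels x %d bins (order-%d B-splines, %d interior knots)\n",
              length(x$curves), length(x$bins), x$spline_order,
              x$n_interior_knots))
  cat(sprintf("  learned from %d subjects, %d toe-in steps\n",
              x$provenance$n_subjects, x$provenance$n_steps))
  counts <- unlist(x$provenance$steps_per_bin)
  cat("  steps per bin:", paste(sprintf("%s:%d", names(counts), counts),
                                collapse = " "), "\n")
  if (length(x$provenance$interpolated_bins))
    cat("  interpolated (empty) bins:",
        paste(x$provenance$interpolated_bins, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate learned offset curves
#'
#' `predict()` on a pattern library returns the offset (mm) of a channel's
#' curve at given stance percents for a given bin.
#'
#' @param object a `pattern_library`.
#' @param channel one of `KJC_ML, KJC_AP, FCP_ML, FCP_AP`.
#' @param bin integer bin 1..10.
#' @param at stance percents (0..100).
#' @param ... unused.
#' @return Numeric vector of offsets (mm).
#' @export
predict.pattern_library <- function(object, channel, bin, at = 0:100, ...) {
  channel <- match.arg(channel, PATTERN_CHANNELS)
  cv <- object$curves[[channel]][[as.character(bin)]]
  if (is.null(cv)) abort_integrity(sprintf("library has no bin %s for channel %s",
                                           bin, channel))
  eval_curve(cv, at)
}

#' @export
plot.pattern_library <- function(x, channel = "KJC_ML", ...) {
  channel <- match.arg(channel, PATTERN_CHANNELS)
  at <- 0:100
  ys <- sapply(x$bins, function(b) predict(x, channel, b, at))
  graphics::matplot(at, ys, type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(x$bins), "viridis"),
                    xlab = "% stance", ylab = sprintf("%s offset (mm)", channel),
                    ...)
  graphics::legend("topright", legend = paste0(x$bins, "°"), lty = 1,
                   col = grDevices::hcl.colors(length(x$bins), "viridis"),
                   cex = 0.6, ncol = 2)
  invisible(x)
}

#' Leave-one-out cross-validation of the pattern library
#'
#' For each subject in turn: learn the library from the remaining subjects,
#' synthesize toe-in gait at the left-out subject's mean relative toe-in
#' angle from their baseline mean cycle, compute the synthetic KAM using
#' the subject's own baseline GRF (which does not change with toe-in), and
#' compare against the subject's real toe-in cycles. Trajectory RMSEs are
#' against the subject's mean toe-in trajectory; the KAM-trace RMSE and
#' first-peak MAE are against the mean of the subject's real toe-in KAM
#' traces.
#'
#' @param cohort list of [subject_record] (>= 3, with toe-in cycles; the
#'   clinical `height`/`weight` fields are used to normalize KAM).
#' @param order,n_interior_knots spline configuration passed to
#'   [learn_patterns()].
#' @return A `loocv_report`: per-subject data frame plus mean/SD summaries
#'   of per-channel trajectory RMSE (mm), KAM-trace RMSE (%BW*HT) and
#'   first-peak MAE (%BW*HT).
#' @export
loocv_evaluate <- function(cohort, order = 12, n_interior_knots = 0L) {
  if (length(cohort) < 3L) abort_value("LOOCV needs at least 3 subjects")
  rows <- list()
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    if (!length(subj$toe_in_cycles)) {
      warning(sprintf("subject %s has no toe-in cycles; skipped", subj$subject_id))
      next
    }
    lib <- learn_patterns(cohort[-i], order = order,
                          n_interior_knots = n_interior_knots)
    theta <- mean(vapply(subj$toe_in_cycles, `[[`, 0, "rel_toe_in_deg"))
    bin <- assign_bin(theta)
    if (is.na(bin)) bin <- max(1L, min(10L, as.integer(round(theta))))
    bm <- baseline_mean_cycle(subj$baseline_cycles)
    synth <- apply_pattern(bm, lib, bin)

    real_mean <- baseline_mean_cycle(subj$toe_in_cycles)
    rmse <- function(a, b) sqrt(mean((a - b)^2))
    traj <- vapply(PATTERN_CHANNELS, function(ch)
      rmse(synth$channels[[ch]], real_mean$channels[[ch]]), 0)

    synth_kam <- cycle_kam(synth, subj$weight, subj$height)
    real_kams <- lapply(subj$toe_in_cycles, cycle_kam, subj$weight, subj$height)
    real_kam_mean <- rowMeans(vapply(real_kams, `[[`, numeric(101), "values"))
    real_first_peak <- mean(vapply(real_kams, `[[`, 0, "first_peak"))

    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subj$subject_id, theta_deg = theta, bin = bin,
      kjc_ml_rmse_mm = traj[["KJC_ML"]], kjc_ap_rmse_mm = traj[["KJC_AP"]],
      fcp_ml_rmse_mm = traj[["FCP_ML"]], fcp_ap_rmse_mm = traj[["FCP_AP"]],
      kam_rmse_pbwht = rmse(synth_kam$values, real_kam_mean),
      first_peak_mae_pbwht = abs(synth_kam$first_peak - real_first_peak)
    )
  }
  if (!length(rows)) abort_value("no subject could be cross-validated")
  per_subject <- do.call(rbind, rows)
  metrics <- setdiff(names(per_subject), c("subject_id", "theta_deg", "bin"))
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_subject[[m]]), 0),
    sd = vapply(metrics, function(m) stats::sd(per_subject[[m]]), 0),
    row.names = NULL
  )
  structure(list(per_subject = per_subject, summary = summary),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %d subjects\n", nrow(x$per_subject)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-22s %8.3f (+/- %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
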