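# Reading/writing gait trials and learned artifacts.
#
# Trial format: a wide marker CSV (one row per motion-capture frame), a force
# CSV at the plate's own rate, and a JSON sidecar with subject metadata.
# Positions are mm in the lab frame, forces N. These are this package's own
# documented conventions; C3D and other binary formats are out of scope.

REQUIRED_MARKERS <- c("CALC", "MET2", "LASI", "RASI", "LPSI", "RPSI",
                      "LEPI", "MEPI", "LMAL", "HJC")
ARTIFACT_VERSION <- "1"

#' Construct a gait trial recording
#'
#' Bundles one subject/condition treadmill trial: marker trajectories (mm,
#' lab frame), ground reaction force and center of pressure series from the
#' assigned force plate, the vertical force on the other plate (used to
#' reject steps that straddle both belts), and subject metadata.
#'
#' @param subject_id character scalar.
#' @param condition `"baseline"` or `"toe_in"`.
#' @param side `"left"` or `"right"` (instrumented leg).
#' @param markers named list of n-by-3 numeric matrices (mm); must contain
#'   `CALC, MET2, LASI, RASI, LPSI, RPSI, LEPI, MEPI, LMAL, HJC`.
#' @param grf m-by-3 matrix of ground reaction force (N).
#' @param cop m-by-3 matrix of center of pressure (mm, lab frame).
#' @param other_plate_fz length-m vertical force on the non-assigned plate (N).
#' @param marker_rate,force_rate sampling rates in Hz.
#' @param height,weight,walking_speed subject height (m), weight (kg) and
#'   self-selected treadmill speed (m/s).
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(subject_id, condition, side, markers, grf, cop,
                       other_plate_fz, marker_rate, force_rate,
                       height, weight, walking_speed) {
  condition <- match.arg(condition, c("baseline", "toe_in"))
  side <- match.arg(side, c("left", "right"))
  if (!all(REQUIRED_MARKERS %in% names(markers)))
    abort_schema(paste("missing marker(s):",
                       paste(setdiff(REQUIRED_MARKERS, names(markers)), collapse = ", ")))
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) abort_value("marker matrices must have 3 columns")
    unname(m)
  })
  nfr <- vapply(markers, nrow, 0L)
  if (length(unique(nfr)) != 1L)
    abort_value("all marker sequences must share the same length")
  if (nfr[[1L]] == 0L) abort_value("zero-length marker series")
  grf <- unname(as.matrix(grf)); cop <- unname(as.matrix(cop))
  if (nrow(grf) == 0L) abort_value("zero-length force series")
  if (nrow(grf) != nrow(cop) || nrow(grf) != length(other_plate_fz))
    abort_value("force, COP and other-plate series must share length")
  check_scalar_num(marker_rate, "marker_rate", lower = 1e-9)
  check_scalar_num(force_rate, "force_rate", lower = 1e-9)
  check_scalar_num(height, "height", lower = 0.5, upper = 2.5)
  check_scalar_num(weight, "weight", lower = 20, upper = 250)
  check_scalar_num(walking_speed, "walking_speed", lower = 0)
  structure(list(
    subject_id = as.character(subject_id), condition = condition, side = side,
    markers = markers, grf = grf, cop = cop,
    other_plate_fz = as.numeric(other_plate_fz),
    marker_rate = marker_rate, force_rate = force_rate,
    height = height, weight = weight, walking_speed = walking_speed
  ), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> subject %s, %s, %s side\n", x$subject_id,
              x$condition, x$side))
  cat(sprintf("  markers: %d frames @ %g Hz; forces: %d frames @ %g Hz\n",
              nrow(x$markers[[1L]]), x$marker_rate, nrow(x$grf), x$force_rate))
  cat(sprintf("  height %.3f m, weight %.1f kg, speed %.2f m/s\n",
              x$height, x$weight, x$walking_speed))
  invisible(x)
}

#' Construct a stance cycle
#'
#' One stance phase (heel strike to toe-off) with every channel resampled to
#' 101 points (0--100% stance inclusive), tagged with its foot progression
#' angle and the toe-in angle relative to the subject's baseline mean.
#'
#' @param subject_id,condition,step_index identifiers.
#' @param channels named list of length-101 numeric vectors; must contain
#'   `KJC_ML, KJC_AP, FCP_ML, FCP_AP` (mm, pelvis-relative),
#'   `KJC_LAB_ML, KJC_LAB_Z, COP_LAB_ML, COP_LAB_Z` (mm, lab frame) and
#'   `GRF_ML, GRF_AP, GRF_V` (N).
#' @param fpa_deg step foot progression angle (degrees, toe-out positive).
#' @param rel_toe_in_deg toe-in angle relative to the subject's baseline mean
#'   FPA (degrees, positive = toeing in); `NA` for baseline steps.
#' @param duration_s stance duration in seconds.
#' @return An object of class `stance_cycle`.
#' @export
stance_cycle <- function(subject_id, condition, step_index, channels,
                         fpa_deg, rel_toe_in_deg = NA_real_, duration_s) {
  missing_ch <- setdiff(CYCLE_CHANNELS, names(channels))
  if (length(missing_ch))
    abort_value(paste("missing channel(s):", paste(missing_ch, collapse = ", ")))
  channels <- lapply(channels[CYCLE_CHANNELS], as.numeric)
  bad <- names(channels)[vapply(channels, length, 0L) != N_STANCE_SAMPLES]
  if (length(bad))
    abort_value(paste("channels must have exactly 101 samples:",
                      paste(bad, collapse = ", ")))
  if (any(channels$GRF_V < -1e-9))
    abort_value("GRF_V must be non-negative over stance")
  check_scalar_num(duration_s, "duration_s", lower = 0)
  structure(list(
    subject_id = as.character(subject_id), condition = condition,
    step_index = as.integer(step_index), channels = channels,
    fpa_deg = as.numeric(fpa_deg), rel_toe_in_deg = as.numeric(rel_toe_in_deg),
    duration_s = duration_s
  ), class = "stance_cycle")
}

#' @export
print.stance_cycle <- function(x, ...) {
  cat(sprintf("<stance_cycle> %s/%s step %d: FPA %.2f deg, rel toe-in %s, %.3f s\n",
              x$subject_id, x$condition, x$step_index, x$fpa_deg,
              if (is.na(x$rel_toe_in_deg)) "NA"
              else sprintf("%.2f deg", x$rel_toe_in_deg), x$duration_s))
  invisible(x)
}

#' Construct a subject record
#'
#' Per-subject container for the clinical features used by the predictor and
#' the subject's step-normalized stance cycles.
#'
#' @param subject_id identifier.
#' @param height,weight,walking_speed clinical features (m, kg, m/s).
#' @param static_valgus_deg static frontal-plane knee alignment (degrees,
#'   valgus positive).
#' @param baseline_fpa_deg mean baseline foot progression angle (degrees,
#'   toe-out positive).
#' @param baseline_cycles list of [stance_cycle] from baseline walking
#'   (must be non-empty before learning or synthesis).
#' @param toe_in_cycles list of [stance_cycle] from toe-in walking (may be
#'   empty for cohorts with only baseline trials).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, height, weight, walking_speed,
                           static_valgus_deg, baseline_fpa_deg,
                           baseline_cycles, toe_in_cycles = list()) {
  check_scalar_num(height, "height", lower = 0.5, upper = 2.5)
  check_scalar_num(weight, "weight", lower = 20, upper = 250)
  check_scalar_num(walking_speed, "walking_speed", lower = 0)
  check_scalar_num(static_valgus_deg, "static_valgus_deg")
  check_scalar_num(baseline_fpa_deg, "baseline_fpa_deg")
  if (!length(baseline_cycles)) abort_value("baseline_cycles must be non-empty")
  structure(list(
    subject_id = as.character(subject_id), height = height, weight = weight,
    walking_speed = walking_speed, static_valgus_deg = static_valgus_deg,
    baseline_fpa_deg = baseline_fpa_deg,
    baseline_cycles = baseline_cycles, toe_in_cycles = toe_in_cycles
  ), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s: %d baseline / %d toe-in cycles\n",
              x$subject_id, length(x$baseline_cycles), length(x$toe_in_cycles)))
  cat(sprintf("  height %.3f m, weight %.1f kg, speed %.2f m/s, valgus %.2f deg, baseline FPA %.2f deg\n",
              x$height, x$weight, x$walking_speed, x$static_valgus_deg,
              x$baseline_fpa_deg))
  invisible(x)
}

#' Write a gait trial to disk
#'
#' Writes the wide marker CSV (`time_s, <LABEL>_X/_Y/_Z` in mm), the force
#' CSV (`time_s, GRF_X/Y/Z` in N, `COP_X/Y/Z` in mm, `OTHER_PLATE_FZ` in N)
#' and the JSON metadata sidecar. Missing marker frames are stored as `NA`.
#'
#' @param record a [gait_trial].
#' @param trial_path path for the marker CSV; the force CSV is written next
#'   to it with suffix `_force.csv`.
#' @param meta_path path for the JSON sidecar.
#' @return Invisibly, the three paths written.
#' @seealso [read_trial()]
#' @export
write_trial <- function(record, trial_path, meta_path) {
  stopifnot(inherits(record, "gait_trial"))
  nfr <- nrow(record$markers[[1L]])
  mk <- data.frame(time_s = (seq_len(nfr) - 1L) / record$marker_rate)
  for (lab in names(record$markers)) {
    m <- record$markers[[lab]]
    mk[[paste0(lab, "_X")]] <- m[, 1L]
    mk[[paste0(lab, "_Y")]] <- m[, 2L]
    mk[[paste0(lab, "_Z")]] <- m[, 3L]
  }
  nfo <- nrow(record$grf)
  fo <- data.frame(
    time_s = (seq_len(nfo) - 1L) / record$force_rate,
    GRF_X = record$grf[, 1L], GRF_Y = record$grf[, 2L], GRF_Z = record$grf[, 3L],
    COP_X = record$cop[, 1L], COP_Y = record$cop[, 2L], COP_Z = record$cop[, 3L],
    OTHER_PLATE_FZ = record$other_plate_fz
  )
  force_path <- sub("\\.csv$", "_force.csv", trial_path)
  if (identical(force_path, trial_path)) force_path <- paste0(trial_path, "_force.csv")
  ok <- tryCatch({
    utils::write.csv(mk, trial_path, row.names = FALSE)
    utils::write.csv(fo, force_path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_with(paste("cannot write trial files at", trial_path), "io_error")
  meta <- list(subject_id = record$subject_id, condition = record$condition,
               side = record$side, height_m = record$height,
               weight_kg = record$weight, speed_mps = record$walking_speed,
               marker_rate_hz = record$marker_rate,
               force_rate_hz = record$force_rate,
               units = list(position = "mm", force = "N"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(trial_path, force_path, meta_path))
}

#' Read a gait trial from disk
#'
#' Counterpart of [write_trial()]. Validates the schema (required marker
#' columns, monotone time, declared units) and returns a [gait_trial] in
#' canonical units (mm, N, m, kg, m/s). Right-side trials are *not* mirrored
#' here; see [mirror_to_canonical()].
#'
#' @param trial_path marker CSV path (force CSV expected at `*_force.csv`).
#' @param meta_path JSON sidecar path.
#' @return A [gait_trial].
#' @export
read_trial <- function(trial_path, meta_path) {
  mk <- utils::read.csv(trial_path, check.names = FALSE)
  force_path <- sub("\\.csv$", "_force.csv", trial_path)
  if (identical(force_path, trial_path)) force_path <- paste0(trial_path, "_force.csv")
  fo <- utils::read.csv(force_path, check.names = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$units)) abort_format("sidecar lacks a unit declaration")
  for (df_name in c("marker", "force")) {
    df <- if (df_name == "marker") mk else fo
    if (!"time_s" %in% names(df))
      abort_format(paste(df_name, "CSV lacks a time_s column"))
    tt <- df$time_s
    if (any(diff(tt) <= 0)) abort_format(paste(df_name, "time column not monotone"))
  }
  need <- as.vector(t(outer(REQUIRED_MARKERS, c("_X", "_Y", "_Z"), paste0)))
  miss <- setdiff(need, names(mk))
  if (length(miss)) {
    labs <- unique(sub("_[XYZ]$", "", miss))
    abort_schema(paste("marker CSV missing column(s) for:", paste(labs, collapse = ", ")))
  }
  fneed <- c("GRF_X", "GRF_Y", "GRF_Z", "COP_X", "COP_Y", "COP_Z", "OTHER_PLATE_FZ")
  fmiss <- setdiff(fneed, names(fo))
  if (length(fmiss))
    abort_schema(paste("force CSV missing column(s):", paste(fmiss, collapse = ", ")))
  if (anyNA(fo[, fneed]) || anyNA(fo$time_s) || anyNA(mk$time_s))
    abort_format("force CSV contains missing fields (truncated record?)")
  markers <- lapply(REQUIRED_MARKERS, function(lab)
    unname(as.matrix(mk[, paste0(lab, c("_X", "_Y", "_Z"))])))
  names(markers) <- REQUIRED_MARKERS
  gait_trial(
    subject_id = meta$subject_id, condition = meta$condition, side = meta$side,
    markers = markers,
    grf = as.matrix(fo[, c("GRF_X", "GRF_Y", "GRF_Z")]),
    cop = as.matrix(fo[, c("COP_X", "COP_Y", "COP_Z")]),
    other_plate_fz = fo$OTHER_PLATE_FZ,
    marker_rate = meta$marker_rate_hz, force_rate = meta$force_rate_hz,
    height = meta$height_m, weight = meta$weight_kg,
    walking_speed = meta$speed_mps
  )
}

#' Persist a learned artifact
#'
#' Writes a [pattern_library] or [kam_model] as versioned JSON, or a feature
#' table (data frame) as a versioned CSV. [load_artifact()] restores the
#' object and detects version mismatches.
#'
#' @param obj object to persist.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
persist_artifact <- function(obj, path) {
  if (inherits(obj, "pattern_library")) {
    out <- list(
      version = ARTIFACT_VERSION, kind = "pattern_library",
      spline_order = obj$spline_order, n_interior_knots = obj$n_interior_knots,
      bins = obj$bins, channels = PATTERN_CHANNELS,
      curves = lapply(obj$curves, function(by_bin)
        lapply(by_bin, function(cv)
          list(knots = cv$knots, coefs = cv$coefs, n_steps = cv$n_steps,
               interpolated = isTRUE(cv$interpolated)))),
      provenance = obj$provenance
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(obj, "kam_model")) {
    out <- list(
      version = ARTIFACT_VERSION, kind = "kam_model",
      feature_names = obj$feature_names, means = obj$means, scales = obj$scales,
      beta0 = obj$intercept, betas = unname(obj$coefficients),
      stderrs = unname(obj$stderrs), t_stats = unname(obj$t_stats),
      pvalues = unname(obj$p_values), n_train = obj$n_train,
      sigma = obj$sigma, df_residual = obj$df_residual,
      split_seed = obj$split_seed
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else if (is.data.frame(obj)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# toeinkam_feature_table v%s", ARTIFACT_VERSION), con)
    utils::write.csv(obj, con, row.names = FALSE)
  } else {
    abort_value("persist_artifact: unsupported object type")
  }
  invisible(path)
}

#' Load a persisted artifact
#'
#' @param path file written by [persist_artifact()].
#' @return The restored object (a [pattern_library], [kam_model] or data
#'   frame, depending on what was saved).
#' @export
load_artifact <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^# toeinkam_feature_table", first)) {
    ver <- sub("^# toeinkam_feature_table v", "", first)
    if (!identical(ver, ARTIFACT_VERSION))
      abort_version(paste("unknown feature table version:", ver))
    return(utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$version) || !identical(as.character(x$version), ARTIFACT_VERSION))
    abort_version(paste("unknown artifact version:", x$version))
  if (identical(x$kind, "pattern_library")) {
    bins <- as.integer(x$bins)
    curves <- lapply(PATTERN_CHANNELS, function(ch) {
      by_bin <- x$curves[[ch]]
      if (is.null(by_bin)) abort_integrity(paste("pattern file missing channel", ch))
      out <- lapply(as.character(bins), function(b) {
        cv <- by_bin[[b]]
        if (is.null(cv))
          abort_integrity(sprintf("pattern file missing bin %s for channel %s", b, ch))
        list(knots = as.numeric(cv$knots), coefs = as.numeric(cv$coefs),
             n_steps = as.integer(cv$n_steps),
             interpolated = isTRUE(cv$interpolated))
      })
      names(out) <- as.character(bins)
      out
    })
    names(curves) <- PATTERN_CHANNELS
    return(new_pattern_library(curves = curves, spline_order = x$spline_order,
                               n_interior_knots = x$n_interior_knots,
                               bins = bins, provenance = x$provenance))
  }
  if (identical(x$kind, "kam_model")) {
    betas <- as.numeric(x$betas); names(betas) <- x$feature_names
    return(structure(list(
      feature_names = x$feature_names, means = as.numeric(x$means),
      scales = as.numeric(x$scales), intercept = x$beta0,
      coefficients = betas, stderrs = as.numeric(x$stderrs),
      t_stats = as.numeric(x$t_stats), p_values = as.numeric(x$pvalues),
      n_train = x$n_train, sigma = x$sigma, df_residual = x$df_residual,
      split_seed = x$split_seed
    ), class = "kam_model"))
  }
  abort_format(paste("unrecognized artifact kind:", x$kind))
}
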