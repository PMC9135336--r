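# End-to-end orchestration: learn -> synthesize -> features -> split ->
# train -> evaluate, with every artifact written in a versioned format.

#' Default pipeline configuration
#'
#' All module parameters in one list: simulation settings for the pattern
#' (ground-truth-style) and baseline (synthesis target) cohorts, spline
#' configuration, toe-in angles, split fractions and the master seed.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param pattern_n_subjects,baseline_n_subjects cohort sizes.
#' @param steps_per_condition steps per subject per condition.
#' @param noise_mm,fpa_jitter_deg simulator noise levels.
#' @param spline_order,n_interior_knots spline basis configuration.
#' @param angles toe-in angles to synthesize (degrees).
#' @param split_fractions train/validation/test fractions.
#' @param run_loocv run leave-one-out cross-validation of the pattern
#'   cohort as part of the pipeline?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, pattern_n_subjects = 12L,
                            baseline_n_subjects = 138L,
                            steps_per_condition = 10L, noise_mm = 1,
                            fpa_jitter_deg = 1, spline_order = 12,
                            n_interior_knots = 0L, angles = 1:10,
                            split_fractions = c(0.8, 0.1, 0.1),
                            run_loocv = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on simulated cohorts
#'
#' Simulates a pattern cohort (baseline + toe-in) and a larger
#' baseline-only cohort, learns the pattern library, optionally
#' cross-validates it, synthesizes toe-in entries for the baseline cohort
#' at every configured angle, builds the feature table, splits by subject,
#' fits the standardized six-feature predictor on the training split and
#' evaluates it on all three splits. With `out_dir` set, writes
#' `patterns.json`, `entries.csv`, `features.csv`, `model.json`,
#' `eval.json`, `loocv.json` and `config.json`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for the artifact bundle.
#' @return Invisibly, a list with `library`, `entries`, `features`,
#'   `model`, `eval` (per-split reports), `loocv` (or `NULL`).
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- as.integer(config$seed)
  pat_cfg <- sim_config(n_subjects = config$pattern_n_subjects,
                        steps_per_condition = config$steps_per_condition,
                        noise_mm = config$noise_mm,
                        fpa_jitter_deg = config$fpa_jitter_deg)
  base_cfg <- sim_config(n_subjects = config$baseline_n_subjects,
                         steps_per_condition = config$steps_per_condition,
                         noise_mm = config$noise_mm,
                         fpa_jitter_deg = config$fpa_jitter_deg)
  pattern_cohort <- simulate_cohort(pat_cfg, seed = seed)
  baseline_cohort <- simulate_cohort(base_cfg, seed = seed + 1000L,
                                     with_toe_in = FALSE)

  lib <- learn_patterns(pattern_cohort, order = config$spline_order,
                        n_interior_knots = config$n_interior_knots,
                        bins = config$angles)
  loocv <- if (isTRUE(config$run_loocv))
    loocv_evaluate(pattern_cohort, order = config$spline_order,
                   n_interior_knots = config$n_interior_knots) else NULL

  entries <- synthesize_cohort(baseline_cohort, lib, bins = config$angles)
  features <- build_feature_table(entries, baseline_cohort)
  features <- split_by_subject(features, fractions = config$split_fractions,
                               seed = seed + 2000L)
  model <- fit_kam_model(features, split_seed = seed + 2000L)
  evals <- lapply(c(train = "train", val = "val", test = "test"), function(sp) {
    sub <- features[features$split == sp, , drop = FALSE]
    if (nrow(sub)) evaluate_predictions(model, sub) else NULL
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    persist_artifact(lib, file.path(out_dir, "patterns.json"))
    ent_df <- as.data.frame(entries)
    utils::write.csv(ent_df, file.path(out_dir, "entries.csv"), row.names = FALSE)
    persist_artifact(features, file.path(out_dir, "features.csv"))
    persist_artifact(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(evals, file.path(out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(loocv))
      jsonlite::write_json(list(per_subject = loocv$per_subject,
                                summary = loocv$summary),
                           file.path(out_dir, "loocv.json"),
                           auto_unbox = TRUE, digits = NA)
    cfg_out <- unclass(config)
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(library = lib, entries = entries, features = features,
                 model = model, eval = evals, loocv = loocv))
}
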