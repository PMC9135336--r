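# The six-feature linear predictor of first-peak KAM reduction:
# feature-table assembly, subject-level splitting, standardized OLS with
# coefficient inference, and prediction/evaluation.

KAM_FEATURES <- c("height", "weight", "walking_speed", "static_valgus_deg",
                  "baseline_fpa_deg", "toe_in_deg")

#' Build the predictor feature table
#'
#' One row per synthetic entry, combining the subject's clinical features
#' (height, weight, baseline walking speed, static valgus angle, baseline
#' FPA) with the entry's toe-in angle and its first-peak KAM reduction as
#' the response.
#'
#' @param entries [synthetic_entries][synthesize_cohort()] (or any data
#'   frame with `subject_id`, `toe_in_deg`, `reduction`).
#' @param subjects list of [subject_record] covering every entry's subject.
#' @return Data frame with `subject_id`, the six features, and `reduction`
#'   (%BW*HT).
#' @export
build_feature_table <- function(entries, subjects) {
  ids <- vapply(subjects, `[[`, "", "subject_id")
  idx <- match(entries$subject_id, ids)
  if (anyNA(idx))
    stop_with(paste("entries reference unknown subject(s):",
                    paste(unique(entries$subject_id[is.na(idx)]), collapse = ", ")),
              "key_error")
  grab <- function(field) vapply(subjects, `[[`, 0, field)[idx]
  data.frame(
    subject_id = entries$subject_id,
    height = grab("height"), weight = grab("weight"),
    walking_speed = grab("walking_speed"),
    static_valgus_deg = grab("static_valgus_deg"),
    baseline_fpa_deg = grab("baseline_fpa_deg"),
    toe_in_deg = as.numeric(entries$toe_in_deg),
    reduction = entries$reduction
  )
}

#' Split a feature table by subject
#'
#' Subjects (never individual rows) are shuffled with the seed and
#' partitioned into train/validation/test so that every row of a subject
#' carries the same label -- the guard against inflated performance from
#' gait cycles of one subject leaking across sets. Validation and test
#' each get `round(fraction * N)` subjects; the remainder trains.
#'
#' @param rows feature table ([build_feature_table()]).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer RNG seed for the subject shuffle.
#' @param n_val,n_test optional explicit subject counts overriding the
#'   fractions.
#' @return `rows` with an added `split` factor column.
#' @export
split_by_subject <- function(rows, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                             n_val = NULL, n_test = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9) abort_value("fractions must sum to 1")
  ids <- unique(rows$subject_id)
  n <- length(ids)
  if (n < 3L) abort_value("need at least 3 subjects to split")
  if (is.null(n_val)) n_val <- round(fractions[2L] * n)
  if (is.null(n_test)) n_test <- round(fractions[3L] * n)
  if (n_val + n_test >= n) abort_value("no subjects left for training")
  shuffled <- local({ set.seed(seed); sample(ids) })
  val_ids <- shuffled[seq_len(n_val)]
  test_ids <- shuffled[n_val + seq_len(n_test)]
  rows$split <- factor(
    ifelse(rows$subject_id %in% val_ids, "val",
           ifelse(rows$subject_id %in% test_ids, "test", "train")),
    levels = c("train", "val", "test"))
  rows
}

#' Fit the standardized linear predictor of KAM reduction
#'
#' Ordinary least squares of first-peak KAM reduction on the requested
#' features, each z-scored with the *training* means and standard
#' deviations (so coefficients are on the standardized scale and
#' comparable in magnitude). Standard errors come from the residual
#' variance and the normal-equations inverse; p-values are two-sided
#' t-tests with `n - p - 1` degrees of freedom.
#'
#' @param rows training rows of a feature table (if a `split` column is
#'   present, only `split == "train"` rows are used).
#' @param features character vector of feature columns; defaults to the
#'   six clinical features. Subsets are allowed (e.g. only `toe_in_deg`).
#' @param response response column name.
#' @param split_seed optional seed recorded for provenance.
#' @return An object of class `kam_model` with fields `feature_names`,
#'   `means`, `scales`, `intercept`, `coefficients`, `stderrs`, `t_stats`,
#'   `p_values`, `n_train`, `sigma`, `df_residual`.
#' @examples
#' tab <- simulate_feature_response(n_subjects = 30, seed = 2)
#' fit <- fit_kam_model(tab)
#' coef(fit)
#' @export
fit_kam_model <- function(rows, features = KAM_FEATURES,
                          response = "reduction", split_seed = NA) {
  if ("split" %in% names(rows)) rows <- rows[rows$split == "train", , drop = FALSE]
  miss <- setdiff(c(features, response), names(rows))
  if (length(miss)) abort_value(paste("missing column(s):", paste(miss, collapse = ", ")))
  n <- nrow(rows)
  if (n < 10L) abort_value("need at least 10 training rows")
  X <- as.matrix(rows[, features, drop = FALSE])
  means <- colMeans(X)
  scales <- apply(X, 2L, stats::sd)
  degenerate <- features[scales < 1e-12]
  if (length(degenerate))
    abort_value(paste("zero-variance feature(s):", paste(degenerate, collapse = ", ")))
  Z <- sweep(sweep(X, 2L, means), 2L, scales, "/")
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1L) {
    dropped <- c("(intercept)", features)[qrz$pivot[-seq_len(qrz$rank)]]
    stop_with(paste("collinear feature(s):", paste(dropped, collapse = ", ")),
              "collinearity_error")
  }
  df <- data.frame(Z, y = rows[[response]], check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  # noiseless designs (oracle inputs) are legitimate; the perfect-fit note
  # from summary.lm is expected there, not actionable
  smry <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- smry$coefficients
  structure(list(
    feature_names = features,
    means = unname(means), scales = unname(scales),
    intercept = unname(sm[1L, 1L]),
    coefficients = stats::setNames(sm[-1L, 1L], features),
    stderrs = unname(sm[-1L, 2L]),
    t_stats = unname(sm[-1L, 3L]),
    p_values = unname(sm[-1L, 4L]),
    n_train = n, sigma = smry$sigma,
    df_residual = fit$df.residual, split_seed = split_seed,
    lm_fit = fit
  ), class = "kam_model")
}

#' @export
coef.kam_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.kam_model <- function(x, ...) {
  cat(sprintf("<kam_model> first-peak KAM reduction ~ %d standardized feature(s), n = %d\n",
              length(x$feature_names), x$n_train))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.kam_model <- function(object, ...) {
  tab <- data.frame(
    estimate = object$coefficients,
    std_error = object$stderrs,
    t_value = object$t_stats,
    p_value = object$p_values,
    row.names = object$feature_names
  )
  out <- list(coefficients = tab, intercept = object$intercept,
              sigma = object$sigma, df_residual = object$df_residual,
              n_train = object$n_train)
  class(out) <- "summary.kam_model"
  out
}

#' @export
print.summary.kam_model <- function(x, ...) {
  cat(sprintf("Standardized linear model of first-peak KAM reduction (%%BW*HT)\n"))
  cat(sprintf("n = %d, residual sigma = %.4f on %d df\n\n", x$n_train, x$sigma,
              x$df_residual))
  cat(sprintf("(Intercept)  %.4f\n", x$intercept))
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
residuals.kam_model <- function(object, ...) {
  if (is.null(object$lm_fit)) abort_value("residuals unavailable for a reloaded model")
  stats::residuals(object$lm_fit)
}

#' Predict first-peak KAM reduction
#'
#' Applies the training standardization to the new rows and evaluates the
#' linear model.
#'
#' @param object a [kam_model][fit_kam_model()].
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @return Numeric vector of predicted reductions (%BW*HT).
#' @export
predict.kam_model <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) abort_value(paste("missing feature(s):", paste(miss, collapse = ", ")))
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Z <- sweep(sweep(X, 2L, object$means), 2L, object$scales, "/")
  as.numeric(object$intercept + Z %*% object$coefficients)
}

#' @export
plot.kam_model <- function(x, rows, ...) {
  pred <- predict(x, rows)
  graphics::plot(rows$reduction, pred,
                 xlab = "actual reduction (%BW*HT)",
                 ylab = "predicted reduction (%BW*HT)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Evaluate predictions of a fitted model
#'
#' Computes the mean absolute error (with the SD of the absolute errors),
#' two flavours of R-squared (the coefficient of determination of the
#' predictions, and the R-squared of the least-squares line through the
#' actual-vs-predicted scatter), and the mean signed error. Signed error
#' uses the convention actual minus predicted, aggregated per subject
#' across that subject's toe-in angles when a `subject_id` column is
#' present, then summarized with a t-based 95% confidence interval.
#'
#' @param model a [kam_model][fit_kam_model()].
#' @param rows feature-table rows with responses.
#' @param response response column name.
#' @return List with `mae`, `mae_sd`, `r2_pred`, `r2_fit`,
#'   `mean_signed_error`, `signed_error_ci` (95%), `n`.
#' @export
evaluate_predictions <- function(model, rows, response = "reduction") {
  if (!nrow(rows)) abort_value("no rows to evaluate")
  actual <- rows[[response]]
  pred <- predict(model, rows)
  err <- actual - pred
  ss_res <- sum(err^2); ss_tot <- sum((actual - mean(actual))^2)
  r2_pred <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  r2_fit <- if (ss_tot > 0 && stats::var(pred) > 0)
    stats::cor(actual, pred)^2 else NA_real_
  per_subj <- if ("subject_id" %in% names(rows))
    tapply(err, rows$subject_id, mean) else err
  m <- mean(per_subj)
  ci <- if (length(per_subj) > 1L && stats::sd(per_subj) > 0) {
    se <- stats::sd(per_subj) / sqrt(length(per_subj))
    m + c(-1, 1) * stats::qt(0.975, length(per_subj) - 1L) * se
  } else c(m, m)
  list(mae = mean(abs(err)), mae_sd = stats::sd(abs(err)),
       r2_pred = r2_pred, r2_fit = r2_fit,
       mean_signed_error = m, signed_error_ci = ci, n = length(actual))
}
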