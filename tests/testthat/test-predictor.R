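# Feature table, subject-level splitting, standardized OLS, prediction and
# evaluation.

test_that("feature table has one row per entry with the subject's clinical features", {
  co <- simulate_cohort(sim_config(n_subjects = 4), seed = 1, with_toe_in = FALSE)
  lib <- learn_patterns(simulate_cohort(sim_config(n_subjects = 4), seed = 2))
  entries <- synthesize_cohort(co, lib)
  tab <- build_feature_table(entries, co)
  expect_equal(nrow(tab), nrow(entries))
  expect_equal(tab$reduction, entries$reduction)
  one <- tab[tab$subject_id == "S002", ]
  expect_equal(nrow(one), 10)
  expect_equal(unique(one$height), co[[2]]$height)
  expect_equal(unique(one$static_valgus_deg), co[[2]]$static_valgus_deg)
  expect_equal(one$toe_in_deg, as.numeric(1:10))

  bad <- entries
  bad$subject_id[1] <- "GHOST"
  expect_error(build_feature_table(bad, co), class = "toeinkam_key_error")
})

test_that("subject-level split: partition sizes, no leakage, seed-reproducible", {
  tab <- simulate_feature_response(n_subjects = 138, seed = 5)
  sp <- split_by_subject(tab, seed = 42)
  by_subj <- tapply(as.character(sp$split), sp$subject_id,
                    function(x) length(unique(x)))
  expect_true(all(by_subj == 1))  # every subject in exactly one set
  n_subj <- tapply(sp$subject_id, sp$split, function(x) length(unique(x)))
  expect_equal(unname(n_subj["val"]), 14L)
  expect_equal(unname(n_subj["test"]), 14L)
  expect_equal(unname(n_subj["train"]), 110L)

  sp2 <- split_by_subject(tab, seed = 42)
  expect_identical(sp$split, sp2$split)
  sp3 <- split_by_subject(tab, seed = 43)
  expect_false(identical(sp$split, sp3$split))

  # explicit counts override the fractions (e.g. a 108/15/15 split)
  sp4 <- split_by_subject(tab, seed = 1, n_val = 15, n_test = 15)
  n4 <- tapply(sp4$subject_id, sp4$split, function(x) length(unique(x)))
  expect_equal(as.integer(n4), c(108L, 15L, 15L))

  expect_error(split_by_subject(tab[tab$subject_id %in% c("S001", "S002"), ]),
               class = "toeinkam_value_error")
  expect_error(split_by_subject(tab, fractions = c(0.5, 0.2, 0.2)),
               class = "toeinkam_value_error")
})

test_that("standardization: training z-scores exact, val/test use training parameters", {
  tab <- simulate_feature_response(n_subjects = 60, seed = 7)
  tab <- split_by_subject(tab, seed = 1)
  m <- fit_kam_model(tab)
  train <- tab[tab$split == "train", ]
  Z <- sweep(sweep(as.matrix(train[, m$feature_names]), 2, m$means), 2,
             m$scales, "/")
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, var) - 1)), 1e-10)
  # leakage guard: the stored parameters are the training ones, so the
  # transformed test features are NOT zero-mean
  test_rows <- tab[tab$split == "test", ]
  Zt <- sweep(sweep(as.matrix(test_rows[, m$feature_names]), 2, m$means), 2,
              m$scales, "/")
  expect_gt(max(abs(colMeans(Zt))), 1e-6)
})

test_that("noiseless linear responses are fit exactly", {
  set.seed(3)
  n <- 200
  z1 <- rnorm(n); z2 <- rnorm(n)
  rows <- data.frame(subject_id = sprintf("S%03d", rep(1:20, each = 10)),
                     f1 = z1, f2 = z2, reduction = 2 * z1 - z2)
  m <- fit_kam_model(rows, features = c("f1", "f2"))
  # de-standardized (raw-scale) coefficients recover (2, -1)
  raw <- m$coefficients / m$scales
  expect_equal(unname(raw), c(2, -1), tolerance = 1e-8)
  expect_equal(predict(m, rows), rows$reduction, tolerance = 1e-8)
  ev <- evaluate_predictions(m, rows)
  expect_equal(ev$r2_pred, 1, tolerance = 1e-10)
  expect_equal(ev$mae, 0, tolerance = 1e-10)

  # constant response: zero slopes, intercept = the constant
  rows$reduction <- 1.25
  mc <- fit_kam_model(rows, features = c("f1", "f2"))
  expect_equal(unname(coef(mc)), c(1.25, 0, 0), tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- simulate_feature_response(n_subjects = 20, seed = 2)
  tab$flat <- 5
  expect_error(fit_kam_model(tab, features = c("toe_in_deg", "flat")),
               class = "toeinkam_value_error")
  tab$dup <- 2 * tab$toe_in_deg + 1
  expect_error(fit_kam_model(tab, features = c("toe_in_deg", "dup")),
               class = "toeinkam_collinearity_error")
  expect_error(fit_kam_model(tab[1:5, ]), class = "toeinkam_value_error")
  expect_error(fit_kam_model(tab, features = c("toe_in_deg", "nope")),
               class = "toeinkam_value_error")
})

test_that("prediction is the standardized linear form", {
  tab <- simulate_feature_response(n_subjects = 40, seed = 9)
  m <- fit_kam_model(tab)
  # features at the training means predict the intercept
  at_means <- as.data.frame(as.list(setNames(m$means, m$feature_names)))
  expect_equal(predict(m, at_means), m$intercept, tolerance = 1e-10)
  # +1 scale unit on toe-in moves the prediction by exactly beta_toe_in
  shifted <- at_means
  shifted$toe_in_deg <- shifted$toe_in_deg + m$scales[6]
  expect_equal(predict(m, shifted) - predict(m, at_means),
               unname(m$coefficients["toe_in_deg"]), tolerance = 1e-10)
  expect_error(predict(m, at_means[, 1:3]), class = "toeinkam_value_error")
})

test_that("single-feature (toe-in only) models are supported", {
  tab <- simulate_feature_response(n_subjects = 40, seed = 11)
  m1 <- fit_kam_model(tab, features = "toe_in_deg")
  expect_equal(length(coef(m1)), 2L)
  expect_true(is.finite(m1$p_values))
  ev <- evaluate_predictions(m1, tab)
  expect_true(ev$r2_pred > 0.5)  # toe-in dominates the simulated response
})

test_that("evaluation metrics: offsets, signed-error convention and permutation null", {
  tab <- simulate_feature_response(n_subjects = 50, seed = 13, sigma_y = 0)
  m <- fit_kam_model(tab)
  ev <- evaluate_predictions(m, tab)
  expect_equal(ev$mae, 0, tolerance = 1e-8)
  expect_equal(ev$r2_fit, 1, tolerance = 1e-8)
  expect_equal(ev$mean_signed_error, 0, tolerance = 1e-8)

  # predictions uniformly 0.1 too low => signed error (actual - predicted) = +0.1
  m_lo <- m
  m_lo$intercept <- m$intercept - 0.1
  ev_lo <- evaluate_predictions(m_lo, tab)
  expect_equal(ev_lo$mae, 0.1, tolerance = 1e-8)
  expect_equal(ev_lo$mean_signed_error, 0.1, tolerance = 1e-8)
  # per-subject errors are all (numerically) 0.1, so the CI degenerates there
  expect_equal(ev_lo$signed_error_ci, c(0.1, 0.1), tolerance = 1e-6)

  # shuffled responses: R^2 of the best-fit line collapses toward zero
  set.seed(1)
  shuf <- tab
  shuf$reduction <- sample(shuf$reduction)
  ev_shuf <- evaluate_predictions(m, shuf)
  expect_lt(ev_shuf$r2_fit, 0.05)
  expect_error(evaluate_predictions(m, tab[0, ]), class = "toeinkam_value_error")
})

test_that("coefficient estimates cover the truth at the nominal rate", {
  # moderate-n Monte Carlo: 60 replicates, 95% CIs per coefficient
  truth <- attr(simulate_feature_response(n_subjects = 5, seed = 1), "truth")
  hits <- 0L; total <- 0L
  for (r in 1:60) {
    tab <- simulate_feature_response(n_subjects = 40, seed = 1000 + r,
                                     sigma_y = 0.1)
    m <- fit_kam_model(tab)
    raw <- m$coefficients / m$scales
    raw_se <- m$stderrs / m$scales
    tcrit <- qt(0.975, m$df_residual)
    covered <- abs(raw - truth$beta_raw[m$feature_names]) <= tcrit * raw_se
    hits <- hits + sum(covered); total <- total + length(covered)
  }
  expect_gt(hits / total, 0.90)
  expect_lt(hits / total, 0.99)
})
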