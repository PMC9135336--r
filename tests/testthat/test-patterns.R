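# Offset computation, binning, spline fitting, library learning, LOOCV.

test_that("step offsets are pointwise differences of the pelvis-relative channels", {
  base <- const_cycle(10)
  toe <- const_cycle(10, condition = "toe_in")
  off <- compute_step_offsets(toe, base)
  expect_equal(names(off), c("KJC_ML", "KJC_AP", "FCP_ML", "FCP_AP"))
  for (ch in names(off)) expect_equal(off[[ch]], rep(0, 101))

  toe2 <- set_channel(toe, "KJC_ML", 13)
  off2 <- compute_step_offsets(toe2, base)
  expect_equal(off2$KJC_ML, rep(3, 101))
  expect_equal(off2$FCP_ML, rep(0, 101))

  # antisymmetry under swapping the roles
  swapped <- compute_step_offsets(base, toe2)
  expect_equal(swapped$KJC_ML, -off2$KJC_ML)
})

test_that("bin assignment rounds to the nearest degree within 1..10", {
  expect_equal(assign_bin(5.4), 5L)
  expect_true(is.na(assign_bin(0.3)))
  expect_equal(assign_bin(0.5), 1L)
  expect_equal(assign_bin(10.49), 10L)
  expect_true(is.na(assign_bin(10.5)))
  expect_true(is.na(assign_bin(-3)))
  expect_equal(assign_bin(c(1, 2.5, 11)), c(1L, 3L, NA_integer_))
})

test_that("bin-curve fitting: constants, averaging, and a known noisy sine", {
  cv <- fit_bin_curve(list(rep(2.5, 101)), 3, "KJC_ML")
  expect_lt(max(abs(toeinkam:::eval_curve(cv, 0:100) - 2.5)), 1e-6)
  expect_equal(cv$n_steps, 1L)

  cv2 <- fit_bin_curve(list(rep(1, 101), rep(-1, 101)), 3, "KJC_ML")
  expect_lt(max(abs(toeinkam:::eval_curve(cv2, 0:100))), 1e-6)

  # 20 noisy copies of a 5 mm sine: the fit must recover the true curve
  set.seed(5)
  t <- seq(0, 1, length.out = 101)
  truth <- 5 * sin(2 * pi * t)
  offs <- lapply(1:20, function(i) truth + rnorm(101, 0, 1))
  cv3 <- fit_bin_curve(offs, 4, "FCP_ML")
  rmse <- sqrt(mean((toeinkam:::eval_curve(cv3, 0:100) - truth)^2))
  expect_lt(rmse, 0.5)

  expect_error(fit_bin_curve(list(), 2, "KJC_ML"), class = "toeinkam_value_error")
})

test_that("spline residual against the raw bin mean is non-increasing in basis size", {
  set.seed(8)
  t <- seq(0, 1, length.out = 101)
  avg <- 3 * sin(2 * pi * t) + 2 * cos(5 * pi * t) + rnorm(101, 0, 0.3)
  rmse_by_order <- vapply(3:20, function(ord) {
    cv <- fit_bin_curve(list(avg), 1, "KJC_ML", order = ord)
    sqrt(mean((toeinkam:::eval_curve(cv, 0:100) - avg)^2))
  }, 0)
  expect_true(all(diff(rmse_by_order) <= 1e-9))
})

test_that("library learned from a zero-response cohort is zero everywhere", {
  co <- simulate_cohort(sim_config(n_subjects = 4, noise_mm = 0,
                                   kjc_ml_slope = 0, fcp_ml_slope = 0,
                                   kjc_ap_slope = 0, fcp_ap_slope = 0),
                        seed = 3)
  lib <- learn_patterns(co)
  for (ch in c("KJC_ML", "KJC_AP", "FCP_ML", "FCP_AP"))
    for (b in lib$bins)
      expect_lt(max(abs(predict(lib, ch, b))), 1e-8)
})

test_that("learning recovers the linear ground-truth response per bin", {
  cfg <- sim_config(n_subjects = 12, steps_per_condition = 10, noise_mm = 1)
  co <- simulate_cohort(cfg, seed = 1)
  truth <- truth_shapes(cfg)
  lib <- learn_patterns(co)
  for (ch in names(truth))
    for (b in 1:10) {
      fitted <- predict(lib, ch, b)
      rmse <- sqrt(mean((fitted - b * truth[[ch]])^2))
      expect_lt(rmse, 0.5)
    }
})

test_that("learned curves are linear in the bin label (slope recovers g_c)", {
  cfg <- sim_config(n_subjects = 12, noise_mm = 0.5)
  co <- simulate_cohort(cfg, seed = 2)
  truth <- truth_shapes(cfg)
  lib <- learn_patterns(co)
  at <- seq(0, 100, by = 5)
  for (ch in c("KJC_ML", "FCP_ML")) {
    curves <- sapply(1:10, function(b) predict(lib, ch, b, at))  # |at| x 10
    slopes <- apply(curves, 1, function(y) coef(lm(y ~ I(1:10)))[2])
    g_true <- approx(0:100, truth[[ch]], at)$y
    expect_lt(max(abs(slopes - g_true)), 0.25)
  }
})

test_that("library learning is deterministic and stores per-bin provenance", {
  co <- simulate_cohort(sim_config(n_subjects = 5), seed = 9)
  lib1 <- learn_patterns(co)
  lib2 <- learn_patterns(co)
  expect_identical(lib1, lib2)
  counts <- unlist(lib1$provenance$steps_per_bin)
  expect_equal(sum(counts), lib1$provenance$n_steps)
  expect_equal(lib1$provenance$n_subjects, 5)
})

test_that("bins empty across the cohort are interpolated from neighbours and flagged", {
  # four subjects targeting 2 and 6 degrees only, no jitter: bins 3-5 and
  # 7-10 are empty
  cfg <- sim_config(n_subjects = 4, noise_mm = 0, fpa_jitter_deg = 0)
  co <- simulate_cohort(cfg, seed = 4)
  for (i in seq_along(co)) {
    tgt <- if (i %% 2) 2 else 6
    co[[i]]$toe_in_cycles <- lapply(co[[i]]$toe_in_cycles, function(cy) {
      cy$rel_toe_in_deg <- tgt + 0 * cy$rel_toe_in_deg
      cy
    })
  }
  # rebuild channels so offsets match the relabelled angles
  truth <- truth_shapes(cfg)
  for (i in seq_along(co)) {
    tgt <- if (i %% 2) 2 else 6
    bm <- baseline_mean_cycle(co[[i]]$baseline_cycles)
    co[[i]]$toe_in_cycles <- lapply(co[[i]]$toe_in_cycles, function(cy) {
      for (ch in names(truth)) cy$channels[[ch]] <- bm$channels[[ch]] + tgt * truth[[ch]]
      cy
    })
  }
  lib <- learn_patterns(co)
  expect_setequal(lib$provenance$interpolated_bins, c(1, 3, 4, 5, 7, 8, 9, 10))
  # interpolated bin 4 sits halfway between bins 2 and 6
  mid <- (predict(lib, "KJC_ML", 2) + predict(lib, "KJC_ML", 6)) / 2
  expect_equal(predict(lib, "KJC_ML", 4), mid, tolerance = 1e-9)
  # edge bins extrapolate linearly from the two nearest non-empty bins,
  # which reproduces a linear-in-angle ground truth exactly
  extrap10 <- 2 * predict(lib, "KJC_ML", 6) - predict(lib, "KJC_ML", 2)
  expect_equal(predict(lib, "KJC_ML", 10), extrap10, tolerance = 1e-9)
  # ... which reproduces a linear-in-angle ground truth up to the spline's
  # own approximation error
  truth10 <- 10 * truth_shapes(cfg)$KJC_ML
  expect_lt(max(abs(predict(lib, "KJC_ML", 10) - truth10)), 0.05)
})

test_that("LOOCV on a noise-free cohort is self-consistent", {
  co <- noise_free_cohort(6, seed = 10)
  rep <- loocv_evaluate(co)
  expect_equal(nrow(rep$per_subject), 6)
  s <- rep$summary
  expect_true(all(is.finite(s$mean)) && all(is.finite(s$sd)) && all(s$sd >= 0))
  traj <- s$mean[grepl("rmse_mm", s$metric)]
  expect_lt(max(traj), 0.1)
  expect_lt(s$mean[s$metric == "first_peak_mae_pbwht"], 0.01)
})

test_that("LOOCV error is plausible at realistic noise and skips toe-in-free subjects", {
  co <- simulate_cohort(sim_config(n_subjects = 6, noise_mm = 2), seed = 6)
  co[[3]]$toe_in_cycles <- list()
  expect_warning(rep <- loocv_evaluate(co), "no toe-in")
  expect_equal(nrow(rep$per_subject), 5)
  kjc_ml <- rep$summary$mean[rep$summary$metric == "kjc_ml_rmse_mm"]
  expect_gt(kjc_ml, 0.05)
  expect_lt(kjc_ml, 10)
  expect_error(loocv_evaluate(co[1:2]), class = "toeinkam_value_error")
})
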