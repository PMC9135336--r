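# Zero-lag filtering, stance detection, step rejection, 101-point
# resampling.

test_that("zero-lag filter has unit DC gain and preserves symmetric pulse location", {
  # DC: a constant signal passes through exactly, including the edges
  x <- rep(7.5, 600)
  expect_equal(lowpass_filter(x, rate = 1000), x, tolerance = 1e-9)

  # zero lag: the peak of a symmetric pulse stays at the same sample
  n <- 1000; k <- 437
  pulse <- exp(-((seq_len(n) - k) / 25)^2)
  y <- lowpass_filter(pulse, rate = 1000)
  expect_equal(which.max(y), k)
  # and the response is symmetric about the peak
  w <- 150
  expect_equal(y[(k - w):(k - 1)], rev(y[(k + 1):(k + w)]), tolerance = 1e-6)
})

test_that("stopband attenuation matches the Butterworth frequency-response oracle", {
  rate <- 1000; f <- 50; cutoff <- 15; order <- 4
  t <- seq(0, 2, by = 1 / rate)
  x <- sin(2 * pi * f * t)
  y <- lowpass_filter(x, rate, cutoff = cutoff, order = order)
  core <- y[101:(length(y) - 100)]  # discard edge samples
  expect_lt(max(abs(core)), 0.01)
  # exact digital oracle via the transfer function at the tone frequency,
  # applied twice (forward + backward). The filter's own start-up transient
  # decays like the pole radius^n, so compare deep inside the record.
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  z <- exp(-1i * 2 * pi * f / rate)
  H <- sum(bf$b * z^(0:order)) / sum(bf$a * z^(0:order))
  deep <- y[501:(length(y) - 500)]
  expect_equal(max(abs(deep)), Mod(H)^2, tolerance = 0.05)
  # and the digital response is at least as selective as the analog
  # prototype |H| = 1/sqrt(1 + (f/fc)^(2n))
  h2_analog <- (1 / sqrt(1 + (f / cutoff)^(2 * order)))^2
  expect_lt(max(abs(deep)), h2_analog * 1.05)
})

test_that("filter input validation", {
  expect_error(lowpass_filter(rep(1, 10), rate = 1000), class = "toeinkam_value_error")
  expect_error(lowpass_filter(rep(1, 100), rate = 25, cutoff = 15),
               class = "toeinkam_value_error")
})

test_that("stance detection finds threshold-crossing events of the right duration", {
  rate <- 1000
  expect_equal(nrow(detect_stance_phases(rep(0, 2000), rate)), 0L)

  # one square pulse of 0.6 s
  g <- rep(0, 2000); g[500:1099] <- 700
  ev <- detect_stance_phases(g, rate)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$duration_s - 0.6), 2 / rate + 1e-12)

  # two pulses separated by 0.4 s of swing
  g <- rep(0, 3000); g[500:1099] <- 700; g[1500:2099] <- 700
  expect_equal(nrow(detect_stance_phases(g, rate)), 2L)

  # partial phases touching the record edges are discarded
  g <- rep(0, 2000); g[1:300] <- 700; g[600:1199] <- 700; g[1800:2000] <- 700
  ev <- detect_stance_phases(g, rate)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$heel_strike_idx, 600L, tolerance = 1)

  # sub-debounce glitches do not split an event
  g <- rep(0, 2000); g[500:1099] <- 700; g[800:802] <- 5
  expect_equal(nrow(detect_stance_phases(g, rate)), 1L)

  # out-of-bounds durations are rejected
  g <- rep(0, 2000); g[500:549] <- 700  # 50 ms
  expect_equal(nrow(detect_stance_phases(g, rate)), 0L)
})

test_that("clean-step test checks the other plate over the whole stance", {
  ev <- list(heel_strike_idx = 100L, toe_off_idx = 700L)
  other <- rep(0, 1000)
  expect_true(is_clean_step(ev, other))
  other[400:410] <- 100
  expect_false(is_clean_step(ev, other))
  other[400:410] <- 19  # strictly below the 20 N threshold
  expect_true(is_clean_step(ev, other))
  expect_error(is_clean_step(list(heel_strike_idx = 0L, toe_off_idx = 10L), other),
               class = "toeinkam_value_error")
})

test_that("time normalization maps stance onto 0..100% with exact endpoints", {
  ev <- list(heel_strike_idx = 1, toe_off_idx = 201)
  ramp <- seq(0, 2, length.out = 201)
  out <- time_normalize_stance(ramp, ev)
  expect_equal(out, seq(0, 2, length.out = 101), tolerance = 1e-12)

  out <- time_normalize_stance(rep(3.3, 201), ev)
  expect_equal(out, rep(3.3, 101))

  # a stance of exactly 101 frames is returned unchanged
  x <- rnorm(101)
  expect_equal(time_normalize_stance(x, list(heel_strike_idx = 1, toe_off_idx = 101)),
               x, tolerance = 1e-12)

  expect_error(time_normalize_stance(rep(1, 20), list(heel_strike_idx = 1, toe_off_idx = 5)),
               class = "toeinkam_value_error")
})

test_that("normalization of an upsampled 101-point channel is idempotent", {
  set.seed(1)
  x <- cumsum(rnorm(101))
  up <- approx(seq(0, 1, length.out = 101), x, xout = seq(0, 1, length.out = 1001))$y
  back <- time_normalize_stance(up, list(heel_strike_idx = 1, toe_off_idx = 1001))
  expect_equal(back, x, tolerance = 1e-9)
})

test_that("detector recovers the simulator's event times within one frame", {
  cfg <- sim_config()
  tr <- simulate_trial(cfg, n_steps = 4, seed = 11)
  truth <- attr(tr, "events")
  gv <- lowpass_filter(tr$grf[, 3], tr$force_rate)
  ev <- detect_stance_phases(gv, tr$force_rate)
  expect_equal(nrow(ev), 4L)
  hs_s <- (ev$heel_strike_idx - 1) / tr$force_rate
  to_s <- (ev$toe_off_idx - 1) / tr$force_rate
  # within one frame of the analytic threshold-crossing times
  expect_lt(max(abs(hs_s - truth$detect_hs_s)), 1 / tr$force_rate + 1e-12)
  expect_lt(max(abs(to_s - truth$detect_to_s)), 1 / tr$force_rate + 1e-12)
  # and the threshold bias to the true contact interval stays small
  expect_lt(max(abs(hs_s - truth$heel_strike_s)), 0.015)
  expect_lt(max(abs(to_s - truth$toe_off_s)), 0.015)
})

test_that("extract_cycles yields clean 101-point cycles with the trial's FPA", {
  cfg <- sim_config(noise_mm = 0.2)
  tr <- simulate_trial(cfg, n_steps = 4, seed = 5, fpa_deg = 6)
  cycles <- extract_cycles(tr)
  expect_equal(length(cycles), 4L)
  for (cy in cycles) {
    expect_s3_class(cy, "stance_cycle")
    expect_true(all(cy$channels$GRF_V >= 0))
    expect_equal(length(cy$channels$KJC_ML), 101L)
    expect_lt(abs(cy$fpa_deg - 6), 0.5)
  }
  # pelvis-relative = lab - pelvis: KJC_ML must differ from lab by the
  # simulated pelvis sway (zero at heel strike, about -20 mm midstance)
  cy <- cycles[[1]]
  sway <- cy$channels$KJC_LAB_ML - cy$channels$KJC_ML
  expect_lt(abs(sway[1]), 2)
  expect_lt(abs(min(sway) - (-20)), 3)
})

test_that("marker gaps: short gaps interpolated, steps with long gaps dropped", {
  cfg <- sim_config(noise_mm = 0)
  tr <- simulate_trial(cfg, n_steps = 3, seed = 9)
  events <- attr(tr, "events")
  # short gap (5 frames) inside step 2's stance window: filled, step kept
  i2 <- round(events$heel_strike_s[2] * tr$marker_rate) + 20
  tr_short <- tr
  tr_short$markers$LEPI[i2:(i2 + 4), ] <- NA_real_
  expect_equal(length(extract_cycles(tr_short)), 3L)
  # long gap (25 frames): the enclosing step is dropped
  tr_long <- tr
  tr_long$markers$LEPI[i2:(i2 + 24), ] <- NA_real_
  expect_equal(length(extract_cycles(tr_long)), 2L)
})
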