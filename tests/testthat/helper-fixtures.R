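# Shared fixtures: tiny cohorts and hand-built cycles.

# a stance cycle with every channel constant (easy to reason about)
const_cycle <- function(value = 0, subject_id = "S001", condition = "baseline",
                        grf_v = 700, duration_s = 0.6, fpa_deg = 4,
                        rel_toe_in_deg = NA_real_) {
  ch <- lapply(toeinkam:::CYCLE_CHANNELS, function(x) rep(value, 101))
  names(ch) <- toeinkam:::CYCLE_CHANNELS
  ch$GRF_V <- rep(grf_v, 101)
  stance_cycle(subject_id, condition, 1L, ch, fpa_deg = fpa_deg,
               rel_toe_in_deg = rel_toe_in_deg, duration_s = duration_s)
}

# modify one channel of a cycle
set_channel <- function(cycle, channel, values) {
  cycle$channels[[channel]] <- rep_len(values, 101)
  cycle
}

# small noise-free cohort with integer per-step toe-in angles: every
# subject's toe-in response is exactly theta * g_c(t)
noise_free_cohort <- function(n_subjects = 6, seed = 42) {
  simulate_cohort(sim_config(n_subjects = n_subjects, noise_mm = 0,
                             fpa_jitter_deg = 0),
                  seed = seed)
}

expect_cycles_equal <- function(a, b, tolerance = 1e-12) {
  for (ch in toeinkam:::CYCLE_CHANNELS)
    expect_equal(a$channels[[ch]], b$channels[[ch]], tolerance = tolerance,
                 info = ch)
}
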