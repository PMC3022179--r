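test_that("noiseless rectangular events are recovered exactly", {
  tr <- rect_trace(onsets = c(1, 4, 8), durations = c(1, 2, 3),
                   amplitude = 10, total = 30)
  ev <- idealize_trace(tr, idealize_params(unit_amplitude = 10))
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$duration_s, c(1, 2, 3), tolerance = 1.5e-3)  # +/- 1 sample
  expect_equal(ev$amplitude_pA, rep(10, 3), tolerance = 1e-9)
  expect_equal(ev$level, rep(1L, 3))
})

test_that("event count is stable under 10% amplitude noise", {
  base <- rect_trace(onsets = c(1, 4, 8), durations = c(1, 2, 3),
                     amplitude = 10, total = 30)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- current_trace(base$time_s,
                           base$current_pA + rnorm(length(base$time_s), 0, 1),
                           voltage_mV = 60, sampling_rate_Hz = 1000)
    nrow(idealize_trace(noisy, idealize_params(unit_amplitude = 10)))
  }, 0L)
  expect_gte(mean(hits == 3L), 0.99)
})

test_that("degenerate traces are handled per contract", {
  flat <- current_trace((0:999) / 1000, rnorm(1000, 0, 0.1), 60, 1000)
  # all-baseline with a fixed unit amplitude: empty table
  ev <- idealize_trace(flat, idealize_params(unit_amplitude = 10))
  expect_equal(nrow(ev), 0L)
  # flat trace with auto unit: no unit detectable
  expect_error(idealize_trace(flat, idealize_params(unit_amplitude = "auto")),
               class = "chankit_no_unit_detectable")
  # non-uniform sampling is a format error
  bad <- current_trace(c(0, 0.001, 0.003, 0.007), rep(0, 4), 60, 1000)
  expect_error(idealize_trace(bad), class = "chankit_format_error")
})

test_that("auto unit amplitude finds the first open level", {
  tr <- rect_trace(onsets = seq(1, 55, by = 3), durations = rep(1, 19),
                   amplitude = 9.66, total = 60)
  noisy <- current_trace(tr$time_s, tr$current_pA +
                           rnorm(length(tr$time_s), 0, 0.5),
                         voltage_mV = 60, sampling_rate_Hz = 1000)
  set.seed(1)
  ev <- idealize_trace(noisy)  # auto unit, median baseline
  expect_equal(nrow(ev), 19L)
  expect_equal(mean(ev$amplitude_pA), 9.66, tolerance = 0.05)
})

test_that("idealization round trip recovers simulated ground truth", {
  m <- sparse_model()  # noise 1.4 pA vs 9.66 pA amplitude (0.145x)
  params <- idealize_params(dead_time = 0.01)
  tot_truth <- 0L; tot_recalled <- 0L
  for (s in 1:20) {
    truth <- simulate_event_table(m, voltage = 60, duration = 300, seed = s)
    tr <- simulate_trace(m, voltage = 60, duration = 300, seed = s)
    det <- idealize_trace(tr, params)
    eligible <- truth[truth$duration_s >= 5 * params$dead_time, , drop = FALSE]
    rec <- recall_events(eligible, det, dur_tol = 2 * params$dead_time)
    tot_truth <- tot_truth + nrow(eligible)
    tot_recalled <- tot_recalled + sum(rec)
  }
  expect_gt(tot_truth, 150)
  expect_gte(tot_recalled / tot_truth, 0.95)
})

test_that("output events respect dead time and onset ordering", {
  m <- gating_model(opening_rate = 30, dwell_tau1 = 0.1, noise_sd = 0.8,
                    unit_conductance_sd = 0.02)
  tr <- simulate_trace(m, voltage = 60, duration = 120, seed = 5)
  ev <- idealize_trace(tr, idealize_params(dead_time = 0.01,
                                           unit_amplitude = 9.66))
  expect_true(all(ev$duration_s >= 0.01))
  for (k in unique(ev$level))
    expect_true(!is.unsorted(ev$onset_s[ev$level == k], strictly = TRUE))
})

test_that("event frequency is count over minutes, with burst exclusion", {
  ev <- event_table(data.frame(onset_s = seq(0, 108, by = 12),
                               duration_s = rep(0.5, 10),
                               amplitude_pA = rep(10, 10)),
                    recording_s = 120)
  expect_equal(event_frequency(ev), 5.0)

  empty <- event_table(data.frame(onset_s = numeric(0),
                                  duration_s = numeric(0),
                                  amplitude_pA = numeric(0)),
                       recording_s = 60)
  expect_equal(event_frequency(empty), 0)

  expect_error(event_frequency(event_table(
    data.frame(onset_s = 1, duration_s = 1, amplitude_pA = 1),
    recording_s = 0)), class = "chankit_invalid_parameter")

  # bursts: 2 of 10 events flagged inside a 60 s window
  evb <- event_table(data.frame(onset_s = seq(0, 108, by = 12),
                                duration_s = rep(0.5, 10),
                                amplitude_pA = rep(10, 10),
                                in_burst = c(rep(FALSE, 8), TRUE, TRUE)),
                     recording_s = 120,
                     burst_windows = matrix(c(90, 120), ncol = 2))
  expect_equal(event_frequency(evb, exclude_bursts = TRUE), 8 / (90 / 60))
})

test_that("idealized frequency tracks a Poisson generator", {
  m <- gating_model(opening_rate = 7.73, dwell_tau1 = 0.3,
                    unit_conductance_sd = 0.02, noise_sd = 0.8)
  freqs <- vapply(1:60, function(s) {
    ev <- simulate_event_table(m, voltage = 60, duration = 300, seed = 100 + s)
    event_frequency(ev)
  }, 0)
  se <- sqrt(7.73 / 5) / sqrt(60)
  expect_lt(abs(mean(freqs) - 7.73), 3 * se)
})
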