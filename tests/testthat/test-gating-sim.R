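test_that("trace sampling grid and degenerate silence are exact", {
  m <- control_model(noise_sd = 0)
  tr <- simulate_trace(m, voltage = 60, duration = 10, sampling_rate = 1000,
                       seed = 1)
  expect_length(tr$time_s, 10000L)
  expect_equal(diff(tr$time_s), rep(1e-3, 9999))

  quiet <- gating_model(opening_rate = 0, noise_sd = 0)
  tr0 <- simulate_trace(quiet, duration = 2, sampling_rate = 500, seed = 1)
  expect_identical(unique(tr0$current_pA), 0)
})

test_that("simulation is seed-deterministic and trace embeds the event table", {
  m <- gating_model(opening_rate = 20, noise_sd = 0.3,
                    unit_conductance_sd = 0.03)
  a <- simulate_trace(m, voltage = 60, duration = 30, seed = 11)
  b <- simulate_trace(m, voltage = 60, duration = 30, seed = 11)
  expect_identical(a, b)
  ev1 <- simulate_event_table(m, voltage = 60, duration = 30, seed = 11)
  ev2 <- simulate_event_table(m, voltage = 60, duration = 30, seed = 11)
  expect_identical(ev1, ev2)
  expect_false(identical(
    ev1, simulate_event_table(m, voltage = 60, duration = 30, seed = 12)))

  # rebuilding a noiseless trace from the event table reproduces the trace,
  # so the same seed embeds exactly these events; the rebuild applies the
  # same saturation rule (arrivals at a full stack carry no extra current)
  m0 <- gating_model(opening_rate = 20, noise_sd = 0,
                     unit_conductance_sd = 0.03)
  tr <- simulate_trace(m0, voltage = 60, duration = 30, seed = 11)
  ev <- simulate_event_table(m0, voltage = 60, duration = 30, seed = 11)
  rebuilt <- numeric(length(tr$time_s))
  fs <- tr$sampling_rate_Hz
  open_ends <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    open_ends <- open_ends[open_ends > ev$onset_s[i]]
    if (length(open_ends) >= m0$max_stack) next
    open_ends <- c(open_ends, ev$onset_s[i] + ev$duration_s[i])
    i1 <- floor(ev$onset_s[i] * fs) + 1
    i2 <- min(ceiling((ev$onset_s[i] + ev$duration_s[i]) * fs),
              length(rebuilt))
    rebuilt[i1:i2] <- rebuilt[i1:i2] + ev$amplitude_pA[i]
  }
  expect_equal(rebuilt, tr$current_pA)
})

test_that("dwell-time mixture has the exponential-mixture moments", {
  n <- 1e5
  d <- simulate_dwell_times(n, w = 1, tau1 = 2.07, seed = 4)
  expect_lt(abs(mean(d) - 2.07), 3 * 2.07 / sqrt(n))

  # general mixture mean w*tau1 + (1-w)*tau2, several parameter sets
  cases <- list(c(0.8, 1.53, 8.34), c(0.3, 0.5, 4), c(0.5, 1, 1))
  for (cs in cases) {
    d <- simulate_dwell_times(2e4, w = cs[1], tau1 = cs[2], tau2 = cs[3],
                              seed = 9)
    mu <- cs[1] * cs[2] + (1 - cs[1]) * cs[3]
    sd_th <- sqrt(cs[1] * 2 * cs[2]^2 + (1 - cs[1]) * 2 * cs[3]^2 - mu^2)
    expect_lt(abs(mean(d) - mu), 3 * sd_th / sqrt(2e4))
  }
})

test_that("dwell-time sampler validates its arguments", {
  expect_error(simulate_dwell_times(0, w = 1, tau1 = 2),
               class = "chankit_invalid_parameter")
  expect_error(simulate_dwell_times(10, w = 1.2, tau1 = 2),
               class = "chankit_invalid_parameter")
  expect_error(simulate_dwell_times(10, w = 0.5, tau1 = 2),
               class = "chankit_invalid_parameter")  # tau2 missing
  expect_error(simulate_trace(control_model(), duration = -1),
               class = "chankit_invalid_parameter")
})

test_that("event arrivals are Poisson at the model rate", {
  m <- gating_model(opening_rate = 5, dwell_tau1 = 0.2, noise_sd = 0)
  counts <- vapply(1:500, function(s)
    nrow(simulate_event_table(m, voltage = 60, duration = 120, seed = s)),
    0L)
  expect_gt(mean(counts), 9.0)   # expected 10 events per 2-min recording
  expect_lt(mean(counts), 11.0)

  # inter-onset exponentiality (no bursts): KS against Exp(rate)
  busy <- gating_model(opening_rate = 600, dwell_tau1 = 0.05, noise_sd = 0)
  ev <- simulate_event_table(busy, voltage = 60, duration = 1000, seed = 2)
  gaps <- diff(ev$onset_s)
  ks <- suppressWarnings(ks.test(gaps, "pexp", rate = 600 / 60))
  expect_gt(ks$p.value, 0.01)
})

test_that("embedded event conductances follow the unit-conductance Gaussian", {
  m <- gating_model(opening_rate = 120, dwell_tau1 = 0.05,
                    unit_conductance_mean = 0.161,
                    unit_conductance_sd = 0.02, noise_sd = 0)
  ev <- simulate_event_table(m, voltage = 60, duration = 600, seed = 3)
  expect_gt(nrow(ev), 1000)
  g <- ev$amplitude_pA / 60
  ks <- suppressWarnings(ks.test(g, "pnorm", mean = 0.161, sd = 0.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("burst windows multiply the opening rate and are flagged", {
  m <- gating_model(opening_rate = 10, dwell_tau1 = 0.2, noise_sd = 0,
                    burst_rate = 1, burst_duration = 10, burst_intensity = 8)
  ev <- simulate_event_table(m, voltage = 60, duration = 600, seed = 6)
  expect_true(any(ev$in_burst))
  expect_true(any(!ev$in_burst))
  bw <- attr(ev, "burst_windows")
  expect_true(nrow(bw) >= 1)
  burst_time <- sum(bw[, 2] - bw[, 1])
  in_rate <- sum(ev$in_burst) / (burst_time / 60)
  out_rate <- sum(!ev$in_burst) / ((600 - burst_time) / 60)
  expect_gt(in_rate, 3 * out_rate)
})

test_that("stacked openings are capped at max_stack in the rendered trace", {
  m <- gating_model(opening_rate = 120, dwell_tau1 = 1,
                    unit_conductance_mean = 0.161, unit_conductance_sd = 0,
                    noise_sd = 0, max_stack = 2L)
  tr <- simulate_trace(m, voltage = 60, duration = 60, seed = 8)
  unit <- 0.161 * 60
  expect_lte(max(tr$current_pA), 2 * unit + 1e-9)
  ev <- simulate_event_table(m, voltage = 60, duration = 60, seed = 8)
  expect_lte(max(ev$level), 2L)
})
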