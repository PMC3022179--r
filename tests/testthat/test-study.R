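test_that("trace and event tables survive a disk round trip", {
  m <- gating_model(opening_rate = 30, noise_sd = 0.5,
                    burst_rate = 2, burst_duration = 3, burst_intensity = 5,
                    label = "rt")
  tr <- simulate_trace(m, voltage = 60, duration = 20, sampling_rate = 500,
                       seed = 2)
  tmp <- tempfile(fileext = ".csv")
  write_trace(tr, tmp)
  back <- read_trace(tmp)
  expect_equal(back$current_pA, tr$current_pA)
  expect_equal(back$voltage_mV, 60)
  expect_equal(back$sampling_rate_Hz, 500)
  expect_equal(back$meta$burst_windows, tr$meta$burst_windows,
               ignore_attr = TRUE)

  ev <- simulate_event_table(m, voltage = 60, duration = 20, seed = 2)
  tmp2 <- tempfile(fileext = ".tsv")
  write_events(ev, tmp2)
  back2 <- read_events(tmp2)
  expect_equal(as.data.frame(back2), as.data.frame(ev), tolerance = 1e-9)
  expect_equal(attr(back2, "recording_s"), 20)
  expect_equal(event_frequency(back2, exclude_bursts = TRUE),
               event_frequency(ev, exclude_bursts = TRUE))
})

test_that("a two-condition study reproduces the frequency doubling", {
  cfg <- study_config(
    conditions = list(
      # short dwells keep overlap rare so counted frequency tracks the rate
      control = gating_model(opening_rate = 7.73, dwell_tau1 = 0.3,
                             unit_conductance_mean = 0.161,
                             unit_conductance_sd = 0.03, noise_sd = 0.5,
                             label = "control"),
      choline = gating_model(opening_rate = 15.97, dwell_tau1 = 0.25,
                             dwell_tau2 = 1.2, dwell_w = 0.8,
                             unit_conductance_mean = 0.215,
                             unit_conductance_sd = 0.03, noise_sd = 0.5,
                             label = "choline")),
    voltages = 60, duration_s = 900, sampling_rate = 500, seed = 7)
  rep <- run_study(cfg)

  fr <- rep$frequency
  f_ctl <- fr$frequency_per_min[fr$condition == "control"]
  f_cho <- fr$frequency_per_min[fr$condition == "choline"]
  expect_gt(f_cho / f_ctl, 1.5)   # choline roughly doubles the frequency
  expect_lt(f_cho / f_ctl, 2.8)

  expect_equal(nrow(rep$comparisons), 1)
  expect_lt(rep$comparisons$p_value, 0.05)

  lt <- rep$lifetime
  expect_true(all(c("control", "choline") %in% lt$condition))
  expect_true(all(lt$tau1_s > 0))
  expect_true(all(c("simulate", "idealize", "lifetime") %in% rep$log$stage))
})

test_that("studies are deterministic given the seed", {
  cfg <- study_config(
    conditions = list(c1 = gating_model(opening_rate = 20, noise_sd = 0.4)),
    voltages = c(60, -60), duration_s = 120, sampling_rate = 500, seed = 3)
  a <- run_study(cfg)
  b <- run_study(cfg)
  expect_identical(a$conductance, b$conductance)
  expect_identical(a$frequency, b$frequency)
  expect_identical(a$lifetime, b$lifetime)
})

test_that("study configuration is validated", {
  expect_error(study_config(conditions = list()),
               class = "chankit_invalid_parameter")
  expect_error(study_config(conditions = list(gating_model())),
               class = "chankit_invalid_parameter")  # unnamed
  expect_error(study_config(conditions = list(a = gating_model()),
                            voltages = c(60, 0)),
               class = "chankit_invalid_parameter")
})

test_that("fixtures are generated with a manifest and stable schemas", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  m1 <- make_fixtures(seed = 1, out_dir = d1)
  m2 <- make_fixtures(seed = 2, out_dir = d2)

  for (f in names(m1$files))
    expect_true(file.exists(file.path(d1, f)))
  expect_true(file.exists(file.path(d1, "manifest.json")))

  t1 <- read_trace(file.path(d1, "trace_control.csv"))
  t2 <- read_trace(file.path(d2, "trace_control.csv"))
  expect_false(identical(t1$current_pA, t2$current_pA))
  expect_identical(length(t1$current_pA), length(t2$current_pA))

  # the I-V fixture inverts back to the generating selectivity
  iv <- read.csv(file.path(d1, "iv_choline_cis.csv"))
  fit <- fit_reversal_potential(iv)
  expect_lt(abs(fit$v_rev_mV - ghk_reversal(0.46, kcl_conditions(100, 50))),
            0.5)
})

test_that("command-line front end inverts GHK and simulates traces", {
  cli <- system.file("cli", "chankit.R", package = "chankit")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  # child process must see the library this package is installed in
  lib_env <- paste0("R_LIBS=",
                    paste(.libPaths(), collapse = .Platform$path.sep))

  out <- system2(rscript, c(cli, "selectivity", "--vrev", "6.87",
                            "--cis", "100", "--trans", "50"),
                 stdout = TRUE, stderr = FALSE, env = lib_env)
  got <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(round(got$ratio, 2), 0.43)

  bad <- suppressWarnings(
    system2(rscript, c(cli, "nonsense"), stdout = FALSE, stderr = FALSE,
            env = lib_env))
  expect_equal(bad, 2)
})
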