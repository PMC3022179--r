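test_that("survival curve counts events open at least t", {
  s <- survival_curve(c(1, 2, 3))
  expect_equal(s$t, c(1, 2, 3))
  expect_equal(s$n_open, c(3, 2, 1))

  tied <- survival_curve(c(5, 5, 5))
  expect_equal(tied$t, 5)
  expect_equal(tied$n_open, 3)
  expect_equal(tied$n_total, 3)

  expect_error(survival_curve(numeric(0)),
               class = "chankit_invalid_parameter")

  # N(0+) conservation
  d <- simulate_dwell_times(500, tau1 = 2, seed = 3)
  expect_equal(max(survival_curve(d)$n_open), 500)
})

test_that("log-survival slope matches the exponential rate", {
  d <- simulate_dwell_times(1e4, tau1 = 2.07, seed = 12)
  s <- survival_curve(d)
  keep <- s$n_open >= 10   # avoid the noisy tail
  slope <- unname(coef(lm(log(s$n_open[keep]) ~ s$t[keep]))[2])
  expect_lt(abs(slope - (-1 / 2.07)), 0.05 / 2.07)
})

test_that("noiseless single-exponential curve is fitted exactly", {
  grid <- seq(0.05, 10, by = 0.05)
  curve <- structure(list(t = grid, n_open = 100 * exp(-grid / 2),
                          n_total = 100), class = "survival_curve")
  fit <- fit_lifetime(curve, order = 1)
  expect_equal(fit$tau1, 2, tolerance = 1e-6)
  expect_equal(fit$A1, 100, tolerance = 1e-4)
  expect_equal(fit$A2, 0)
  expect_lt(fit$ss_resid, 1e-8)
})

test_that("order-2 fit recovers two-exponential mixture parameters", {
  d <- simulate_dwell_times(2000, w = 0.8, tau1 = 1.53, tau2 = 8.34, seed = 21)
  fit <- fit_lifetime(d, order = 2)
  expect_true(fit$converged)
  expect_lt(fit$tau1, fit$tau2)  # canonical order
  expect_lt(abs(fit$tau1 - 1.53) / 1.53, 0.10)
  expect_lt(abs(fit$tau2 - 8.34) / 8.34, 0.15)

  # invariant to permuted initial component labels
  fit_rev <- fit_lifetime(d, order = 2,
                          init = c(A1 = 400, tau1 = 8, A2 = 1600, tau2 = 1.5))
  expect_equal(fit_rev$tau1, fit$tau1, tolerance = 1e-3)
  expect_equal(fit_rev$tau2, fit$tau2, tolerance = 1e-3)
})

test_that("order-2 fit on single-exponential data degenerates gracefully", {
  d <- simulate_dwell_times(1000, tau1 = 2, seed = 31)
  f2 <- fit_lifetime(d, order = 2)
  # either a vanishing second amplitude or two equal time constants
  expect_true(min(f2$A1, f2$A2) < 0.05 * 1000 ||
                f2$tau2 / f2$tau1 < 1.5)
})

test_that("fits validate their inputs", {
  expect_error(fit_lifetime(c(1, 2, 3), order = 2),
               class = "chankit_insufficient_data")
  expect_error(fit_lifetime(simulate_dwell_times(100, tau1 = 1, seed = 1),
                            order = 3),
               class = "chankit_invalid_parameter")
})

test_that("F-test selection prefers the simpler model on equal fits", {
  d <- simulate_dwell_times(300, tau1 = 2, seed = 41)
  f1 <- fit_lifetime(d, order = 1)
  # fabricate an order-2 fit with identical SS: F must be 0, P 1, order 1
  f2 <- f1
  f2$order <- 2L; f2$A2 <- 0; f2$tau2 <- f1$tau1
  f2$df <- f1$df - 2L
  class(f2) <- "lifetime_fit"
  sel <- select_lifetime_model(f1, f2)
  expect_equal(sel$F, 0)
  expect_equal(sel$p_value, 1)
  expect_equal(sel$selected_order, 1L)

  # a worse order-2 fit clips F at 0
  f2$ss_resid <- f1$ss_resid * 1.1
  sel2 <- select_lifetime_model(f1, f2)
  expect_equal(sel2$F, 0)
  expect_equal(sel2$selected_order, 1L)
})

test_that("F-test has power against a genuine two-component mixture", {
  hits <- vapply(1:100, function(s) {
    d <- simulate_dwell_times(500, w = 0.8, tau1 = 1.53, tau2 = 8.34,
                              seed = 500 + s)
    f1 <- fit_lifetime(d, order = 1)
    f2 <- fit_lifetime(d, order = 2)
    select_lifetime_model(f1, f2)$selected_order == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("borderline selections are flagged indeterminate", {
  d <- simulate_dwell_times(400, tau1 = 2, seed = 51)
  f1 <- fit_lifetime(d, order = 1)
  f2 <- fit_lifetime(d, order = 2)
  sel <- select_lifetime_model(f1, f2, alpha = 0.05)
  expect_identical(sel$indeterminate,
                   sel$p_value >= 0.05 && sel$p_value < 0.15)
})

test_that("MLE cross-check agrees with the least-squares fit", {
  d <- simulate_dwell_times(3000, w = 0.8, tau1 = 1.53, tau2 = 8.34, seed = 61)
  ls <- fit_lifetime(d, order = 2)
  ml <- fit_lifetime_mle(d, order = 2)
  expect_lt(abs(ml$tau1 - ls$tau1) / ls$tau1, 0.15)
  expect_lt(abs(ml$tau2 - ls$tau2) / ls$tau2, 0.15)
  ml1 <- fit_lifetime_mle(d, order = 1)
  expect_equal(ml1$tau1, mean(d))
})

test_that("tau1 recovery error shrinks as the sample grows", {
  med_err <- function(n) {
    median(vapply(1:10, function(s) {
      d <- simulate_dwell_times(n, w = 0.8, tau1 = 1.53, tau2 = 8.34,
                                seed = n + s)
      abs(fit_lifetime(d, order = 2)$tau1 - 1.53) / 1.53
    }, 0))
  }
  errs <- vapply(c(200, 1000, 5000), med_err, 0)
  expect_true(all(diff(errs) < 0))
})
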