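# Event generation shared by simulate_trace() and simulate_event_table().
# Both seed the RNG identically and draw events first, so the two functions
# embed exactly the same openings for the same (model, args, seed).
.sim_events <- function(model, voltage, duration, seed) {
  set.seed(as.integer(seed))
  rate_s <- .rate_at(model, voltage) / 60

  # burst windows: Poisson onsets, fixed width, clipped to the recording
  windows <- matrix(numeric(0), ncol = 2)
  if (model$burst_rate > 0 && model$burst_duration > 0) {
    nb <- stats::rpois(1L, model$burst_rate / 60 * duration)
    if (nb > 0) {
      bo <- sort(stats::runif(nb, 0, duration))
      windows <- cbind(bo, pmin(bo + model$burst_duration, duration))
    }
  }

  # arrivals: homogeneous base process plus an extra process confined to the
  # burst windows at rate (intensity - 1) * base
  n1 <- stats::rpois(1L, rate_s * duration)
  onsets <- stats::runif(n1, 0, duration)
  if (nrow(windows) > 0 && model$burst_intensity > 1) {
    widths <- windows[, 2] - windows[, 1]
    total <- sum(widths)
    n2 <- stats::rpois(1L, rate_s * (model$burst_intensity - 1) * total)
    if (n2 > 0) {
      pos <- stats::runif(n2, 0, total)
      cum <- c(0, cumsum(widths))
      idx <- findInterval(pos, cum, rightmost.closed = TRUE)
      onsets <- c(onsets, windows[idx, 1] + (pos - cum[idx]))
    }
  }
  onsets <- sort(onsets)
  n <- length(onsets)

  if (n == 0L) {
    ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     amplitude_pA = numeric(0), level = integer(0),
                     in_burst = logical(0))
    return(list(events = ev, rendered = logical(0), windows = windows))
  }

  comp_fast <- stats::runif(n) < model$dwell_w
  tau <- ifelse(comp_fast, model$dwell_tau1,
                if (is.null(model$dwell_tau2)) model$dwell_tau1
                else model$dwell_tau2)
  durs <- stats::rexp(n, rate = 1 / tau)
  g <- stats::rnorm(n, model$unit_conductance_mean, model$unit_conductance_sd)
  g <- pmax(g, 1e-6)
  amp <- g * voltage                       # nS * mV = pA, signed by voltage

  # stacking: level index = concurrent rendered openings at onset; arrivals
  # at a full stack are kept in the table but not rendered in the trace
  level <- integer(n)
  rendered <- logical(n)
  open_ends <- numeric(0)
  for (i in seq_len(n)) {
    open_ends <- open_ends[open_ends > onsets[i]]
    k <- length(open_ends)
    if (k < model$max_stack) {
      rendered[i] <- TRUE
      open_ends <- c(open_ends, onsets[i] + durs[i])
      level[i] <- k + 1L
    } else {
      level[i] <- model$max_stack
    }
  }

  in_burst <- rep(FALSE, n)
  if (nrow(windows) > 0) {
    for (w in seq_len(nrow(windows)))
      in_burst <- in_burst |
        (onsets < windows[w, 2] & (onsets + durs) > windows[w, 1])
  }

  ev <- data.frame(onset_s = onsets, duration_s = durs, amplitude_pA = amp,
                   level = level, in_burst = in_burst)
  list(events = ev, rendered = rendered, windows = windows)
}

#' Draw open dwell times from an exponential mixture
#'
#' Samples i.i.d. open lifetimes from
#' `w * Exp(tau1) + (1 - w) * Exp(tau2)`: the component is chosen
#' Bernoulli(`w`) and the duration is exponential with the chosen mean.
#'
#' @param n Number of draws (>= 1).
#' @param w Fast-component weight in `[0, 1]`; `w = 1` collapses to a single
#'   exponential and `tau2` may then be omitted.
#' @param tau1,tau2 Component means (s), both > 0.
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of `n` durations (s).
#' @examples
#' d <- simulate_dwell_times(1000, w = 0.8, tau1 = 1.53, tau2 = 8.34, seed = 1)
#' mean(d)  # close to 0.8 * 1.53 + 0.2 * 8.34
#' @export
simulate_dwell_times <- function(n, w = 1, tau1, tau2 = NULL, seed = NULL) {
  .chk_number(n, "n", 1)
  .chk_number(w, "w", 0, 1)
  .chk_number(tau1, "tau1", 0, strict_lower = TRUE)
  if (!is.null(tau2)) .chk_number(tau2, "tau2", 0, strict_lower = TRUE)
  if (w < 1 && is.null(tau2))
    .chk_stop("`tau2` is required when `w` < 1", "chankit_invalid_parameter")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n)
  comp_fast <- stats::runif(n) < w
  tau <- ifelse(comp_fast, tau1, if (is.null(tau2)) tau1 else tau2)
  stats::rexp(n, rate = 1 / tau)
}

#' Simulate the ground-truth event table of a recording
#'
#' Generates the exact channel openings (onset, duration, amplitude, level,
#' burst flag) of a simulated recording, without rasterization or noise.
#' Called with the same `(model, voltage, duration, seed)` as
#' [simulate_trace()], it returns precisely the events embedded in that
#' trace, which makes it the ground truth for testing idealization.
#'
#' @param model A [gating_model()].
#' @param voltage Applied voltage (mV, trans-side sign convention).
#' @param duration Recording length (s), > 0.
#' @param seed Integer seed.
#' @return An [event_table()] with `recording_s` and burst-window attributes.
#' @export
simulate_event_table <- function(model, voltage = 60, duration = 60, seed = 1) {
  stopifnot(inherits(model, "gating_model"))
  .chk_number(duration, "duration", 0, strict_lower = TRUE)
  sim <- .sim_events(model, voltage, duration, seed)
  event_table(sim$events, recording_s = duration, burst_windows = sim$windows,
              voltage_mV = voltage, condition = model$label)
}

#' Simulate a sampled single-channel current trace
#'
#' Renders a recording as rectangular openings on a noisy baseline: openings
#' arrive as a Poisson process at the model's opening rate, each with a
#' constant amplitude `level x g x voltage` where the unit conductance `g`
#' is drawn per event from the model's Gaussian, plus additive Gaussian
#' baseline noise. Identical seeds give bit-identical traces.
#'
#' @inheritParams simulate_event_table
#' @param sampling_rate Samples per second (>= 100 Hz).
#' @param cis_KCl_mM,trans_KCl_mM,temperature_C Bath metadata carried into
#'   the trace (defaults: symmetric 50 mM KCl, 23 degrees C).
#' @return A `current_trace` object.
#' @examples
#' m <- gating_model(noise_sd = 0.3)
#' tr <- simulate_trace(m, voltage = 60, duration = 5, sampling_rate = 1000,
#'                      seed = 7)
#' tr
#' @export
simulate_trace <- function(model, voltage = 60, duration = 60,
                           sampling_rate = 1000, seed = 1,
                           cis_KCl_mM = 50, trans_KCl_mM = 50,
                           temperature_C = 23) {
  stopifnot(inherits(model, "gating_model"))
  .chk_number(duration, "duration", 0, strict_lower = TRUE)
  .chk_number(sampling_rate, "sampling_rate", 100)

  sim <- .sim_events(model, voltage, duration, seed)
  n_samp <- as.integer(round(duration * sampling_rate))
  times <- (seq_len(n_samp) - 1L) / sampling_rate
  current <- numeric(n_samp)

  ev <- sim$events[sim$rendered, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    i1 <- floor(ev$onset_s[i] * sampling_rate) + 1L
    i2 <- ceiling((ev$onset_s[i] + ev$duration_s[i]) * sampling_rate)
    i1 <- max(i1, 1L); i2 <- min(i2, n_samp)
    if (i2 >= i1)
      current[i1:i2] <- current[i1:i2] + ev$amplitude_pA[i]
  }
  if (model$noise_sd > 0)
    current <- current + stats::rnorm(n_samp, 0, model$noise_sd)

  current_trace(times, current, voltage_mV = voltage,
                sampling_rate_Hz = sampling_rate,
                condition = model$label,
                cis_KCl_mM = cis_KCl_mM, trans_KCl_mM = trans_KCl_mM,
                temperature_C = temperature_C, seed = seed,
                burst_windows = sim$windows)
}

#' Simulate recordings from a gating model
#'
#' `simulate()` method: returns one `current_trace` (or a list of `nsim`
#' traces with consecutive derived seeds).
#'
#' @param object A [gating_model()].
#' @param nsim Number of traces.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_trace()] (`voltage`, `duration`,
#'   `sampling_rate`, bath metadata).
#' @return A `current_trace`, or a list of them when `nsim > 1`.
#' @export
simulate.gating_model <- function(object, nsim = 1, seed = 1, ...) {
  if (nsim == 1) return(simulate_trace(object, seed = seed, ...))
  lapply(seq_len(nsim), function(i)
    simulate_trace(object, seed = .derive_seed(seed, i), ...))
}
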