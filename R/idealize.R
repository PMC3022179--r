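#' Idealization parameters
#'
#' Settings for the half-amplitude threshold idealization in
#' [idealize_trace()].
#'
#' @param baseline `"median"` (robust default: openings are sparse, so the
#'   trace median sits on the closed level) or a fixed baseline current (pA).
#' @param unit_amplitude Single-level opening amplitude in pA (magnitude), or
#'   `"auto"` to estimate it from the first non-baseline mode of the
#'   amplitude distribution.
#' @param threshold_fraction Fraction of the unit amplitude at which a level
#'   transition is declared; 0.5 is the standard half-amplitude criterion.
#' @param dead_time Minimum resolvable event duration (s). Events shorter
#'   than this are discarded; 10 ms is the worst-case resolution of a
#'   chart-recorder setup.
#' @param max_levels Maximum number of stacked open levels considered.
#' @return An object of class `idealize_params`.
#' @export
idealize_params <- function(baseline = "median", unit_amplitude = "auto",
                            threshold_fraction = 0.5, dead_time = 0.01,
                            max_levels = 5L) {
  if (!(identical(baseline, "median") ||
        (is.numeric(baseline) && length(baseline) == 1L)))
    .chk_stop("`baseline` must be \"median\" or a fixed pA value",
              "chankit_invalid_parameter")
  if (!(identical(unit_amplitude, "auto") ||
        (is.numeric(unit_amplitude) && length(unit_amplitude) == 1L &&
         unit_amplitude > 0)))
    .chk_stop("`unit_amplitude` must be \"auto\" or a positive pA value",
              "chankit_invalid_parameter")
  .chk_number(threshold_fraction, "threshold_fraction", 0, 1,
              strict_lower = TRUE)
  if (threshold_fraction >= 1)
    .chk_stop("`threshold_fraction` must be in (0, 1)",
              "chankit_invalid_parameter")
  .chk_number(dead_time, "dead_time", 0)
  .chk_number(max_levels, "max_levels", 1)
  structure(list(baseline = baseline, unit_amplitude = unit_amplitude,
                 threshold_fraction = threshold_fraction,
                 dead_time = dead_time, max_levels = as.integer(max_levels)),
            class = "idealize_params")
}

# First non-baseline mode of the deviation distribution: density of samples
# clearly above the noise floor, first local maximum with appreciable mass.
.auto_unit_amplitude <- function(dev) {
  noise <- stats::mad(dev)
  open <- dev[dev > max(5 * noise, 1e-12)]
  if (length(open) < 10)
    .chk_stop("no unit amplitude detectable: trace has no openings above noise",
              "chankit_no_unit_detectable")
  d <- stats::density(open, n = 512)
  y <- d$y
  # first substantial mode (the single-level plateau); minor bumps from
  # transition samples are ignored, then the estimate is sharpened to the
  # median of the samples around that plateau
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] >= 0.5 * max(y)]
  if (length(peaks) == 0) peaks <- which.max(y)
  u0 <- d$x[peaks[1]]
  stats::median(open[open >= 0.5 * u0 & open <= 1.5 * u0])
}

#' Idealize a current trace into discrete channel events
#'
#' Half-amplitude threshold idealization with multi-level support: the trace
#' is reduced to an integer level occupancy `k(t)` (a level-k opening begins
#' when the baseline-subtracted current crosses
#' `(k - threshold_fraction) x unit_amplitude` and ends on the reverse
#' crossing), stacked openings are decomposed into per-level occupancy
#' segments, and events shorter than the dead time are discarded. The
#' reported per-event amplitude is the plateau mean minus baseline (minus the
#' lower levels' contribution for stacked events), so conductance histograms
#' remain well defined under stacking.
#'
#' @param trace A [current_trace()], uniformly sampled.
#' @param params An [idealize_params()].
#' @return An [event_table()]; events overlapping burst windows flagged in
#'   the trace metadata are marked `in_burst`.
#' @examples
#' m <- gating_model(noise_sd = 0.4)
#' tr <- simulate_trace(m, voltage = 60, duration = 120, seed = 3)
#' ev <- idealize_trace(tr)
#' event_frequency(ev)
#' @export
idealize_trace <- function(trace, params = idealize_params()) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(params, "idealize_params"))
  n <- length(trace$time_s)
  if (n < 2) .chk_stop("trace too short", "chankit_format_error")
  dt <- diff(trace$time_s)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    .chk_stop("trace is not uniformly sampled", "chankit_format_error")
  fs <- trace$sampling_rate_Hz
  if (is.na(fs)) fs <- 1 / stats::median(dt)

  base <- if (identical(params$baseline, "median"))
    stats::median(trace$current_pA) else params$baseline
  dev <- trace$current_pA - base
  # openings deflect in the voltage's direction; fall back to the dominant
  # excursion when the voltage is unknown or zero
  pol <- if (!is.na(trace$voltage_mV) && trace$voltage_mV != 0)
    sign(trace$voltage_mV) else if (mean(dev) >= 0) 1 else -1
  dev <- dev * pol

  unit <- if (identical(params$unit_amplitude, "auto"))
    .auto_unit_amplitude(dev) else params$unit_amplitude

  # occupancy with half-amplitude hysteresis-free rule:
  # level k while dev >= (k - threshold_fraction) * unit
  occ <- pmin(pmax(floor(dev / unit + params$threshold_fraction), 0),
              params$max_levels)

  bw <- trace$meta$burst_windows
  dead_samples <- floor(params$dead_time * fs)
  out <- list()
  for (k in seq_len(max(occ, 1L))) {
    on <- occ >= k
    if (!any(on)) next
    # closures shorter than the dead time are unresolvable: bridge internal
    # sub-dead-time gaps before applying the same rule to openings
    if (dead_samples > 0) {
      r <- rle(on)
      if (length(r$lengths) > 2) {
        inner <- seq(2, length(r$lengths) - 1L)
        bridge <- inner[!r$values[inner] & r$lengths[inner] < dead_samples]
        if (length(bridge) > 0) {
          r$values[bridge] <- TRUE
          on <- inverse.rle(r)
        }
      }
    }
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_i <- which(r$values)
    for (j in run_i) {
      i1 <- starts[j]; i2 <- ends[j]
      dur <- (i2 - i1 + 1L) / fs
      if (dur < params$dead_time) next
      sel <- i1:i2
      at_k <- sel[occ[sel] == k]
      amp_k <- if (length(at_k) > 0) mean(dev[at_k]) - (k - 1) * unit else unit
      onset <- trace$time_s[i1]
      in_b <- FALSE
      if (nrow(bw) > 0)
        in_b <- any(onset < bw[, 2] & (onset + dur) > bw[, 1])
      out[[length(out) + 1L]] <- data.frame(
        onset_s = onset, duration_s = dur, amplitude_pA = amp_k * pol,
        level = k, in_burst = in_b)
    }
  }
  ev <- if (length(out) > 0) do.call(rbind, out)
        else data.frame(onset_s = numeric(0), duration_s = numeric(0),
                        amplitude_pA = numeric(0), level = integer(0),
                        in_burst = logical(0))
  ev <- ev[order(ev$level, ev$onset_s), , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  event_table(ev, recording_s = n / fs, burst_windows = bw,
              voltage_mV = trace$voltage_mV, condition = trace$meta$condition)
}
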