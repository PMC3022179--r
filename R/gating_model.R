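#' Stochastic gating model for a single channel in a planar bilayer
#'
#' Defines the generative model used by [simulate_trace()] and
#' [simulate_event_table()]: channel openings arrive as a Poisson process,
#' each opening lasts a duration drawn from a one- or two-component
#' exponential mixture, and each opening conducts with a unit conductance
#' drawn from a Gaussian. Openings may stack up to `max_stack` simultaneous
#' levels in the rendered trace, and optional "paroxystic" burst episodes
#' multiply the opening rate inside flagged windows.
#'
#' Defaults are the control condition of an amyloid-peptide channel in an
#' oxidized-cholesterol bilayer at +60 mV: 7.73 openings/min, single
#' exponential open lifetime with mean 2.07 s, unit conductance
#' 0.161 +/- 0.02 nS, 0.5 pA baseline noise. The conductance spread is kept
#' at about 12% CV so that discrete conductance levels stay resolvable by
#' half-amplitude thresholding, as they are in real recordings of this kind.
#'
#' @param opening_rate Openings per minute (Poisson intensity). Either a
#'   single number or a named vector indexed by applied voltage in mV
#'   (e.g. `c("60" = 7.73, "-60" = 3.2)`).
#' @param dwell_w Mixture weight of the fast open-lifetime component,
#'   in `[0, 1]`. `dwell_w = 1` gives a single exponential.
#' @param dwell_tau1,dwell_tau2 Mean open lifetimes (s) of the fast and slow
#'   components; `dwell_tau1 <= dwell_tau2`. `dwell_tau2` may be `NULL` when
#'   `dwell_w = 1`.
#' @param unit_conductance_mean,unit_conductance_sd Gaussian unit conductance
#'   (nS) drawn once per opening.
#' @param max_stack Maximum number of simultaneously rendered open levels
#'   (integer >= 1). Arrivals while the stack is full still appear in the
#'   event table (they are real openings of a saturated pore) but do not add
#'   current to the trace.
#' @param noise_sd Baseline Gaussian noise (pA) added to rendered traces.
#' @param burst_rate Burst episodes per minute (0 disables bursts).
#' @param burst_duration Duration of a burst window (s).
#' @param burst_intensity Multiplier applied to `opening_rate` inside burst
#'   windows (>= 1).
#' @param label Condition label carried into trace/event metadata.
#'
#' @return An object of class `gating_model`.
#' @seealso [simulate_trace()], [simulate_event_table()],
#'   [simulate_dwell_times()]
#' @examples
#' m <- gating_model(opening_rate = 15.97, unit_conductance_mean = 0.215,
#'                   label = "choline-cis")
#' m
#' @export
gating_model <- function(opening_rate = 7.73,
                         dwell_w = 1,
                         dwell_tau1 = 2.07,
                         dwell_tau2 = NULL,
                         unit_conductance_mean = 0.161,
                         unit_conductance_sd = 0.02,
                         max_stack = 1L,
                         noise_sd = 0.5,
                         burst_rate = 0,
                         burst_duration = 0,
                         burst_intensity = 1,
                         label = "") {
  if (!is.numeric(opening_rate) || length(opening_rate) < 1L ||
      any(is.na(opening_rate)) || any(opening_rate < 0))
    .chk_stop("`opening_rate` must be non-negative (events/min)",
              "chankit_invalid_parameter")
  if (length(opening_rate) > 1L && is.null(names(opening_rate)))
    .chk_stop("a vector `opening_rate` must be named by voltage (mV)",
              "chankit_invalid_parameter")
  .chk_number(dwell_w, "dwell_w", 0, 1)
  .chk_number(dwell_tau1, "dwell_tau1", 0, strict_lower = TRUE)
  if (!is.null(dwell_tau2)) {
    .chk_number(dwell_tau2, "dwell_tau2", 0, strict_lower = TRUE)
    if (dwell_tau1 > dwell_tau2)
      .chk_stop("`dwell_tau1` must not exceed `dwell_tau2`",
                "chankit_invalid_parameter")
  } else if (dwell_w < 1) {
    .chk_stop("`dwell_tau2` is required when `dwell_w` < 1",
              "chankit_invalid_parameter")
  }
  .chk_number(unit_conductance_mean, "unit_conductance_mean", 0,
              strict_lower = TRUE)
  .chk_number(unit_conductance_sd, "unit_conductance_sd", 0)
  .chk_number(max_stack, "max_stack", 1)
  .chk_number(noise_sd, "noise_sd", 0)
  .chk_number(burst_rate, "burst_rate", 0)
  .chk_number(burst_duration, "burst_duration", 0)
  .chk_number(burst_intensity, "burst_intensity", 1)

  structure(list(
    opening_rate = opening_rate,
    dwell_w = dwell_w,
    dwell_tau1 = dwell_tau1,
    dwell_tau2 = dwell_tau2,
    unit_conductance_mean = unit_conductance_mean,
    unit_conductance_sd = unit_conductance_sd,
    max_stack = as.integer(max_stack),
    noise_sd = noise_sd,
    burst_rate = burst_rate,
    burst_duration = burst_duration,
    burst_intensity = burst_intensity,
    label = label
  ), class = "gating_model")
}

# Opening rate (events/min) at a given voltage; vector rates are matched by
# name, falling back to an exact numeric match.
.rate_at <- function(model, voltage) {
  r <- model$opening_rate
  if (length(r) == 1L) return(unname(r))
  key <- as.character(voltage)
  if (key %in% names(r)) return(unname(r[[key]]))
  num <- suppressWarnings(as.numeric(names(r)))
  hit <- which(!is.na(num) & num == voltage)
  if (length(hit) == 1L) return(unname(r[[hit]]))
  .chk_stop(sprintf("no opening rate defined for voltage %g mV", voltage),
            "chankit_invalid_parameter")
}

#' @export
print.gating_model <- function(x, ...) {
  cat("Gating model", if (nzchar(x$label)) sprintf("(%s)", x$label), "\n")
  if (length(x$opening_rate) == 1L) {
    cat(sprintf("  opening rate    : %.3g events/min\n", x$opening_rate))
  } else {
    cat("  opening rate    :",
        paste(sprintf("%s mV: %.3g", names(x$opening_rate), x$opening_rate),
              collapse = ", "), "events/min\n")
  }
  if (x$dwell_w < 1) {
    cat(sprintf("  open lifetime   : mixture w=%.2f, tau1=%.3g s, tau2=%.3g s\n",
                x$dwell_w, x$dwell_tau1, x$dwell_tau2))
  } else {
    cat(sprintf("  open lifetime   : exponential, tau=%.3g s\n", x$dwell_tau1))
  }
  cat(sprintf("  unit conductance: %.3g +/- %.3g nS\n",
              x$unit_conductance_mean, x$unit_conductance_sd))
  cat(sprintf("  max stack       : %d    baseline noise: %.3g pA\n",
              x$max_stack, x$noise_sd))
  if (x$burst_rate > 0)
    cat(sprintf("  bursts          : %.3g/min x %.3g s, intensity %.3g\n",
                x$burst_rate, x$burst_duration, x$burst_intensity))
  invisible(x)
}
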