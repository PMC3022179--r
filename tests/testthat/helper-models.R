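# Shared fixture builders (all synthetic, generated at test time).

# control condition: 7.73 openings/min, tau 2.07 s, 0.161 nS centre
control_model <- function(...) gating_model(label = "control", ...)

# a sparse, well-separated model for idealization round trips: low rate and
# short dwells keep overlapping openings rare
sparse_model <- function(noise_sd = 1.4) {
  gating_model(opening_rate = 3, dwell_tau1 = 0.4,
               unit_conductance_mean = 0.161, unit_conductance_sd = 0.02,
               noise_sd = noise_sd, label = "sparse")
}

# noiseless rectangular test trace: events at given onsets/durations (s),
# fixed amplitude (pA), on a zero baseline
rect_trace <- function(onsets, durations, amplitude = 10, fs = 1000,
                       total = NULL, voltage = 60) {
  if (is.null(total)) total <- max(onsets + durations) + 1
  n <- round(total * fs)
  cur <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  for (k in seq_along(onsets)) {
    sel <- tt >= onsets[k] & tt < onsets[k] + durations[k]
    cur[sel] <- cur[sel] + amplitude
  }
  current_trace(tt, cur, voltage_mV = voltage, sampling_rate_Hz = fs)
}

# match idealized events to ground truth: recalled if some detected event
# starts within `onset_tol` of the true onset and has |duration error| < dur_tol
recall_events <- function(truth, detected, onset_tol = 0.05, dur_tol = 0.02) {
  if (nrow(truth) == 0) return(numeric(0))
  vapply(seq_len(nrow(truth)), function(i) {
    d_on <- abs(detected$onset_s - truth$onset_s[i])
    ok <- d_on < onset_tol &
      abs(detected$duration_s - truth$duration_s[i]) < dur_tol
    any(ok)
  }, logical(1))
}
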