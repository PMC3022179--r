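#' Sampled single-channel current trace
#'
#' Container for a uniformly sampled current recording plus its metadata
#' (applied voltage with the trans-side sign convention, sampling rate, bath
#' composition, condition label, burst windows flagged by the simulator).
#'
#' @param time_s Sample times (s), uniform grid.
#' @param current_pA Current samples (pA); same length as `time_s`.
#' @param voltage_mV Applied voltage (mV); a minus sign means the negative
#'   potential was applied to the trans side.
#' @param sampling_rate_Hz Sampling rate (Hz).
#' @param condition Condition label.
#' @param cis_KCl_mM,trans_KCl_mM,temperature_C Bath metadata.
#' @param seed Generator seed, if simulated.
#' @param burst_windows Two-column matrix of burst window start/end times (s).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(time_s, current_pA, voltage_mV, sampling_rate_Hz,
                          condition = "", cis_KCl_mM = 50, trans_KCl_mM = 50,
                          temperature_C = 23, seed = NA_integer_,
                          burst_windows = NULL) {
  if (length(time_s) != length(current_pA))
    .chk_stop("`time_s` and `current_pA` must have equal length",
              "chankit_format_error")
  if (anyNA(time_s) || anyNA(current_pA) ||
      any(!is.finite(time_s)) || any(!is.finite(current_pA)))
    .chk_stop("trace contains non-finite values", "chankit_format_error")
  if (is.null(burst_windows)) burst_windows <- matrix(numeric(0), ncol = 2)
  structure(list(
    time_s = as.numeric(time_s),
    current_pA = as.numeric(current_pA),
    voltage_mV = voltage_mV,
    sampling_rate_Hz = sampling_rate_Hz,
    meta = list(condition = condition, cis_KCl_mM = cis_KCl_mM,
                trans_KCl_mM = trans_KCl_mM, temperature_C = temperature_C,
                seed = seed, burst_windows = burst_windows)
  ), class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples @ %g Hz (%.3g s), %+g mV",
              length(x$time_s), x$sampling_rate_Hz,
              length(x$time_s) / x$sampling_rate_Hz, x$voltage_mV))
  if (nzchar(x$meta$condition)) cat(sprintf(" [%s]", x$meta$condition))
  cat("\n")
  cat(sprintf("  KCl %g/%g mM cis/trans, %g degC; current range %.3g..%.3g pA\n",
              x$meta$cis_KCl_mM, x$meta$trans_KCl_mM, x$meta$temperature_C,
              min(x$current_pA), max(x$current_pA)))
  if (nrow(x$meta$burst_windows) > 0)
    cat(sprintf("  %d burst window(s) flagged\n", nrow(x$meta$burst_windows)))
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$current_pA, type = "l",
                 xlab = "time (s)", ylab = "current (pA)",
                 main = sprintf("%s %+g mV", x$meta$condition, x$voltage_mV),
                 ...)
  if (nrow(x$meta$burst_windows) > 0)
    graphics::rect(x$meta$burst_windows[, 1], min(x$current_pA),
                   x$meta$burst_windows[, 2], max(x$current_pA),
                   col = grDevices::adjustcolor("red", 0.1), border = NA)
  invisible(x)
}

#' Write / read a current trace as CSV plus JSON sidecar
#'
#' The trace itself is a two-column CSV (`time_s`, `current_pA`); voltage,
#' sampling rate, bath composition, condition, seed and burst windows go to a
#' JSON sidecar with the same basename and extension `.json`.
#'
#' @param trace A `current_trace`.
#' @param path CSV path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   `current_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s,
                              current_pA = trace$current_pA),
                   path, row.names = FALSE)
  side <- trace$meta
  side$voltage_mV <- trace$voltage_mV
  side$sampling_rate_Hz <- trace$sampling_rate_Hz
  side$burst_windows <- if (nrow(side$burst_windows) > 0)
    unname(apply(side$burst_windows, 1, as.numeric, simplify = FALSE))
  else list()
  jsonlite::write_json(side, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @param sidecar Optional sidecar path; default replaces the CSV extension
#'   with `.json`.
#' @export
read_trace <- function(path, sidecar = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(df)))
    .chk_stop("trace CSV must have columns time_s, current_pA",
              "chankit_format_error")
  if (is.null(sidecar)) sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- list(voltage_mV = NA_real_, sampling_rate_Hz = NA_real_,
               condition = "", cis_KCl_mM = NA_real_, trans_KCl_mM = NA_real_,
               temperature_C = NA_real_, seed = NA_integer_,
               burst_windows = list())
  if (file.exists(sidecar)) {
    got <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  if (is.na(meta$sampling_rate_Hz) && nrow(df) > 1)
    meta$sampling_rate_Hz <- 1 / stats::median(diff(df$time_s))
  bw <- meta$burst_windows
  bw <- if (length(bw) == 0) matrix(numeric(0), ncol = 2)
        else matrix(unlist(bw), ncol = 2, byrow = !is.matrix(bw))
  current_trace(df$time_s, df$current_pA, voltage_mV = meta$voltage_mV,
                sampling_rate_Hz = meta$sampling_rate_Hz,
                condition = meta$condition, cis_KCl_mM = meta$cis_KCl_mM,
                trans_KCl_mM = meta$trans_KCl_mM,
                temperature_C = meta$temperature_C, seed = meta$seed,
                burst_windows = bw)
}
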