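#' Idealized channel-event table
#'
#' A data frame of discrete channel openings — onset, duration, amplitude,
#' conductance level and burst flag — plus the recording duration and burst
#' windows as attributes. Produced by [idealize_trace()] and
#' [simulate_event_table()].
#'
#' @param events Data frame with columns `onset_s`, `duration_s`,
#'   `amplitude_pA` and optionally `level`, `in_burst`.
#' @param recording_s Total recording duration (s).
#' @param burst_windows Two-column matrix of burst window start/end times (s).
#' @param voltage_mV,condition Recording metadata.
#' @return An object of classes `event_table` and `data.frame`.
#' @export
event_table <- function(events, recording_s, burst_windows = NULL,
                        voltage_mV = NA_real_, condition = "") {
  need <- c("onset_s", "duration_s", "amplitude_pA")
  if (!all(need %in% names(events)))
    .chk_stop("event table needs columns onset_s, duration_s, amplitude_pA",
              "chankit_format_error")
  if (is.null(events$level)) events$level <- rep(1L, nrow(events))
  if (is.null(events$in_burst)) events$in_burst <- rep(FALSE, nrow(events))
  events <- events[, c(need, "level", "in_burst")]
  if (is.null(burst_windows)) burst_windows <- matrix(numeric(0), ncol = 2)
  structure(events,
            recording_s = recording_s,
            burst_windows = burst_windows,
            voltage_mV = voltage_mV,
            condition = condition,
            class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d events in %.4g s", nrow(x),
              attr(x, "recording_s")))
  if (!is.na(attr(x, "voltage_mV")))
    cat(sprintf(" at %+g mV", attr(x, "voltage_mV")))
  cond <- attr(x, "condition")
  if (!is.null(cond) && nzchar(cond)) cat(sprintf(" [%s]", cond))
  cat("\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.event_table <- function(object, ...) {
  cat(sprintf("%d events, %.4g s recording, %.3g events/min\n", nrow(object),
              attr(object, "recording_s"), event_frequency(object)))
  if (nrow(object) > 0)
    cat(sprintf("  duration: median %.3g s (range %.3g..%.3g)\n  |amplitude|: mean %.3g pA\n",
                stats::median(object$duration_s), min(object$duration_s),
                max(object$duration_s), mean(abs(object$amplitude_pA))))
  invisible(object)
}

#' Channel opening frequency in events per minute
#'
#' Event count divided by recording duration in minutes. With
#' `exclude_bursts = TRUE`, burst-flagged events are dropped from the count
#' and the total burst-window time from the denominator, since individual
#' openings cannot be counted reliably during paroxystic episodes.
#'
#' @param events An [event_table()].
#' @param exclude_bursts Drop burst-flagged events and burst time.
#' @return Events per minute.
#' @examples
#' ev <- event_table(data.frame(onset_s = c(1, 30), duration_s = c(1, 2),
#'                              amplitude_pA = c(10, 9)), recording_s = 120)
#' event_frequency(ev)  # 1.0/min
#' @export
event_frequency <- function(events, exclude_bursts = FALSE) {
  stopifnot(inherits(events, "event_table"))
  .chk_flag(exclude_bursts, "exclude_bursts")
  dur_s <- attr(events, "recording_s")
  if (is.null(dur_s) || is.na(dur_s) || dur_s <= 0)
    .chk_stop("recording duration must be positive", "chankit_invalid_parameter")
  n <- nrow(events)
  if (exclude_bursts) {
    n <- sum(!events$in_burst)
    bw <- attr(events, "burst_windows")
    if (!is.null(bw) && nrow(bw) > 0)
      dur_s <- dur_s - sum(pmin(bw[, 2], dur_s) - pmax(bw[, 1], 0))
    if (dur_s <= 0)
      .chk_stop("burst windows cover the whole recording",
                "chankit_invalid_parameter")
  }
  n / (dur_s / 60)
}

#' Write / read an event table as TSV
#'
#' Columns `onset_s`, `duration_s`, `amplitude_pA`, `level`, `in_burst`;
#' recording duration, voltage and burst windows are kept in `#`-prefixed
#' header lines so a table survives a round trip through disk.
#'
#' @param events An [event_table()].
#' @param path TSV path.
#' @return `write_events()` returns `path` invisibly; `read_events()` an
#'   [event_table()].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# recording_s=%.10g", attr(events, "recording_s")), con)
  if (!is.na(attr(events, "voltage_mV")))
    writeLines(sprintf("# voltage_mV=%.10g", attr(events, "voltage_mV")), con)
  cond <- attr(events, "condition")
  if (!is.null(cond) && nzchar(cond))
    writeLines(sprintf("# condition=%s", cond), con)
  bw <- attr(events, "burst_windows")
  if (!is.null(bw) && nrow(bw) > 0)
    writeLines(sprintf("# burst_windows=%s",
                       paste(sprintf("%.10g:%.10g", bw[, 1], bw[, 2]),
                             collapse = ",")), con)
  utils::write.table(as.data.frame(events), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(sprintf("^# %s=", key), "", hit[1])
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE)
  bw <- get("burst_windows")
  windows <- matrix(numeric(0), ncol = 2)
  if (!is.null(bw)) {
    parts <- strsplit(strsplit(bw, ",")[[1]], ":")
    windows <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  }
  rec <- get("recording_s")
  if (is.null(rec))
    .chk_stop("event TSV lacks the '# recording_s=' header line",
              "chankit_format_error")
  v <- get("voltage_mV")
  event_table(df, recording_s = as.numeric(rec), burst_windows = windows,
              voltage_mV = if (is.null(v)) NA_real_ else as.numeric(v),
              condition = if (is.null(get("condition"))) "" else get("condition"))
}
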