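#' Configuration of a multi-condition single-channel study
#'
#' Describes a full study grid — conditions (each a [gating_model()]) crossed
#' with applied voltages — together with the analysis settings used for every
#' cell: recording length, idealization parameters, histogram binning and the
#' model-selection threshold.
#'
#' @param conditions Named list of [gating_model()] objects; names are the
#'   condition labels and must be unique.
#' @param voltages Applied voltages (mV), all non-zero.
#' @param duration_s Recording length per cell (s).
#' @param sampling_rate Sampling rate (Hz).
#' @param idealize An [idealize_params()].
#' @param binning Histogram binning rule or edges (see
#'   [fit_conductance_histogram()]).
#' @param min_fit_events Histogram-fit floor; cells with fewer events report
#'   the raw mean +/- SD instead.
#' @param alpha F-test threshold for lifetime model selection.
#' @param seed Master seed; every cell derives its own sub-seed from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(conditions, voltages = 60, duration_s = 600,
                         sampling_rate = 1000,
                         idealize = idealize_params(),
                         binning = "fd", min_fit_events = 30,
                         alpha = 0.05, seed = 1) {
  if (!is.list(conditions) || length(conditions) == 0)
    .chk_stop("`conditions` must be a non-empty named list of gating models",
              "chankit_invalid_parameter")
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)) ||
      any(!nzchar(names(conditions))))
    .chk_stop("condition labels must be unique and non-empty",
              "chankit_invalid_parameter")
  for (m in conditions)
    if (!inherits(m, "gating_model"))
      .chk_stop("every condition must be a gating_model",
                "chankit_invalid_parameter")
  if (length(voltages) == 0 || any(voltages == 0))
    .chk_stop("`voltages` must be non-zero", "chankit_invalid_parameter")
  .chk_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  structure(list(conditions = conditions, voltages = voltages,
                 duration_s = duration_s, sampling_rate = sampling_rate,
                 idealize = idealize, binning = binning,
                 min_fit_events = min_fit_events, alpha = alpha,
                 seed = seed),
            class = "study_config")
}

#' Run a full simulated single-channel study
#'
#' For every condition x voltage cell: simulate a recording, idealize it,
#' fit the conductance histogram, compute the opening frequency (bursts
#' excluded), fit one- and two-exponential open-lifetime models and select
#' between them by F-test. Aggregates per-cell results into conductance,
#' frequency and lifetime tables, compares each condition's central
#' conductance against the first (reference) condition, and keeps a
#' structured per-stage log. Deterministic given the config seed; any stage
#' error is recorded for its cell and the study continues.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, tables are written as TSV,
#'   the comparisons and log as JSON.
#' @return An object of class `study_report` with elements `conductance`,
#'   `frequency`, `lifetime`, `comparisons` (data frames), `cells` (per-cell
#'   objects) and `log`.
#' @examples
#' \donttest{
#' cfg <- study_config(
#'   conditions = list(
#'     control = gating_model(opening_rate = 7.73, unit_conductance_mean = 0.161),
#'     choline = gating_model(opening_rate = 15.97, unit_conductance_mean = 0.215)),
#'   voltages = 60, duration_s = 600, seed = 1)
#' rep <- run_study(cfg)
#' rep
#' }
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  labels <- names(config$conditions)
  grid <- expand.grid(condition = labels, voltage = config$voltages,
                      stringsAsFactors = FALSE)
  cells <- vector("list", nrow(grid))
  log <- list()
  note <- function(cond, v, stage, status, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(
      condition = cond, voltage = v, stage = stage, status = status,
      detail = detail)
  }

  cond_rows <- list(); freq_rows <- list(); life_rows <- list()
  for (i in seq_len(nrow(grid))) {
    lab <- grid$condition[i]; v <- grid$voltage[i]
    model <- config$conditions[[lab]]
    cell_seed <- .derive_seed(config$seed, i)
    cell <- list(condition = lab, voltage = v, seed = cell_seed)

    events <- tryCatch({
      tr <- simulate_trace(model, voltage = v, duration = config$duration_s,
                           sampling_rate = config$sampling_rate,
                           seed = cell_seed)
      note(lab, v, "simulate", "ok", sprintf("seed=%d", cell_seed))
      ev <- idealize_trace(tr, config$idealize)
      note(lab, v, "idealize", "ok", sprintf("%d events", nrow(ev)))
      ev
    }, chankit_error = function(e) {
      note(lab, v, "idealize", "error", conditionMessage(e)); NULL
    })
    cell$events <- events

    if (!is.null(events)) {
      freq <- tryCatch(event_frequency(events, exclude_bursts = TRUE),
                       chankit_error = function(e) {
                         note(lab, v, "frequency", "error",
                              conditionMessage(e)); NA_real_
                       })
      freq_rows[[length(freq_rows) + 1L]] <- data.frame(
        condition = lab, voltage_mV = v, n_events = nrow(events),
        frequency_per_min = freq)

      lam <- conductances_from_events(events, voltage = v)
      fit <- tryCatch(
        fit_conductance_histogram(lam, binning = config$binning,
                                  min_events = config$min_fit_events,
                                  voltage = v, condition = lab),
        chankit_error = function(e) {
          note(lab, v, "conductance", "fallback", conditionMessage(e))
          if (length(lam) > 0)
            conductance_fit(mean(lam), stats::sd(lam) / sqrt(length(lam)),
                            length(lam), sigma = stats::sd(lam),
                            voltage = v, condition = lab)
          else NULL
        })
      cell$conductance <- fit
      if (!is.null(fit))
        cond_rows[[length(cond_rows) + 1L]] <- data.frame(
          condition = lab, voltage_mV = v, lambda_c_nS = fit$lambda_c,
          lambda_c_se_nS = fit$lambda_c_se, sigma_nS = fit$sigma,
          n_events = fit$n_events, method = fit$method)

      life <- tryCatch({
        dur <- events$duration_s[!events$in_burst]
        curve <- survival_curve(dur)
        f1 <- fit_lifetime(curve, order = 1)
        f2 <- fit_lifetime(curve, order = 2)
        sel <- select_lifetime_model(f1, f2, alpha = config$alpha)
        note(lab, v, "lifetime", "ok",
             sprintf("order %d, P=%.3g", sel$selected_order, sel$p_value))
        list(f1 = f1, f2 = f2, sel = sel)
      }, chankit_error = function(e) {
        note(lab, v, "lifetime", "error", conditionMessage(e)); NULL
      })
      cell$lifetime <- life
      if (!is.null(life)) {
        chosen <- if (life$sel$selected_order == 2L) life$f2 else life$f1
        life_rows[[length(life_rows) + 1L]] <- data.frame(
          condition = lab, voltage_mV = v,
          tau1_s = chosen$tau1,
          tau2_s = if (life$sel$selected_order == 2L) chosen$tau2 else NA_real_,
          selected_order = life$sel$selected_order,
          F = life$sel$F, P = life$sel$p_value,
          label = if (life$sel$indeterminate) "indeterminate"
                  else if (life$sel$selected_order == 2L) "two-component"
                  else "one-component")
      }
    }
    cells[[i]] <- cell
  }

  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else
    data.frame()
  conductance <- bind(cond_rows)
  frequency <- bind(freq_rows)
  lifetime <- bind(life_rows)

  comparisons <- data.frame()
  if (length(labels) > 1 && nrow(conductance) > 0) {
    ref <- labels[1]
    comp_rows <- list()
    for (v in config$voltages) {
      ref_cell <- Filter(function(c) c$condition == ref && c$voltage == v &&
                           !is.null(c$conductance), cells)
      for (lab in labels[-1]) {
        other <- Filter(function(c) c$condition == lab && c$voltage == v &&
                          !is.null(c$conductance), cells)
        if (length(ref_cell) == 1 && length(other) == 1) {
          ht <- tryCatch(
            compare_central_conductance(ref_cell[[1]]$conductance,
                                        other[[1]]$conductance),
            chankit_error = function(e) {
              note(lab, v, "compare", "error", conditionMessage(e)); NULL
            })
          if (!is.null(ht))
            comp_rows[[length(comp_rows) + 1L]] <- data.frame(
              reference = ref, condition = lab, voltage_mV = v,
              t = unname(ht$statistic), p_value = ht$p.value)
        }
      }
    }
    comparisons <- bind(comp_rows)
  }

  report <- structure(list(config = config, cells = cells,
                           conductance = conductance, frequency = frequency,
                           lifetime = lifetime, comparisons = comparisons,
                           log = bind(log)),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("conductance", "frequency", "lifetime", "comparisons"))
      utils::write.table(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report$log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d condition(s) x %d voltage(s), %.4g s per cell\n",
              length(x$config$conditions), length(x$config$voltages),
              x$config$duration_s))
  cat("\nFrequency (events/min):\n"); print(x$frequency, row.names = FALSE)
  cat("\nCentral conductance (nS):\n"); print(x$conductance, row.names = FALSE)
  cat("\nOpen lifetime:\n"); print(x$lifetime, row.names = FALSE)
  if (nrow(x$comparisons) > 0) {
    cat("\nCentral-conductance comparisons vs reference:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Generate a small set of synthetic fixtures
#'
#' Writes example inputs for the documented workflows: a simulated control
#' trace with its JSON sidecar, the matching ground-truth event table, a
#' noisy I-V point set consistent with a GHK permeability ratio of 0.46
#' under 100/50 mM KCl, and a manifest recording every generator parameter.
#' All files are synthetic and regenerated from the seed.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
make_fixtures <- function(seed = 1, out_dir) {
  if (missing(out_dir)) .chk_stop("`out_dir` is required",
                                  "chankit_invalid_parameter")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    .chk_stop(sprintf("cannot create '%s'", out_dir), "chankit_io_error")

  model <- gating_model(label = "control")
  trace_seed <- .derive_seed(seed, 1)
  tr <- simulate_trace(model, voltage = 60, duration = 30,
                       sampling_rate = 500, seed = trace_seed)
  write_trace(tr, file.path(out_dir, "trace_control.csv"))
  ev <- simulate_event_table(model, voltage = 60, duration = 30,
                             seed = trace_seed)
  write_events(ev, file.path(out_dir, "events_control.tsv"))

  cond <- kcl_conditions(100, 50)
  v_rev <- ghk_reversal(0.46, cond)
  set.seed(.derive_seed(seed, 2))
  v <- seq(-30, 40, by = 5)
  iv <- data.frame(voltage_mV = v,
                   current_pA = 0.2 * (v - v_rev) + stats::rnorm(length(v), 0, 0.15))
  utils::write.csv(iv, file.path(out_dir, "iv_choline_cis.csv"),
                   row.names = FALSE)

  manifest <- list(
    seed = seed,
    files = list(
      trace_control.csv = list(generator = "simulate_trace",
                               opening_rate_per_min = model$opening_rate,
                               dwell_tau1_s = model$dwell_tau1,
                               unit_conductance_nS = model$unit_conductance_mean,
                               unit_conductance_sd_nS = model$unit_conductance_sd,
                               noise_sd_pA = model$noise_sd,
                               voltage_mV = 60, duration_s = 30,
                               sampling_rate_Hz = 500, seed = trace_seed),
      events_control.tsv = list(generator = "simulate_event_table",
                                note = "ground truth for trace_control.csv",
                                seed = trace_seed),
      iv_choline_cis.csv = list(generator = "ghk_reversal + linear I-V",
                                ratio = 0.46, v_rev_mV = v_rev,
                                slope_nS = 0.2, noise_sd_pA = 0.15,
                                cis_KCl_mM = 100, trans_KCl_mM = 50,
                                temperature_C = 23)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
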