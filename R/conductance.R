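#' Event conductances in nS
#'
#' Converts event amplitudes to single-channel conductances
#' `|amplitude (pA) / voltage (mV)|` in nS. Burst-flagged events are excluded
#' by default because their amplitudes are unreliable.
#'
#' @param events An [event_table()].
#' @param voltage Applied voltage (mV); taken from the table's metadata when
#'   omitted. Must be non-zero.
#' @param exclude_bursts Drop burst-flagged events.
#' @return Numeric vector of conductances (nS).
#' @examples
#' ev <- event_table(data.frame(onset_s = 0, duration_s = 1,
#'                              amplitude_pA = 9.66), recording_s = 60)
#' conductances_from_events(ev, voltage = 60)  # 0.161 nS
#' @export
conductances_from_events <- function(events, voltage = attr(events, "voltage_mV"),
                                     exclude_bursts = TRUE) {
  stopifnot(inherits(events, "event_table"))
  if (is.null(voltage) || is.na(voltage) || voltage == 0)
    .chk_stop("`voltage` must be non-zero", "chankit_invalid_parameter")
  ev <- if (exclude_bursts) events[!events$in_burst, , drop = FALSE] else events
  abs(ev$amplitude_pA / voltage)
}

# Minimal constructor, exported so published centres (lambda_c, SE, n) can be
# compared with compare_central_conductance() without raw data.
#' Construct a conductance fit from summary values
#'
#' @param lambda_c Central conductance (nS).
#' @param lambda_c_se Standard error of the fitted centre (nS).
#' @param n_events Number of events behind the fit.
#' @param sigma Gaussian width (nS).
#' @param voltage,condition Metadata.
#' @return A `conductance_fit` object (without histogram data).
#' @export
conductance_fit <- function(lambda_c, lambda_c_se, n_events, sigma = NA_real_,
                            voltage = NA_real_, condition = "") {
  structure(list(lambda_c = lambda_c, lambda_c_se = lambda_c_se,
                 sigma = sigma, amplitude = NA_real_, r2 = NA_real_,
                 n_events = n_events, bin_edges = NULL, p_lambda = NULL,
                 mids = NULL, voltage = voltage, condition = condition,
                 method = "summary"),
            class = "conductance_fit")
}

#' Fit a Gaussian to the conductance probability histogram
#'
#' Builds the normalized conductance histogram (probability per bin, summing
#' to 1) and fits `a * exp(-(L - lambda_c)^2 / (2 sigma^2))` to the bin
#' probabilities by nonlinear least squares, the workflow used for
#' single-peaked single-channel conductance distributions. The centre
#' `lambda_c` and its standard error come from the fit covariance. A direct
#' maximum-likelihood alternative on the raw values (`method = "mle"`:
#' sample mean, SD, SEM) is available as a cross-check.
#'
#' @param conductances Numeric vector of event conductances (nS).
#' @param binning `"fd"` for Freedman-Diaconis binning, or a numeric vector
#'   of explicit bin edges.
#' @param min_events Minimum number of events required to fit (default 30).
#' @param method `"ls"` (histogram least squares) or `"mle"`.
#' @param voltage,condition Metadata carried into the result.
#' @return A `conductance_fit` with elements `lambda_c`, `lambda_c_se`,
#'   `sigma`, `r2`, `n_events`, `bin_edges`, `p_lambda`.
#' @examples
#' set.seed(1)
#' fit <- fit_conductance_histogram(rnorm(505, 0.161, 0.05))
#' fit
#' @export
fit_conductance_histogram <- function(conductances, binning = "fd",
                                      min_events = 30,
                                      method = c("ls", "mle"),
                                      voltage = NA_real_, condition = "") {
  method <- match.arg(method)
  x <- conductances[!is.na(conductances)]
  n <- length(x)
  if (n < min_events)
    .chk_stop(sprintf("need at least %d events to fit a histogram (got %d)",
                      min_events, n), "chankit_insufficient_data")

  degenerate <- diff(range(x)) < 1e-12
  if (degenerate) {
    w <- max(abs(x[1]) * 1e-3, 1e-6)
    edges <- c(x[1] - w, x[1] + w)
    return(structure(list(lambda_c = x[1], lambda_c_se = 0, sigma = w / 2,
                          amplitude = 1, r2 = 1, n_events = n,
                          bin_edges = edges, p_lambda = 1,
                          mids = x[1], voltage = voltage,
                          condition = condition, method = method),
                     class = "conductance_fit"))
  }

  h <- if (is.numeric(binning))
    graphics::hist(x, breaks = binning, plot = FALSE)
  else graphics::hist(x, breaks = "FD", plot = FALSE)
  p <- h$counts / n
  mids <- h$mids

  if (method == "mle") {
    lambda_c <- mean(x); sigma <- stats::sd(x)
    return(structure(list(lambda_c = lambda_c,
                          lambda_c_se = sigma / sqrt(n), sigma = sigma,
                          amplitude = NA_real_, r2 = NA_real_, n_events = n,
                          bin_edges = h$breaks, p_lambda = p, mids = mids,
                          voltage = voltage, condition = condition,
                          method = "mle"),
                     class = "conductance_fit"))
  }

  fn <- function(par) p - par[1] * exp(-(mids - par[2])^2 / (2 * par[3]^2))
  p0 <- c(max(p), sum(mids * p), max(stats::sd(x), 1e-9))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = fn,
                       lower = c(0, min(x), 1e-12),
                       upper = c(Inf, max(x), Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5, 9))
    .chk_stop("Gaussian histogram fit did not converge",
              "chankit_fit_failure")
  par <- fit$par
  ss <- sum(fit$fvec^2)
  dfree <- length(p) - 3L
  se <- rep(NA_real_, 3)
  if (dfree > 0) {
    cv <- tryCatch({
      ih <- chol2inv(chol(fit$hessian))
      diag(ih) * ss / dfree
    }, error = function(e) rep(NA_real_, 3))
    se <- sqrt(pmax(cv, 0))
  }
  r2 <- 1 - ss / sum((p - mean(p))^2)

  structure(list(lambda_c = par[2], lambda_c_se = se[2], sigma = abs(par[3]),
                 amplitude = par[1], r2 = r2, n_events = n,
                 bin_edges = h$breaks, p_lambda = p, mids = mids,
                 voltage = voltage, condition = condition, method = "ls"),
            class = "conductance_fit")
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat("Central conductance fit")
  if (nzchar(x$condition)) cat(sprintf(" [%s]", x$condition))
  if (!is.na(x$voltage)) cat(sprintf(" at %+g mV", x$voltage))
  cat("\n")
  cat(sprintf("  lambda_c = %.4g +/- %.2g nS (sigma %.3g nS, n = %d, %s",
              x$lambda_c, x$lambda_c_se, x$sigma, x$n_events, x$method))
  if (!is.na(x$r2)) cat(sprintf(", R2 = %.3f", x$r2))
  cat(")\n")
  invisible(x)
}

#' @export
coef.conductance_fit <- function(object, ...) {
  c(lambda_c = object$lambda_c, sigma = object$sigma,
    amplitude = object$amplitude)
}

#' @export
predict.conductance_fit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$mids
         else if (is.data.frame(newdata)) newdata[[1]] else newdata
  object$amplitude * exp(-(lam - object$lambda_c)^2 / (2 * object$sigma^2))
}

#' @export
plot.conductance_fit <- function(x, ...) {
  if (is.null(x$bin_edges)) .chk_stop("fit carries no histogram data",
                                      "chankit_invalid_parameter")
  graphics::plot(x$mids, x$p_lambda, type = "h", lwd = 6, col = "grey70",
                 xlab = expression(Lambda ~ "(nS)"),
                 ylab = expression(P[Lambda]), ...)
  if (!is.na(x$amplitude)) {
    grid <- seq(min(x$bin_edges), max(x$bin_edges), length.out = 200)
    graphics::lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  }
  graphics::abline(v = x$lambda_c, lty = 2)
  invisible(x)
}

#' Compare two fitted central conductances
#'
#' Welch-style t-test on the fitted Gaussian centres using their standard
#' errors, with Welch-Satterthwaite degrees of freedom based on each fit's
#' event count. Used to ask whether the central conductance differs between
#' conditions.
#'
#' @param fit_a,fit_b `conductance_fit` objects (or any list carrying
#'   `lambda_c`, `lambda_c_se`, `n_events`).
#' @return An object of class `htest` with the t statistic and two-sided P.
#' @examples
#' a <- conductance_fit(0.161, 0.008, 505)
#' b <- conductance_fit(0.215, 0.007, 898)
#' compare_central_conductance(a, b)
#' @export
compare_central_conductance <- function(fit_a, fit_b) {
  for (f in list(fit_a, fit_b))
    if (is.null(f$lambda_c) || is.null(f$lambda_c_se) || is.na(f$lambda_c_se))
      .chk_stop("both fits must carry lambda_c and its SE",
                "chankit_invalid_parameter")
  d <- fit_b$lambda_c - fit_a$lambda_c
  v <- fit_a$lambda_c_se^2 + fit_b$lambda_c_se^2
  if (v == 0) {
    t <- if (d == 0) 0 else Inf * sign(d)
    p <- if (d == 0) 1 else 0
    dfree <- Inf
  } else {
    t <- d / sqrt(v)
    dfree <- v^2 / (fit_a$lambda_c_se^4 / max(fit_a$n_events - 1, 1) +
                    fit_b$lambda_c_se^4 / max(fit_b$n_events - 1, 1))
    p <- 2 * stats::pt(abs(t), dfree, lower.tail = FALSE)
  }
  structure(list(
    statistic = c(t = t), parameter = c(df = dfree), p.value = p,
    estimate = c("centre a (nS)" = fit_a$lambda_c,
                 "centre b (nS)" = fit_b$lambda_c),
    method = "Welch two-sample t-test on fitted central conductances",
    data.name = sprintf("%s vs %s",
                        if (nzchar(fit_a$condition %||% "")) fit_a$condition else "fit_a",
                        if (nzchar(fit_b$condition %||% "")) fit_b$condition else "fit_b")
  ), class = "htest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
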