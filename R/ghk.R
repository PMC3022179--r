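# Physical constants (CODATA): molar gas constant (J/mol/K) and Faraday
# constant (C/mol).
.GAS_R <- 8.314462618
.FARADAY <- 96485.33212

# RT/F in mV at a bath temperature in degrees C (23 degC -> 25.52 mV)
.rtf_mV <- function(temperature_C)
  1000 * .GAS_R * (temperature_C + 273.15) / .FARADAY

#' Ionic conditions of a bilayer experiment
#'
#' Per-side K+ and Cl- concentrations (mM) and bath temperature, for the
#' Goldman-Hodgkin-Katz relations. For a single-salt KCl system use
#' [kcl_conditions()], which sets `[K] = [Cl]` on each side (full
#' dissociation, concentrations rather than activities).
#'
#' @param K_cis,K_trans,Cl_cis,Cl_trans Concentrations (mM), all > 0.
#' @param temperature Bath temperature (degrees C).
#' @return An object of class `ion_conditions`.
#' @export
ion_conditions <- function(K_cis, K_trans, Cl_cis, Cl_trans,
                           temperature = 23) {
  for (v in c("K_cis", "K_trans", "Cl_cis", "Cl_trans"))
    .chk_number(get(v), v, 0, strict_lower = TRUE)
  .chk_number(temperature, "temperature", -273.15, strict_lower = TRUE)
  structure(list(K_cis = K_cis, K_trans = K_trans, Cl_cis = Cl_cis,
                 Cl_trans = Cl_trans, temperature = temperature),
            class = "ion_conditions")
}

#' @rdname ion_conditions
#' @param cis,trans KCl concentration (mM) on each side.
#' @examples
#' kcl_conditions(100, 50)  # the asymmetric condition used for selectivity
#' @export
kcl_conditions <- function(cis, trans, temperature = 23)
  ion_conditions(cis, trans, cis, trans, temperature)

#' @export
print.ion_conditions <- function(x, ...) {
  cat(sprintf("Ionic conditions: K+ %g/%g mM, Cl- %g/%g mM (cis/trans), %g degC\n",
              x$K_cis, x$K_trans, x$Cl_cis, x$Cl_trans, x$temperature))
  invisible(x)
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' Forward GHK voltage relation for a K+/Cl- system:
#' `V = (RT/F) ln[(r [K]_trans + [Cl]_cis) / (r [K]_cis + [Cl]_trans)]`
#' with `r = P_K / P_Cl` the permeability ratio. `r = 0` gives the Cl-
#' Nernst potential, `r = Inf` the K+ Nernst potential.
#'
#' @param ratio Permeability ratio `P_K+/P_Cl-` (>= 0; `Inf` allowed).
#' @param cond An [ion_conditions()].
#' @return Reversal potential (mV).
#' @examples
#' ghk_reversal(0.28, kcl_conditions(100, 50))  # about 9.7 mV
#' @export
ghk_reversal <- function(ratio, cond) {
  stopifnot(inherits(cond, "ion_conditions"))
  if (length(ratio) != 1L || is.na(ratio) || ratio < 0)
    .chk_stop("`ratio` must be a single non-negative number",
              "chankit_invalid_parameter")
  rtf <- .rtf_mV(cond$temperature)
  if (is.infinite(ratio))
    return(rtf * log(cond$K_trans / cond$K_cis))
  rtf * log((ratio * cond$K_trans + cond$Cl_cis) /
            (ratio * cond$K_cis + cond$Cl_trans))
}

#' Invert the GHK relation for the permeability ratio
#'
#' Closed-form inversion of [ghk_reversal()]:
#' `r = ([Cl]_cis - x [Cl]_trans) / (x [K]_cis - [K]_trans)` with
#' `x = exp(V F / RT)`. Valid only for reversal potentials strictly between
#' the Cl- and K+ Nernst limits implied by the conditions; outside that range
#' the ratio would be negative or infinite and a domain error is raised.
#'
#' @param v_rev Measured reversal potential (mV).
#' @param cond An [ion_conditions()].
#' @return Permeability ratio `P_K+/P_Cl-`.
#' @examples
#' ghk_permeability_ratio(6.87, kcl_conditions(100, 50))  # about 0.43
#' @export
ghk_permeability_ratio <- function(v_rev, cond) {
  stopifnot(inherits(cond, "ion_conditions"))
  .chk_number(v_rev, "v_rev")
  x <- exp(v_rev / .rtf_mV(cond$temperature))
  num <- cond$Cl_cis - x * cond$Cl_trans
  den <- x * cond$K_cis - cond$K_trans
  if (num < 0 || den <= 0 || (num == 0 && den == 0))
    .chk_stop(sprintf(
      "v_rev = %g mV lies at or beyond a Nernst limit for these conditions",
      v_rev), "chankit_domain_error")
  num / den
}

#' Reversal potential and slope conductance from an I-V relation
#'
#' Ordinary least-squares fit of `I = g (V - V_rev)` to current-voltage
#' points; the reversal potential is the voltage-axis intercept
#' `-intercept/slope` and the slope conductance is in nS (pA/mV).
#'
#' @param iv A data frame (or two-column matrix) with voltage (mV) in the
#'   first column and current (pA) in the second, at least 3 points spanning
#'   the zero-current crossing.
#' @return An object of class `reversal_fit`: `v_rev_mV`, `slope_nS`, the
#'   underlying `lm` fit and residuals.
#' @examples
#' iv <- data.frame(v = c(-20, 0, 40), i = 0.2 * (c(-20, 0, 40) - 6.42))
#' fit_reversal_potential(iv)
#' @export
fit_reversal_potential <- function(iv) {
  iv <- as.data.frame(iv)
  if (ncol(iv) < 2 || nrow(iv) < 3)
    .chk_stop("need at least 3 (voltage, current) points",
              "chankit_insufficient_data")
  v <- iv[[1]]; i <- iv[[2]]
  fit <- stats::lm(i ~ v)
  b <- unname(stats::coef(fit))
  if (abs(b[2]) < .Machine$double.eps)
    .chk_stop("zero slope: reversal potential undefined",
              "chankit_fit_failure")
  structure(list(v_rev_mV = -b[1] / b[2], slope_nS = b[2], lm = fit,
                 residuals = stats::residuals(fit)),
            class = "reversal_fit")
}

#' @export
print.reversal_fit <- function(x, ...) {
  cat(sprintf("I-V regression: V_rev = %.4g mV, slope conductance %.4g nS (n = %d)\n",
              x$v_rev_mV, x$slope_nS, length(x$residuals)))
  invisible(x)
}

#' @export
coef.reversal_fit <- function(object, ...)
  c(v_rev_mV = object$v_rev_mV, slope_nS = object$slope_nS)

#' Reversal potential from a voltage step protocol
#'
#' For holding potentials stepped in small increments, returns the potential
#' at which the current is zero: the exact step if a zero was sampled,
#' otherwise linear interpolation between the bracketing pair where the
#' current changes sign.
#'
#' @param holding_potentials Holding potentials (mV), >= 2 steps.
#' @param currents Currents (pA), one per step; must change sign across the
#'   sweep.
#' @return Reversal potential (mV).
#' @examples
#' reversal_from_step_protocol(c(4, 8), c(-2, 2))  # 6 mV
#' @export
reversal_from_step_protocol <- function(holding_potentials, currents) {
  if (length(holding_potentials) != length(currents) ||
      length(currents) < 2)
    .chk_stop("need >= 2 matched (potential, current) steps",
              "chankit_invalid_parameter")
  o <- order(holding_potentials)
  v <- holding_potentials[o]; i <- currents[o]
  zero <- which(i == 0)
  if (length(zero) > 0) return(v[zero[1]])
  s <- sign(i)
  flip <- which(s[-1] != s[-length(s)])
  if (length(flip) == 0)
    .chk_stop("current does not change sign across the sweep",
              "chankit_domain_error")
  k <- flip[1]
  v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Ionic selectivity result
#'
#' Bundles a measured reversal potential with its GHK permeability ratio
#' under stated conditions. The stored ratio always satisfies the round-trip
#' identity `ghk_reversal(ratio, cond) == v_rev`.
#'
#' @param v_rev Reversal potential (mV).
#' @param cond An [ion_conditions()].
#' @param method How `v_rev` was obtained: `"step-protocol"` or
#'   `"iv-regression"`.
#' @return An object of class `selectivity_result`: `v_rev_mV`, `ratio`,
#'   `conditions`, `method`.
#' @examples
#' selectivity_result(6.42, kcl_conditions(100, 50), "iv-regression")
#' @export
selectivity_result <- function(v_rev, cond,
                               method = c("step-protocol", "iv-regression")) {
  method <- match.arg(method)
  structure(list(v_rev_mV = v_rev,
                 ratio = ghk_permeability_ratio(v_rev, cond),
                 conditions = cond, method = method),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("Selectivity (%s): V_rev = %.4g mV -> P_K+/P_Cl- = %.3g\n",
              x$method, x$v_rev_mV, x$ratio))
  print(x$conditions)
  invisible(x)
}
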