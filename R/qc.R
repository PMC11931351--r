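#' Adenylate-convention energy charge
#'
#' Atkinson's energy charge `(NTP + 0.5 NDP) / (NTP + NDP + NMP)`,
#' applied per nucleotide base. A proxy for degradation during sample
#' processing: dephosphorylation drives it from near 1 toward 0.
#'
#' @param ntp,ndp,nmp Amounts (any consistent unit), all >= 0; or give a
#'   panel data frame with these columns as the single first argument.
#' @return Energy charge(s) in `[0, 1]`.
#' @examples
#' energy_charge(1, 0, 0)   # 1
#' energy_charge(1, 1, 1)   # 0.5
#' @export
energy_charge <- function(ntp, ndp = NULL, nmp = NULL) {
  if (is.data.frame(ntp)) {
    panel <- ntp
    return(energy_charge(panel$ntp, panel$ndp, panel$nmp))
  }
  total <- ntp + ndp + nmp
  if (any(ntp < 0 | ndp < 0 | nmp < 0))
    stop("amounts must be >= 0", call. = FALSE)
  if (any(total <= 0))
    stop("all-zero panel: energy charge undefined", call. = FALSE)
  (ntp + 0.5 * ndp) / total
}

#' Triphosphate fraction of a nucleotide panel
#'
#' `NTP / (NTP + NDP + NMP)` per base; the conserved-triphosphate share
#' used to qualify a concentration method (lyophilization should keep it
#' above 0.54).
#'
#' @inheritParams energy_charge
#' @return Fraction(s) in `[0, 1]`.
#' @export
triphosphate_fraction <- function(ntp, ndp = NULL, nmp = NULL) {
  if (is.data.frame(ntp)) {
    panel <- ntp
    return(triphosphate_fraction(panel$ntp, panel$ndp, panel$nmp))
  }
  total <- ntp + ndp + nmp
  if (any(ntp < 0 | ndp < 0 | nmp < 0))
    stop("amounts must be >= 0", call. = FALSE)
  if (any(total <= 0))
    stop("all-zero panel: fraction undefined", call. = FALSE)
  ntp / total
}

#' Energy-charge preservation of one method relative to a reference
#'
#' @param ec_test Energy charge under the method being assessed.
#' @param ec_reference Reference energy charge (> 0), e.g. from the
#'   milder concentration method.
#' @return `100 * ec_test / ec_reference` (percent).
#' @export
method_preservation_ratio <- function(ec_test, ec_reference) {
  if (any(ec_reference <= 0))
    stop("reference energy charge must be > 0", call. = FALSE)
  100 * ec_test / ec_reference
}

#' Q10 cold-processing time budget
#'
#' Lumping all glycosylation reactions into one first-order step, the Q10
#' rule (rates halve per 10 K of cooling) scales the warm processing time
#' to the cold one: `t_cold = t_warm * q10^(delta_T / 10)` with
#' `delta_T = T_warm - T_cold`. Dividing by the number of catalytic steps
#' gives the time budget per step -- the margin available for cold sample
#' processing before turnover biases the readout. With the defaults
#' (22 min warm glycosylation time, 37 -> 4 degC, 7 steps) the budget is
#' 216.7 min total and about 31 min per step.
#'
#' @param t_warm Processing time under warm conditions (minutes, > 0).
#' @param T_warm,T_cold Temperatures, both Celsius or both kelvin (only
#'   the difference enters).
#' @param q10 Q10 factor (> 1, default 2).
#' @param n_steps Number of catalytic steps (>= 1, default 7).
#' @return List with `delta_T` (K), `t_cold` (min, 0.1 precision),
#'   `t_per_step` (min, integer precision) and the unrounded
#'   `t_cold_exact`, `t_per_step_exact`.
#' @examples
#' q10_time_budget(22, 37, 4, n_steps = 7)
#' @export
q10_time_budget <- function(t_warm = 22, T_warm = 37, T_cold = 4,
                            q10 = 2, n_steps = 7L) {
  stopifnot_scalar(t_warm, "t_warm", positive = TRUE)
  if (q10 <= 1) stop("q10 must be > 1", call. = FALSE)
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  delta_T <- T_warm - T_cold  # negative allowed: processing warmer than growth
  t_cold <- t_warm * q10^(delta_T / 10)
  t_step <- t_cold / n_steps
  list(delta_T = delta_T,
       t_cold = round(t_cold, 1), t_per_step = round(t_step),
       t_cold_exact = t_cold, t_per_step_exact = t_step)
}

#' Arrhenius time-scaling factor
#'
#' Alternative parameterization of the cold-processing budget via the
#' Arrhenius law `k = k0 * exp(-Ea / (R T))`: the factor by which a
#' first-order process slows when cooled from `T_warm` to `T_cold`,
#' `exp(Ea/R * (1/T_cold - 1/T_warm))`. An activation energy around
#' 50 kJ/mol reproduces a Q10 near 2 at ambient temperatures.
#'
#' @param Ea Activation energy (J/mol, > 0).
#' @param T_warm,T_cold Absolute temperatures (K, > 0).
#' @return Multiplicative time factor (t_cold = factor * t_warm).
#' @export
arrhenius_time_factor <- function(Ea, T_warm, T_cold) {
  if (Ea <= 0 || T_warm <= 0 || T_cold <= 0)
    stop("Ea and absolute temperatures must be > 0", call. = FALSE)
  R <- 8.314462618
  exp(Ea / R * (1 / T_cold - 1 / T_warm))
}

#' Concentration-method QC report
#'
#' Runs both degradation branches of the generator (or takes measured
#' panels), and reports per-base energy charge, triphosphate fraction and
#' the evaporation-vs-lyophilization preservation ratio with pass/fail
#' verdicts against configurable thresholds.
#'
#' @param lyophilized,evaporated Nucleotide panel data frames.
#' @param tp_threshold Minimum acceptable triphosphate fraction after
#'   the mild method (default 0.54).
#' @return Data frame with one row per base and summary attributes
#'   `preservation_pct` and `tp_pass`.
#' @export
qc_report <- function(lyophilized, evaporated, tp_threshold = 0.54) {
  ec_l <- energy_charge(lyophilized)
  ec_e <- energy_charge(evaporated)
  tp_l <- triphosphate_fraction(lyophilized)
  out <- data.frame(base = lyophilized$base,
                    ec_lyophilized = ec_l,
                    ec_evaporated = ec_e,
                    tp_fraction_lyophilized = tp_l,
                    preservation_pct = method_preservation_ratio(ec_e, ec_l),
                    tp_pass = tp_l > tp_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "preservation_pct") <- mean(out$preservation_pct)
  attr(out, "tp_pass") <- all(out$tp_pass)
  out
}
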