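#' Fit a standard-addition calibration line
#'
#' Ordinary least squares of peak area on spiked concentration. The
#' native (unspiked) vial concentration is the x-axis extrapolation
#' `intercept / slope`; its standard error follows by first-order (delta
#' method) propagation of the coefficient covariance.
#'
#' @param set Either a data frame with columns `spike_nM` and `peak_area`
#'   (e.g. from [simulate_standard_addition()]), or a numeric vector of
#'   spikes with `areas` supplied.
#' @param areas Peak areas when `set` is a numeric spike vector.
#' @return An object of class `stdadd_fit` with components `slope`
#'   (area/nM), `intercept` (area), `native_conc` (nM), `se_native` (nM)
#'   and the underlying `lm`.
#' @examples
#' stdadd_fit(c(0, 1, 2), areas = c(50, 150, 250))  # native 0.5 nM
#' @export
stdadd_fit <- function(set, areas = NULL) {
  if (is.data.frame(set)) {
    spike <- set$spike_nM
    area <- set$peak_area
  } else {
    spike <- set
    area <- areas
  }
  if (length(spike) != length(area) || length(spike) < 2L)
    stop("need matching spikes and areas, n >= 2", call. = FALSE)
  if (length(unique(spike)) < 2L)
    stop("singular design: all spike levels identical", call. = FALSE)
  if (any(area < 0)) stop("peak areas must be >= 0", call. = FALSE)
  fit <- stats::lm(area ~ spike)
  cf <- stats::coef(fit)
  slope <- cf[["spike"]]
  intercept <- cf[["(Intercept)"]]
  if (!is.finite(slope) || slope <= 0)
    stop("non-responsive analyte: calibration slope <= 0", call. = FALSE)
  native <- intercept / slope
  # delta method: var(i/s) = vi/s^2 + i^2 vs/s^4 - 2 i cov/s^3
  se_native <- if (length(spike) > 2L) {
    # suppressWarnings: summary.lm complains on exactly collinear
    # (noise-free) data, where the SE is legitimately ~0
    V <- suppressWarnings(stats::vcov(fit))
    sqrt(max(0, V[1, 1] / slope^2 + intercept^2 * V[2, 2] / slope^4 -
               2 * intercept * V[1, 2] / slope^3))
  } else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 native_conc = native, se_native = se_native, lm = fit),
            class = "stdadd_fit")
}

#' @export
print.stdadd_fit <- function(x, digits = 5, ...) {
  cat("Standard-addition calibration\n")
  cat(sprintf("  slope: %s area/nM, intercept: %s area\n",
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits)))
  cat(sprintf("  native concentration: %s nM (SE %s)\n",
              format(x$native_conc, digits = digits),
              format(x$se_native, digits = digits)))
  invisible(x)
}

#' @export
coef.stdadd_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Dilution-chain steps
#'
#' `transfer()` records a partial carry-over of material (a volume taken
#' out of a total volume, or a plain fraction); `reconstitute()` records
#' resuspension of the dried residue in a final volume, which sets the
#' vial volume but moves no material.
#'
#' @param volume_taken,volume_total Volumes (uL) defining the transferred
#'   fraction; alternatively give `fraction` directly.
#' @param fraction Transferred fraction in (0, 1].
#' @return A step object for [dilution_chain()].
#' @export
transfer <- function(volume_taken = NULL, volume_total = NULL,
                     fraction = NULL) {
  if (is.null(fraction)) {
    if (is.null(volume_taken) || is.null(volume_total))
      stop("give volume_taken and volume_total, or fraction", call. = FALSE)
    if (volume_total <= 0 || volume_taken <= 0)
      stop("volumes must be > 0", call. = FALSE)
    fraction <- volume_taken / volume_total
  }
  if (fraction <= 0 || fraction > 1)
    stop("transfer fraction must lie in (0, 1]", call. = FALSE)
  structure(list(type = "transfer", fraction = fraction),
            class = "chain_step")
}

#' @rdname transfer
#' @param volume_uL Reconstitution volume (uL), > 0.
#' @export
reconstitute <- function(volume_uL) {
  if (volume_uL <= 0) stop("volume must be > 0", call. = FALSE)
  structure(list(type = "reconstitution", volume_uL = volume_uL),
            class = "chain_step")
}

#' Sample-conditioning dilution chain
#'
#' Ordered record of every transfer and reconstitution between the
#' original cell sample and the measured vial, plus the cell count the
#' sample was based on. The default chain mirrors the conditioning of a
#' fractionation sample: a 900 uL extraction from which 650 uL of the
#' aqueous phase is transferred, dried, and reconstituted in 100 uL, for
#' 8e6 cells.
#'
#' @param steps List of [transfer()] / [reconstitute()] steps, in order.
#' @param cells Cells per original sample (> 0).
#' @return An object of class `dilution_chain`.
#' @export
dilution_chain <- function(steps = list(transfer(650, 900),
                                        reconstitute(100)),
                           cells = 8e6) {
  if (cells <= 0) stop("cells must be > 0", call. = FALSE)
  if (!all(vapply(steps, inherits, logical(1), "chain_step")))
    stop("steps must be transfer()/reconstitute() objects", call. = FALSE)
  structure(list(steps = steps, cells = cells), class = "dilution_chain")
}

#' @export
print.dilution_chain <- function(x, ...) {
  cat("Dilution chain (", length(x$steps), " steps, ",
      format(x$cells, big.mark = ","), " cells)\n", sep = "")
  for (s in x$steps) {
    if (s$type == "transfer")
      cat(sprintf("  transfer: fraction %.4f\n", s$fraction))
    else
      cat(sprintf("  reconstitution: %.4g uL\n", s$volume_uL))
  }
  invisible(x)
}

chain_fraction <- function(chain) {
  fr <- vapply(chain$steps, function(s)
    if (s$type == "transfer") s$fraction else 1, numeric(1))
  prod(fr)
}

chain_vial_volume <- function(chain) {
  vols <- vapply(chain$steps, function(s)
    if (s$type == "reconstitution") s$volume_uL else NA_real_, numeric(1))
  vols <- vols[!is.na(vols)]
  if (length(vols) == 0L)
    stop("chain has no reconstitution step; supply vial_volume_uL",
         call. = FALSE)
  vols[length(vols)]
}

#' Back-calculate a vial concentration to an amount per cell
#'
#' Moles in the measured vial (`vial_conc * vial_volume`) are divided by
#' the product of all transfer fractions of the conditioning chain (the
#' share of the original extract that reached the vial) and by the cell
#' count, giving amol/cell. `1 nM x 1 uL = 1000 amol` exactly.
#'
#' @param vial_conc_nM Measured vial concentration (nM).
#' @param chain A [dilution_chain()].
#' @param vial_volume_uL Vial volume (uL); defaults to the chain's last
#'   reconstitution volume.
#' @return Amount in amol/cell.
#' @examples
#' # 100 nM in a 100 uL vial, one 650/900 transfer, 8e6 cells
#' back_calculate_per_cell(100, dilution_chain(list(transfer(650, 900),
#'                                                  reconstitute(100))))
#' @export
back_calculate_per_cell <- function(vial_conc_nM, chain,
                                    vial_volume_uL = NULL) {
  if (is.null(vial_volume_uL)) vial_volume_uL <- chain_vial_volume(chain)
  fr <- chain_fraction(chain)
  if (fr <= 0) stop("zero transfer fraction in chain", call. = FALSE)
  amol_in_vial <- vial_conc_nM * vial_volume_uL * 1000  # nM * uL -> amol
  amol_in_vial / fr / chain$cells
}

#' Expected vial concentration for a given per-cell amount
#'
#' Exact inverse of [back_calculate_per_cell()]; used to couple the
#' ground-truth pools to simulated standard-addition signals.
#'
#' @inheritParams back_calculate_per_cell
#' @param amount_amol_per_cell Amount per cell (amol/cell).
#' @return Vial concentration in nM.
#' @export
expected_vial_conc <- function(amount_amol_per_cell, chain,
                               vial_volume_uL = NULL) {
  if (is.null(vial_volume_uL)) vial_volume_uL <- chain_vial_volume(chain)
  amount_amol_per_cell * chain$cells * chain_fraction(chain) /
    (vial_volume_uL * 1000)
}

#' Flag a vial concentration against the method detection limit
#'
#' Below the MDL the value is `"below"`; between the MDL and three times
#' the MDL, `"near"`; at or above the threefold margin, `"pass"` (the
#' margin by which the lowest reliably quantified level should clear the
#' median 12 nM MDL).
#'
#' @param vial_conc_nM Vial concentration(s) in nM.
#' @param mdl Method detection limit in nM (> 0, default 12).
#' @return Character vector of flags.
#' @export
mdl_flag <- function(vial_conc_nM, mdl = 12) {
  if (mdl <= 0) stop("mdl must be > 0", call. = FALSE)
  ifelse(vial_conc_nM < mdl, "below",
         ifelse(vial_conc_nM < 3 * mdl, "near", "pass"))
}

#' @rdname mdl_flag
#' @param result Data frame with a `vial_conc_nM` column (a quantification
#'   table); a `mdl_flag` column is added or replaced.
#' @export
apply_mdl <- function(result, mdl = 12) {
  result$mdl_flag <- mdl_flag(result$vial_conc_nM, mdl)
  result
}

#' Golgi-to-cytoplasm amount ratio
#'
#' @param cp_amount CP amount (amol/cell), > 0 for a defined ratio.
#' @param ga_amount GA amount (amol/cell).
#' @return `ga_amount / cp_amount`; `NA` with a warning when the CP
#'   amount is zero (undefined, not infinite).
#' @export
compartment_ratio <- function(cp_amount, ga_amount) {
  out <- ifelse(cp_amount == 0, NA_real_, ga_amount / cp_amount)
  if (any(cp_amount == 0))
    warning("undefined GA:CP ratio for zero CP amount; returning NA")
  out
}
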