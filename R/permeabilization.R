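#' Normalize a titration series
#'
#' Default convention (`"total_max"`): for each analyte, every amount is
#' divided by that analyte's maximum per-level total (CP + organelle,
#' replicate means) across the digitonin gradient, so the largest total
#' cellular amount becomes 1. The `"per_fraction"` convention instead
#' divides each (analyte, fraction) series by its own per-level maximum,
#' giving the released share of each fraction's releasable content -- the
#' scale on which the permeabilization curve itself spans floor to
#' saturation regardless of how the pools are distributed, and the one
#' the pipeline's design stage fits.
#'
#' @param series Titration data frame (see [simulate_titration()]).
#' @param denominator `"total_max"` (default) or `"per_fraction"`.
#' @return The series with `amount_amol_per_cell` rescaled per analyte.
#' @export
normalize_series <- function(series,
                             denominator = c("total_max", "per_fraction")) {
  denominator <- match.arg(denominator)
  out <- series
  for (an in unique(series$analyte)) {
    sel <- series$analyte == an
    sub <- series[sel, , drop = FALSE]
    if (all(sub$amount_amol_per_cell == 0))
      stop(sprintf("analyte '%s' has all-zero amounts; cannot normalize", an),
           call. = FALSE)
    lev <- stats::aggregate(
      amount_amol_per_cell ~ digitonin_ug_per_ml + fraction,
      data = sub, FUN = mean)
    if (denominator == "total_max") {
      # per-level total over fractions = sum of fraction means at that level
      tot <- stats::aggregate(amount_amol_per_cell ~ digitonin_ug_per_ml,
                              data = lev, FUN = sum)
      denom <- max(tot$amount_amol_per_cell)
      out$amount_amol_per_cell[sel] <- sub$amount_amol_per_cell / denom
    } else {
      for (fr in unique(sub$fraction)) {
        denom <- max(lev$amount_amol_per_cell[lev$fraction == fr])
        if (denom == 0)
          stop(sprintf("fraction '%s' of analyte '%s' is all zero", fr, an),
               call. = FALSE)
        fsel <- sel & series$fraction == fr
        out$amount_amol_per_cell[fsel] <-
          series$amount_amol_per_cell[fsel] / denom
      }
    }
  }
  out
}

#' Literature-informed compartment distribution
#'
#' Computes relative amounts `n_i = c_i * V_i` from relative
#' concentrations and volumes of the Golgi apparatus and cytoplasm, and
#' the shares `r_i = n_i / sum(n)`. With the literature defaults (GA
#' concentration 40x the CP at 2.2% of cell volume vs. 55%) the Golgi
#' holds 62% and the cytoplasm 38% of the NSD amount -- the CP share used
#' as the target released fraction when choosing the operating digitonin
#' concentration.
#'
#' @param conc_ga,conc_cp Relative concentrations (unitless, > 0).
#' @param vol_ga,vol_cp Relative volumes (unitless, > 0).
#' @return List with `amounts` (named GA/CP), `total`, and `shares_pct`
#'   (named GA/CP, summing to 100).
#' @examples
#' compartment_distribution()  # GA 62%, CP 38%
#' @export
compartment_distribution <- function(conc_ga = 40, vol_ga = 0.022,
                                     conc_cp = 1, vol_cp = 0.55) {
  vals <- c(conc_ga = conc_ga, vol_ga = vol_ga,
            conc_cp = conc_cp, vol_cp = vol_cp)
  if (any(vals <= 0))
    stop("concentrations and volumes must all be > 0", call. = FALSE)
  n <- c(GA = conc_ga * vol_ga, CP = conc_cp * vol_cp)
  total <- sum(n)
  if (total == 0) stop("zero total amount", call. = FALSE)
  list(amounts = n, total = total, shares_pct = 100 * n / total)
}

#' Select the operating digitonin concentration
#'
#' Inverts the fitted release sigmoid at the target CP share and rounds
#' DOWN to the largest available grid concentration not exceeding the
#' exact solve, protecting the organelle fraction from
#' cross-contamination (under-permeabilizing is safe, over-permeabilizing
#' lyses organelles). If the exact solve lies below every grid value, the
#' smallest grid value is returned with a warning flag.
#'
#' @param fit A `release_fit` object, numeric `c(a, b, c, d)`, or a
#'   single numeric exact solve (ug/mL).
#' @param target_cp_share Target released fraction (default 0.38, the CP
#'   share of the default compartment distribution).
#' @param grid Available digitonin concentrations (ug/mL).
#' @return List with `exact` (closed-form solve, ug/mL), `selected`
#'   (grid value) and `below_grid` (logical warning flag).
#' @export
select_operating_digitonin <- function(fit, target_cp_share = 0.38,
                                       grid = c(25, 50, 100, 200, 300, 400)) {
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  exact <- if (is.numeric(fit) && length(fit) == 1L) fit
           else invert_sigmoid(fit, target_cp_share)
  le <- grid[grid <= exact]
  if (length(le) == 0L) {
    warning("exact solve below all grid concentrations; returning smallest")
    return(list(exact = exact, selected = min(grid), below_grid = TRUE))
  }
  list(exact = exact, selected = max(le), below_grid = FALSE)
}
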