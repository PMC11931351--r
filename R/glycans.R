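#' Calibrate a glucose-unit (GU) retention-time map
#'
#' Builds the piecewise-linear monotone map from HILIC retention time to
#' glucose units defined by a dextran ladder: exact at ladder nodes,
#' linearly interpolated between them, and linearly extrapolated beyond
#' the ends using the terminal segment slopes (extrapolated predictions
#' are flagged).
#'
#' @param rt Ladder retention times (minutes), strictly increasing.
#' @param gu Glucose units at those times, strictly increasing.
#' @return An object of class `gu_calibration`.
#' @export
gu_calibrate <- function(rt, gu) {
  if (length(rt) < 2L || length(rt) != length(gu))
    stop("ladder needs >= 2 matched (rt, gu) points", call. = FALSE)
  if (is.unsorted(rt, strictly = TRUE) || is.unsorted(gu, strictly = TRUE))
    stop("ladder must be strictly increasing in both rt and gu",
         call. = FALSE)
  structure(list(rt = rt, gu = gu), class = "gu_calibration")
}

#' @export
print.gu_calibration <- function(x, ...) {
  cat("GU calibration ladder (", length(x$rt), " nodes, rt ",
      format(min(x$rt)), "-", format(max(x$rt)), " min, GU ",
      format(min(x$gu)), "-", format(max(x$gu)), ")\n", sep = "")
  invisible(x)
}

#' Map retention times to glucose units
#'
#' @param object A [gu_calibrate()] calibration.
#' @param newdata Retention times (minutes).
#' @param ... Unused.
#' @return Numeric GU values with attribute `extrapolated` (logical per
#'   value) marking predictions outside the ladder range.
#' @export
predict.gu_calibration <- function(object, newdata, ...) {
  rt <- object$rt
  gu <- object$gu
  n <- length(rt)
  i <- findInterval(newdata, rt, all.inside = TRUE)
  slope <- (gu[i + 1] - gu[i]) / (rt[i + 1] - rt[i])
  out <- gu[i] + slope * (newdata - rt[i])
  extrap <- newdata < rt[1] | newdata > rt[n]
  if (any(extrap))
    warning("retention time(s) outside ladder range; linearly extrapolated")
  attr(out, "extrapolated") <- extrap
  out
}

#' Synthetic IgG N-glycan GU library
#'
#' Representative glucose-unit values for the core-fucosylated
#' biantennary IgG species (synthetic stand-ins for a published 2-AB
#' library table; not measured values).
#'
#' @return Data frame with columns `name` and `gu`.
#' @export
default_glycan_library <- function() {
  data.frame(name = c("FA2", "FA2G1", "FA2G2"),
             gu = c(5.88, 6.75, 7.62),
             stringsAsFactors = FALSE)
}

#' Assign glycan peaks to library species by GU
#'
#' Each peak's retention time is converted to GU and matched to the
#' nearest library entry within `tolerance`; peaks farther than the
#' tolerance from every entry are reported as unassigned. A peak exactly
#' equidistant between two entries is assigned to the lower-GU entry
#' with a warning.
#'
#' @param peaks Data frame with column `rt_min` and optionally `area`
#'   (defaults to 1), or a numeric vector of retention times.
#' @param calib A [gu_calibrate()] calibration.
#' @param library Data frame with columns `name`, `gu`.
#' @param tolerance Maximum |GU| distance for an assignment (> 0).
#' @return List with `profile` (named numeric: summed area per assigned
#'   species) and `unassigned` (data frame of unmatched peaks).
#' @export
assign_glycans <- function(peaks, calib, library = default_glycan_library(),
                           tolerance = 0.3) {
  if (nrow(library) == 0L) stop("glycan library is empty", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (!is.data.frame(peaks))
    peaks <- data.frame(rt_min = peaks)
  if (is.null(peaks$area)) peaks$area <- 1
  gu <- as.numeric(predict(calib, peaks$rt_min))
  lib <- library[order(library$gu), , drop = FALSE]
  assigned <- character(nrow(peaks))
  tie <- FALSE
  for (j in seq_len(nrow(peaks))) {
    d <- abs(lib$gu - gu[j])
    if (min(d) > tolerance) { assigned[j] <- NA_character_; next }
    hits <- which(d == min(d))
    if (length(hits) > 1L) tie <- TRUE
    assigned[j] <- lib$name[hits[1]]  # lib sorted by gu: ties -> lower GU
  }
  if (tie) warning("peak(s) equidistant between library entries; ",
                   "assigned to the lower-GU entry")
  ok <- !is.na(assigned)
  profile <- tapply(peaks$area[ok], assigned[ok], sum)
  profile <- stats::setNames(as.numeric(profile), names(profile))
  list(profile = profile,
       unassigned = data.frame(rt_min = peaks$rt_min[!ok],
                               gu = gu[!ok], area = peaks$area[!ok]))
}

#' Normalize glycan abundances to fractions
#'
#' @param profile Named numeric of non-negative abundances.
#' @return The profile divided by its total (fractions summing to 1).
#' @export
relative_abundances <- function(profile) {
  if (any(profile < 0)) stop("abundances must be >= 0", call. = FALSE)
  total <- sum(profile)
  if (total <= 0) stop("zero total abundance", call. = FALSE)
  profile / total
}

#' Galactosylation index I_G
#'
#' Summarizes terminal galactose occupancy of the biantennary IgG
#' species FA2 (no galactose), FA2G1 (one) and FA2G2 (two). The default
#' arm-normalized convention,
#' `I_G = 100 * (2 FA2G2 + FA2G1) / (2 * (FA2 + FA2G1 + FA2G2))`,
#' is the fraction of occupied arms and is bounded in `[0, 100]`. The
#' `"as_printed"` convention omits the factor 2 in the denominator
#' (galactoses per glycan, in percent) and can exceed 100.
#'
#' @param profile Named numeric containing at least `FA2`, `FA2G1`,
#'   `FA2G2` (absolute or relative abundances; the index is
#'   scale-invariant). Additional species are ignored.
#' @param convention `"arm_normalized"` (default) or `"as_printed"`.
#' @return I_G in percent, with attribute `convention`.
#' @examples
#' galactosylation_index(c(FA2 = 1, FA2G1 = 1, FA2G2 = 1))  # 50
#' @export
galactosylation_index <- function(profile,
                                  convention = c("arm_normalized",
                                                 "as_printed")) {
  convention <- match.arg(convention)
  need <- c("FA2", "FA2G1", "FA2G2")
  if (!all(need %in% names(profile)))
    stop("profile must contain FA2, FA2G1 and FA2G2", call. = FALSE)
  fa2 <- profile[["FA2"]]; g1 <- profile[["FA2G1"]]; g2 <- profile[["FA2G2"]]
  denom <- fa2 + g1 + g2
  if (denom <= 0) stop("zero FA2 + FA2G1 + FA2G2 total", call. = FALSE)
  ig <- if (convention == "arm_normalized")
    100 * (2 * g2 + g1) / (2 * denom)
  else
    100 * (2 * g2 + g1) / denom
  attr(ig, "convention") <- convention
  ig
}
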