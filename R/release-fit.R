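#' Evaluate the four-parameter logistic release curve
#'
#' `y(x) = a + b / (1 + exp((c - x) / d))`: `a` is the floor, `b` the
#' span, `c` the midpoint (half-maximal release, `y(c) = a + b/2`) and
#' `d` the steepness scale, all in digitonin ug/mL where dimensional.
#' The curve is strictly increasing for `b > 0, d > 0`.
#'
#' @param fit A `release_fit` object or a numeric vector `c(a, b, c, d)`.
#' @param x Digitonin concentrations (ug/mL).
#' @return Released fraction(s) at `x`.
#' @examples
#' eval_sigmoid(c(0, 1, 50, 10), 50)  # 0.5
#' @export
eval_sigmoid <- function(fit, x) {
  p <- release_coefs(fit)
  p[["a"]] + p[["b"]] / (1 + exp((p[["c"]] - x) / p[["d"]]))
}

#' Invert the release curve (closed form)
#'
#' Solves `y(x) = y` for `x`: `x = c - d * log(b / (y - a) - 1)`.
#' Defined only on the open range `(a, a + b)`.
#'
#' @param fit A `release_fit` object or numeric `c(a, b, c, d)`.
#' @param y Target released fraction(s), strictly inside `(a, a + b)`.
#' @return Digitonin concentration(s) (ug/mL).
#' @export
invert_sigmoid <- function(fit, y) {
  p <- release_coefs(fit)
  lo <- p[["a"]]; hi <- p[["a"]] + p[["b"]]
  if (any(y <= lo | y >= hi))
    stop(sprintf("y must lie strictly inside (%.4g, %.4g); no solution",
                 lo, hi), call. = FALSE)
  p[["c"]] - p[["d"]] * log(p[["b"]] / (y - p[["a"]]) - 1)
}

release_coefs <- function(fit) {
  if (inherits(fit, "release_fit")) return(fit$coefficients)
  if (is.numeric(fit) && length(fit) == 4L) {
    names(fit) <- c("a", "b", "c", "d")
    return(fit)
  }
  stop("fit must be a release_fit object or numeric c(a, b, c, d)",
       call. = FALSE)
}

#' Fit the digitonin release sigmoid
#'
#' Least-squares fit of the four-parameter logistic
#' `y = a + b / (1 + exp((c - x) / d))` to a (normalized) titration
#' series, the model describing selective plasma-membrane
#' permeabilization: digitonin perforates the cholesterol-rich
#' cytoplasmic membrane with a sigmoidal dose dependence while sparing
#' organelles at low doses.
#'
#' By default replicate measurements are averaged per digitonin level and
#' across analytes before fitting (the fit then describes the average
#' release behaviour of the panel, as a release curve fitted over all
#' metabolites would); `aggregate = "replicates"` fits all points.
#' Levenberg-Marquardt optimization with heuristic starts and up to
#' `restarts` jittered restarts under a fixed sub-seed.
#'
#' @param series Titration data frame (columns `analyte`,
#'   `digitonin_ug_per_ml`, `fraction`, `replicate`,
#'   `amount_amol_per_cell`), normally from [normalize_series()], or a
#'   data frame with plain `x`/`y` columns.
#' @param fraction Which fraction's release to fit (default `"CP"`).
#' @param aggregate `"mean"` (replicate/analyte means per level) or
#'   `"replicates"` (all points).
#' @param restarts Maximum jittered restarts after the heuristic start.
#' @return An object of class `release_fit` with components
#'   `coefficients` (a, b, c, d), `r_squared`, `n_points`, `data`,
#'   `fitted.values`, `residuals` and the underlying `nls` fit.
#' @seealso [eval_sigmoid()], [invert_sigmoid()],
#'   [select_operating_digitonin()]
#' @export
release_fit <- function(series, fraction = "CP",
                        aggregate = c("mean", "replicates"),
                        restarts = 5L) {
  aggregate <- match.arg(aggregate)
  if (all(c("x", "y") %in% names(series))) {
    df <- data.frame(x = series$x, y = series$y)
  } else {
    sub <- series[series$fraction == fraction, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop(sprintf("no rows with fraction '%s'", fraction), call. = FALSE)
    if (aggregate == "mean") {
      agg <- stats::aggregate(amount_amol_per_cell ~ digitonin_ug_per_ml,
                              data = sub, FUN = mean)
      df <- data.frame(x = agg$digitonin_ug_per_ml,
                       y = agg$amount_amol_per_cell)
    } else {
      df <- data.frame(x = sub$digitonin_ug_per_ml,
                       y = sub$amount_amol_per_cell)
    }
  }
  if (length(unique(df$x)) < 4L)
    stop("need >= 4 distinct digitonin levels to fit 4 parameters",
         call. = FALSE)
  yr <- range(df$y)
  if (diff(yr) < 1e-10 * max(1, abs(yr[2])))
    stop("degenerate input: response is constant (span ~ 0)", call. = FALSE)

  span_x <- diff(range(df$x))
  start0 <- c(a = yr[1], b = diff(yr),
              c = df$x[which.min(abs(df$y - mean(yr)))],
              d = span_x / 4)
  lower <- c(a = -Inf, b = 1e-9, c = min(df$x) - span_x,
             d = 1e-6)
  upper <- c(a = Inf, b = Inf, c = max(df$x) + span_x, d = Inf)

  starts <- list(start0)
  jit <- with_seed(1L, lapply(seq_len(restarts), function(i)
    start0 * stats::runif(4, 0.6, 1.5)))
  starts <- c(starts, lapply(jit, function(s)
    pmin(pmax(s, lower + 1e-8), c(Inf, Inf, upper[["c"]], Inf))))

  best <- NULL
  best_rss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + b / (1 + exp((c - x) / d)),
                        data = df, start = as.list(s),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop(sprintf(
      "sigmoid fit failed to converge after %d restarts (best residual: %s)",
      restarts, format(best_rss)), call. = FALSE)

  cf <- stats::coef(best)
  ss_tot <- sum((df$y - mean(df$y))^2)
  r2 <- 1 - best_rss / ss_tot
  structure(list(coefficients = cf, r_squared = r2, n_points = nrow(df),
                 data = df, fitted.values = stats::fitted(best),
                 residuals = stats::residuals(best), nls = best,
                 fraction = fraction),
            class = "release_fit")
}

#' @export
coef.release_fit <- function(object, ...) object$coefficients

#' @export
print.release_fit <- function(x, digits = 5, ...) {
  cat("Four-parameter logistic digitonin release fit\n")
  cat("  y(x) = a + b / (1 + exp((c - x)/d))\n\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nR-squared: %.4f on %d points (fraction: %s)\n",
              x$r_squared, x$n_points, x$fraction))
  invisible(x)
}

#' @export
summary.release_fit <- function(object, ...) {
  s <- summary(object$nls)
  structure(list(fit = object, nls_summary = s,
                 midpoint = object$coefficients[["c"]],
                 asymptotes = c(lower = object$coefficients[["a"]],
                                upper = object$coefficients[["a"]] +
                                  object$coefficients[["b"]])),
            class = "summary.release_fit")
}

#' @export
print.summary.release_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter standard errors:\n")
  print(x$nls_summary$coefficients)
  cat(sprintf("\nAsymptotes: %.4f (floor) to %.4f (saturation)\n",
              x$asymptotes[["lower"]], x$asymptotes[["upper"]]))
  invisible(x)
}

#' @export
predict.release_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  eval_sigmoid(object, x)
}

#' @export
residuals.release_fit <- function(object, ...) object$residuals

#' @export
fitted.release_fit <- function(object, ...) object$fitted.values

#' Simulate normalized release measurements from a fitted curve
#'
#' Draws `nsim` replicate series from the fitted sigmoid with
#' multiplicative lognormal noise, mirroring the generator's noise model.
#'
#' @param object A `release_fit`.
#' @param nsim Number of replicate series.
#' @param seed Optional integer seed.
#' @param noise_cv CV of the multiplicative noise (default 0.10).
#' @param ... Unused.
#' @return Data frame of simulated responses, one column per replicate.
#' @export
simulate.release_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_cv = 0.10, ...) {
  mu <- eval_sigmoid(object, object$data$x)
  draw <- function() mu * lognormal_factors(length(mu), noise_cv)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "x") <- object$data$x
  out
}

#' @export
plot.release_fit <- function(x, n_curve = 200, ...) {
  df <- x$data
  xx <- seq(min(df$x), max(df$x), length.out = n_curve)
  graphics::plot(df$x, df$y, xlab = "digitonin (ug/mL)",
                 ylab = "normalized released fraction",
                 main = "Digitonin release sigmoid", ...)
  graphics::lines(xx, eval_sigmoid(x, xx), col = "steelblue", lwd = 2)
  graphics::abline(v = x$coefficients[["c"]], lty = 3)
  invisible(x)
}
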