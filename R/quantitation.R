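#' Fit an internal-standard calibration curve
#'
#' Least-squares line of response ratio (analyte / isotope-labeled internal
#' standard) on known concentration. Twelve-point curves are typical for
#' GC-MS quantitation of TCA metabolites and ten-point for LC-MS amino-acid
#' panels; at least five points are required to fit. A warning is emitted
#' when r-squared drops below 0.98, the usual bioanalytical acceptance
#' level.
#'
#' @param concentrations known calibrator concentrations (umol/L), strictly
#'   increasing.
#' @param responses measured response ratios, same length.
#' @param analyte analyte name (annotation only).
#' @param weighting `"none"` (default) or `"1/x"` (inverse-concentration
#'   weights, useful when variance grows with level).
#' @return object of class `calibration_curve`: `analyte`, `slope`,
#'   `intercept`, `r_squared`, `weighting`, `points`.
#' @examples
#' conc <- seq(5, 60, length.out = 12)
#' fit_calibration(conc, 0.02 * conc + 0.01, analyte = "glutamate")
#' @export
fit_calibration <- function(concentrations, responses, analyte = "analyte",
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  if (length(concentrations) != length(responses))
    stop("concentrations and responses must have equal length")
  if (length(concentrations) < 5L)
    stop("at least 5 calibration points are required (got ",
         length(concentrations), ")")
  if (any(diff(concentrations) <= 0))
    stop("calibrator concentrations must be strictly increasing")
  w <- if (weighting == "1/x") 1 / concentrations else NULL
  fit <- lm(responses ~ concentrations, weights = w)
  r2 <- cor(responses, stats::fitted(fit))^2
  if (r2 < 0.98)
    warning(sprintf("calibration r-squared %.4f below 0.98 for '%s'",
                    r2, analyte))
  structure(list(analyte = analyte, slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]), r_squared = r2,
                 weighting = weighting,
                 points = data.frame(concentration = concentrations,
                                     response = responses)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: response = %.6g * conc + %.6g (r2 = %.5f, %d points, weighting %s)\n",
    x$analyte, x$slope, x$intercept, x$r_squared, nrow(x$points),
    x$weighting))
  invisible(x)
}

#' Back-calculate concentrations from a calibration curve
#'
#' Inverts the fitted line: `(ratio - intercept) / slope`. Negative
#' estimates (response below the fitted blank) are floored at zero with a
#' warning. Responses beyond 1.5x the top calibrator are flagged as
#' extrapolation rather than rejected, since clinical samples can exceed
#' the calibrated range.
#'
#' @param curve a [fit_calibration()] result.
#' @param response_ratio numeric vector of measured response ratios.
#' @return data.frame `response`, `concentration` (umol/L), `extrapolated`.
#' @export
quantify <- function(curve, response_ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (abs(curve$slope) < 1e-12)
    stop("calibration slope is (near) zero; curve cannot be inverted")
  conc <- (response_ratio - curve$intercept) / curve$slope
  # numerically-zero negatives are clamped silently; real ones warn
  neg <- is.finite(conc) & conc < -1e-9 * max(abs(conc), 1)
  if (any(neg))
    warning(sum(neg), " negative concentration estimate(s) floored at 0")
  conc[is.finite(conc) & conc < 0] <- 0
  extr <- response_ratio > 1.5 * max(curve$points$response)
  if (any(extr))
    warning(sum(extr), " response(s) beyond 1.5x the top calibrator; ",
            "flagged as extrapolation")
  data.frame(response = response_ratio, concentration = conc,
             extrapolated = extr)
}

#' Cross-platform concentration concordance
#'
#' Compares absolute concentrations of the same analyte measured on two
#' platforms (e.g. GC-MS vs LC-MS) on matched samples; delegates to
#' [correlate()]. Slope near 1 and r near 1 indicate concordance.
#'
#' @param gc,lc data.frames with columns `sample_id` and `concentration`
#'   for the same analyte on each platform.
#' @return list `slope`, `intercept`, `r`, `n` over matched samples.
#' @export
platform_concordance <- function(gc, lc) {
  ids <- intersect(gc$sample_id, lc$sample_id)
  if (length(ids) < 3L)
    stop("fewer than 3 matched samples between platforms")
  x <- gc$concentration[match(ids, gc$sample_id)]
  y <- lc$concentration[match(ids, lc$sample_id)]
  correlate(x, y)
}
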