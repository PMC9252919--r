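#' Relative redox-cycling increase
#'
#' \eqn{(A - A_0)/A_0}, where \eqn{A} is the reporter absorbance of the
#' treated well (phenol red / horseradish peroxidase assay, 610 nm) and
#' \eqn{A_0} that of the vehicle control.
#'
#' @param a Treated-well absorbance.
#' @param a0 Control absorbance (> 0).
#' @return Relative increase (dimensionless; 0 at control level).
#' @examples
#' redox_cycling_increase(0.50, 0.25)  # 1.0
#' @export
redox_cycling_increase <- function(a, a0) {
  if (any(!is.finite(a0)) || any(a0 <= 0)) {
    stop("control absorbance a0 must be positive", call. = FALSE)
  }
  (a - a0) / a0
}

#' Methaemoglobin increase (percent)
#'
#' \eqn{(A_{630} - A_{630}^0)/A_{630}^0 \times 100}: percentage increase in
#' 630 nm absorbance of lysed blood relative to the untreated control.
#'
#' @param a630 Treated-well absorbance at 630 nm.
#' @param a630_control Negative-control absorbance at 630 nm (> 0).
#' @return Percent increase (may be negative).
#' @examples
#' methemoglobin_increase(0.2, 0.1)  # 100
#' @export
methemoglobin_increase <- function(a630, a630_control) {
  if (any(!is.finite(a630_control)) || any(a630_control <= 0)) {
    stop("control absorbance must be positive", call. = FALSE)
  }
  (a630 - a630_control) / a630_control * 100
}

#' Haemolysis percentage
#'
#' \eqn{(A_{540} - A_{540}^0)/(A_{540}^{total} - A_{540}^0) \times 100}:
#' 0% at the negative control, 100% at the total-lysis (detergent) control.
#' Affine-invariant: adding a constant to all three absorbances leaves the
#' result unchanged.
#'
#' @param a540 Test-well absorbance at 540 nm.
#' @param a540_negative Negative-control absorbance.
#' @param a540_total Total-lysis control absorbance (must exceed the
#'   negative control).
#' @return Percent haemolysis.
#' @examples
#' hemolysis_percent(0.5, 0.1, 0.9)  # 50
#' @export
hemolysis_percent <- function(a540, a540_negative, a540_total) {
  if (any(!is.finite(c(a540, a540_negative, a540_total)))) {
    stop("absorbances must be finite", call. = FALSE)
  }
  if (any(a540_total <= a540_negative)) {
    stop("total-lysis control must exceed the negative control", call. = FALSE)
  }
  (a540 - a540_negative) / (a540_total - a540_negative) * 100
}

#' Tumour volume from caliper measurements
#'
#' \eqn{V = l \cdot w^2 / 2} in mm\eqn{^3}, with the longest axis first.
#' If `width > length` the two are swapped with a warning.
#'
#' @param length Longest axis, mm (> 0).
#' @param width Perpendicular axis, mm (> 0).
#' @return Volume in mm\eqn{^3}.
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length, width) {
  if (any(!is.finite(c(length, width))) || any(length <= 0) || any(width <= 0)) {
    stop("dimensions must be positive (mm)", call. = FALSE)
  }
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); axes swapped (longest axis first)")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Light-scattering-corrected A280
#'
#' \eqn{A_{280} - 1.929 \, A_{330}}: protein absorbance corrected for the
#' scattering contribution estimated at 330 nm (used when quantifying
#' antibody conjugates). A negative result (scattering-dominated sample)
#' is passed through with a warning.
#'
#' @param a280 Absorbance at 280 nm.
#' @param a330 Absorbance at 330 nm.
#' @return Corrected absorbance.
#' @examples
#' corrected_a280(1.0, 0.1)  # 0.8071
#' @export
corrected_a280 <- function(a280, a330) {
  if (any(!is.finite(c(a280, a330)))) {
    stop("absorbances must be finite", call. = FALSE)
  }
  out <- a280 - 1.929 * a330
  if (any(out < 0)) {
    warning("corrected A280 is negative for ", sum(out < 0),
            " value(s); sample may be scattering-dominated")
  }
  out
}

#' Weighted linear calibration curve
#'
#' Fits a straight line response = intercept + slope * concentration by
#' weighted least squares with weights \eqn{x^{-p}} (default \eqn{p = 2},
#' the 1/x^2 weighting standard in bioanalytical back-calculation, which
#' equalizes relative rather than absolute errors). `weighting_exponent = 0`
#' is ordinary least squares.
#'
#' @param concentration Standard concentrations (>= 3 values; strictly
#'   positive when `weighting_exponent > 0`).
#' @param response_ratio Analyte/internal-standard response ratios.
#' @param weighting_exponent Non-negative exponent \eqn{p} in \eqn{w = x^{-p}}.
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   the weighting exponent, the standards and the underlying `lm` fit.
#' @seealso [back_calculate()]
#' @examples
#' cal <- fit_weighted_calibration(c(0.25, 1, 10, 100), c(0.05, 0.2, 2, 20))
#' back_calculate(cal, 1.0)
#' @export
fit_weighted_calibration <- function(concentration, response_ratio,
                                     weighting_exponent = 2) {
  if (length(concentration) != length(response_ratio)) {
    stop("concentration and response_ratio must have equal length",
         call. = FALSE)
  }
  if (length(concentration) < 3) {
    stop("insufficient standards: need >= 3", call. = FALSE)
  }
  if (weighting_exponent < 0) {
    stop("weighting_exponent must be >= 0", call. = FALSE)
  }
  if (weighting_exponent > 0 && any(concentration <= 0)) {
    stop("concentrations must be positive for 1/x^p weighting", call. = FALSE)
  }
  if (length(unique(concentration)) < 2) {
    stop("singular design: concentrations are all equal", call. = FALSE)
  }
  w <- if (weighting_exponent == 0) rep(1, length(concentration)) else
    concentration^(-weighting_exponent)
  df <- data.frame(concentration = concentration,
                   response_ratio = response_ratio)
  fit <- stats::lm(response_ratio ~ concentration, data = df, weights = w)
  structure(list(
    slope = unname(stats::coef(fit)[["concentration"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    weighting_exponent = weighting_exponent,
    standards = df,
    lloq = min(concentration),
    fit = fit
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration (1/x^%g weights): response = %.6g + %.6g * conc (LLOQ %g)\n",
    x$weighting_exponent, x$intercept, x$slope, x$lloq))
  invisible(x)
}

#' Back-calculate concentrations from a calibration curve
#'
#' Inverts the fitted line: \eqn{x = (r - b)/m}. Results below the lowest
#' calibration standard (the lower limit of quantification) are flagged via
#' the `censored` attribute and a warning; negative back-calculations are
#' additionally below-limit by definition.
#'
#' @param curve A [fit_weighted_calibration()] result.
#' @param response_ratio Observed response ratio(s).
#' @return Numeric concentrations with a logical `censored` attribute
#'   marking values below the LLOQ.
#' @export
back_calculate <- function(curve, response_ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  conc <- (response_ratio - curve$intercept) / curve$slope
  # small relative tolerance so a value at the LLOQ itself is not flagged
  censored <- conc < curve$lloq * (1 - 1e-9)
  if (any(censored)) {
    warning(sum(censored), " back-calculated value(s) below the lower ",
            "limit of quantification (", curve$lloq, "); flagged as censored")
  }
  attr(conc, "censored") <- censored
  attr(conc, "lloq") <- curve$lloq
  conc
}
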