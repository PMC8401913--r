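# Internal-standard-normalized calibration: fit, back-calculation,
# quantification within the validated range.

#' Build calibration standards from a plate
#'
#' Computes the response ratio (analyte / internal standard) for the
#' `cal` rows of a plate data.frame.
#'
#' @param plate plate data.frame (see [read_plate()]).
#' @return data.frame with `nominal`, `ratio` columns.
#' @export
calibration_standards <- function(plate) {
  cal <- plate[plate$role == "cal", , drop = FALSE]
  assert_that(nrow(cal) > 0, "plate contains no calibration (role = 'cal') rows")
  assert_that(all(cal$is_response > 0), "IS responses must be positive")
  data.frame(nominal = cal$nominal_ng_per_ml,
             ratio = cal$analyte_response / cal$is_response)
}

#' Fit the internal-standard-normalized calibration line
#'
#' Least-squares line of response ratio on nominal concentration, with
#' optional `1/x` or `1/x^2` weighting (weights are evaluated at the
#' nominal concentration, the usual bioanalytical choice). R-squared is
#' computed under the same weights. The quantification range
#' `[lloq, uloq]` is set to the span of the fitted standards.
#'
#' @param standards data.frame with `nominal` (ng/mL, >= 3 distinct
#'   levels) and `ratio` columns, e.g. from [calibration_standards()].
#' @param weighting one of `"none"`, `"1/x"`, `"1/x2"`.
#' @return an object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `lloq`, `uloq`, `n_points`, `weighting`.
#' @export
fit_calibration <- function(standards, weighting = c("none", "1/x", "1/x2")) {
  weighting <- match.arg(weighting)
  assert_that(all(c("nominal", "ratio") %in% names(standards)),
              "`standards` needs `nominal` and `ratio` columns")
  x <- standards$nominal
  y <- standards$ratio
  if (length(unique(x)) == 1)
    pk_stop("all nominal levels equal: rank-deficient design",
            "pkassay_rank_deficiency_error")
  if (length(unique(x)) < 3)
    pk_stop("calibration needs at least 3 distinct nominal levels",
            "pkassay_insufficient_data_error")
  w <- switch(weighting,
              "none" = rep(1, length(x)),
              "1/x" = 1 / x,
              "1/x2" = 1 / x^2)
  if (weighting != "none")
    assert_that(all(x > 0),
                "1/x-style weighting requires positive nominal levels")
  fit <- stats::lm(y ~ x, weights = w)
  coefs <- stats::coef(fit)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (y - ybar)^2)
  structure(
    list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
         r_squared = r2, lloq = min(x), uloq = max(x),
         n_points = length(x), weighting = weighting),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> y = %.6gx %+.6g  (n = %d, weighting %s)\n  R^2 = %.6g, range %g-%g ng/mL\n",
    x$slope, x$intercept, x$n_points, x$weighting, x$r_squared,
    x$lloq, x$uloq))
  invisible(x)
}

#' Back-calculate concentration from a response ratio
#'
#' Inverse evaluation of the calibration line:
#' `(ratio - intercept) / slope`. Values may be negative; BLQ policy is
#' the caller's decision (see [quantify()]).
#'
#' @param curve a [fit_calibration()] result.
#' @param ratio response ratio(s), analyte / internal standard.
#' @return concentration(s), ng/mL.
#' @export
back_calculate <- function(curve, ratio) {
  assert_that(inherits(curve, "calibration_curve"),
              "`curve` must be a calibration_curve")
  assert_that(curve$slope != 0, "calibration slope must be nonzero")
  (ratio - curve$intercept) / curve$slope
}

#' Back-calculation table for calibration standards
#'
#' Deviation of each standard's back-calculated concentration from
#' nominal, `(calculated - nominal)/nominal * 100`, judged against the
#' usual calibration acceptance rule: within 15%, relaxed to 20% at the
#' LLOQ level (the lowest nominal on the curve).
#'
#' @param curve a [fit_calibration()] result.
#' @param standards data.frame with `nominal`, `ratio`.
#' @param limit_pct,limit_pct_lloq acceptance limits, %.
#' @return data.frame: `nominal`, `calculated`, `deviation_pct`,
#'   `is_lloq`, `pass`.
#' @export
back_calc_table <- function(curve, standards, limit_pct = 15,
                            limit_pct_lloq = 20) {
  if (any(standards$nominal == 0))
    pk_stop("deviation undefined for nominal 0 in a calibration standard",
            "pkassay_undefined_deviation_error")
  calc <- back_calculate(curve, standards$ratio)
  dev <- (calc - standards$nominal) / standards$nominal * 100
  is_lloq <- standards$nominal == min(standards$nominal)
  limit <- ifelse(is_lloq, limit_pct_lloq, limit_pct)
  data.frame(nominal = standards$nominal, calculated = calc,
             deviation_pct = dev, is_lloq = is_lloq,
             pass = abs(dev) <= limit)
}

#' Quantify unknown samples against a fitted curve
#'
#' Back-calculates each row's response ratio and applies the dilution
#' factor. Measured (pre-dilution-correction) values below the curve's
#' LLOQ are flagged BLQ; values above the ULOQ are flagged above-ULOQ
#' (quantifiable only after dilution). Flags never abort.
#'
#' @param curve a [fit_calibration()] result.
#' @param unknowns plate data.frame rows to quantify.
#' @param dilution_factor dilution applied before measurement, >= 1.
#' @return `unknowns` with `calculated_ng_per_ml`, `blq`, `above_uloq`
#'   columns appended.
#' @export
quantify <- function(curve, unknowns, dilution_factor = 1) {
  assert_that(is_scalar_number(dilution_factor) && dilution_factor >= 1,
              "`dilution_factor` must be >= 1")
  assert_that(all(unknowns$is_response > 0), "IS responses must be positive")
  measured <- back_calculate(curve,
                             unknowns$analyte_response / unknowns$is_response)
  unknowns$calculated_ng_per_ml <- measured * dilution_factor
  unknowns$blq <- measured < curve$lloq
  unknowns$above_uloq <- measured > curve$uloq
  unknowns
}
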