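# S3 containers shared across modules.

#' Concentration-time profile for one subject
#'
#' The NCA input: one subject's plasma concentration measurements with
#' route and dose metadata and per-point BLQ (below the lower limit of
#' quantification) flags.
#'
#' @param subject_id subject label.
#' @param route `"iv_bolus"` or `"oral"`.
#' @param dose_per_kg administered dose, mg/kg.
#' @param body_weight body weight, kg (needed for absolute dose amounts).
#' @param time sampling times, min, strictly increasing.
#' @param conc concentrations, ng/mL, all >= 0.
#' @param blq logical BLQ flags, same length as `time`.
#' @return an object of class `conc_profile`.
#' @export
conc_profile <- function(subject_id, route, dose_per_kg, body_weight,
                         time, conc, blq = rep(FALSE, length(time))) {
  assert_that(route %in% c("iv_bolus", "oral"),
              "`route` must be 'iv_bolus' or 'oral'")
  assert_that(length(time) == length(conc) && length(time) == length(blq),
              "`time`, `conc` and `blq` must have equal length")
  assert_that(!is.unsorted(time, strictly = TRUE),
              "`time` must be strictly increasing")
  assert_that(all(conc >= 0), "`conc` must be non-negative")
  structure(
    list(subject_id = as.character(subject_id), route = route,
         dose_per_kg = dose_per_kg, body_weight = body_weight,
         time = as.numeric(time), conc = as.numeric(conc),
         blq = as.logical(blq)),
    class = "conc_profile"
  )
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s  %s  %g mg/kg x %g kg\n",
              x$subject_id, x$route, x$dose_per_kg, x$body_weight))
  print(data.frame(time_min = x$time, conc_ng_per_ml = x$conc, blq = x$blq),
        row.names = FALSE)
  invisible(x)
}

#' Uniformly sampled MRM chromatogram trace
#'
#' @param times acquisition times, min, strictly increasing and uniformly
#'   spaced (to a relative tolerance of 1e-6 of the spacing).
#' @param intensities detector intensities, same length as `times`.
#' @param channel length-2 numeric `(precursor m/z, product m/z)`.
#' @return an object of class `chromatogram_trace`.
#' @export
chromatogram_trace <- function(times, intensities, channel = c(NA_real_, NA_real_)) {
  assert_that(length(times) == length(intensities),
              "`times` and `intensities` must have equal length")
  assert_that(length(times) >= 2, "a trace needs at least 2 samples")
  dt <- diff(times)
  assert_that(all(dt > 0), "`times` must be strictly increasing")
  assert_that(max(dt) - min(dt) <= 1e-6 * stats::median(dt),
              "`times` must be uniformly spaced")
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         channel = as.numeric(channel)),
    class = "chromatogram_trace"
  )
}

#' @export
print.chromatogram_trace <- function(x, ...) {
  cat(sprintf(
    "<chromatogram_trace> channel %g -> %g m/z, %d samples over %.3g min\n",
    x$channel[1], x$channel[2], length(x$times),
    x$times[length(x$times)] - x$times[1]))
  invisible(x)
}
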