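# Peak integration and signal-to-noise estimation on MRM traces,
# supporting signal-to-noise based LLOQ determination.

in_window <- function(times, window) {
  times >= window[1] & times <= window[2]
}

check_window <- function(trace, window) {
  assert_that(is.numeric(window) && length(window) == 2 && window[1] < window[2],
              "`window` must be (t_start, t_end) with t_start < t_end")
  span <- range(trace$times)
  if (window[1] < span[1] || window[2] > span[2])
    pk_stop("integration window lies outside the trace time span",
            "pkassay_range_error")
}

#' Integrate one chromatographic peak
#'
#' Baseline is the mean intensity over flanking regions (by default, one
#' window-width on each side of `window`, clipped to the trace; explicit
#' regions can be supplied). The area is the trapezoidal integral of the
#' baseline-subtracted intensity, clipped at zero, over `window`; height
#' is the maximum baseline-subtracted intensity, apex time its time
#' (earliest on ties).
#'
#' @param trace a [chromatogram_trace].
#' @param window numeric `(t_start, t_end)`, min, inside the trace span,
#'   containing at least 3 samples.
#' @param baseline_windows optional list of `(t_start, t_end)` windows
#'   used for the baseline estimate instead of the automatic flanks.
#' @return a list of class `peak_result`: `area` (intensity x min),
#'   `height`, `apex_time`, `baseline_level`.
#' @export
integrate_peak <- function(trace, window, baseline_windows = NULL) {
  assert_that(inherits(trace, "chromatogram_trace"),
              "`trace` must be a chromatogram_trace")
  check_window(trace, window)
  sel <- in_window(trace$times, window)
  if (sum(sel) < 3)
    pk_stop("degenerate window: fewer than 3 samples inside `window`",
            "pkassay_degenerate_window_error")

  if (is.null(baseline_windows)) {
    w <- window[2] - window[1]
    baseline_windows <- list(c(window[1] - w, window[1]),
                             c(window[2], window[2] + w))
  }
  base_sel <- Reduce(`|`, lapply(baseline_windows, function(bw)
    in_window(trace$times, bw))) & !sel
  baseline <- if (any(base_sel)) mean(trace$intensities[base_sel]) else 0

  t <- trace$times[sel]
  y <- trace$intensities[sel] - baseline
  height <- max(y)
  if (height < 0) height <- 0
  apex_time <- t[which.max(y)]          # which.max takes the earliest tie
  structure(
    list(area = trapz(t, pmax(y, 0)), height = height,
         apex_time = apex_time, baseline_level = baseline),
    class = "peak_result"
  )
}

#' Estimate baseline noise from a signal-free region
#'
#' Returns the empirical SD (population convention, divisor n) of the
#' intensities inside `noise_window`, which must be disjoint from any
#' peak and contain at least 10 samples.
#'
#' @param trace a [chromatogram_trace].
#' @param noise_window numeric `(t_start, t_end)`, min.
#' @return noise SD in intensity units.
#' @export
estimate_noise <- function(trace, noise_window) {
  assert_that(inherits(trace, "chromatogram_trace"),
              "`trace` must be a chromatogram_trace")
  check_window(trace, noise_window)
  y <- trace$intensities[in_window(trace$times, noise_window)]
  if (length(y) < 10)
    pk_stop("noise window must contain at least 10 samples",
            "pkassay_insufficient_noise_window_error")
  sqrt(mean((y - mean(y))^2))
}

#' Signal-to-noise ratio of an integrated peak
#'
#' Peak-to-RMS convention: baseline-subtracted peak height divided by the
#' baseline noise SD. A noise estimate below `eps` raises a zero-noise
#' error rather than returning infinity.
#'
#' @param peak a `peak_result` from [integrate_peak()].
#' @param noise noise SD from [estimate_noise()], >= 0.
#' @param eps zero-noise floor, intensity units.
#' @return dimensionless S/N.
#' @export
signal_to_noise <- function(peak, noise, eps = 1e-8) {
  assert_that(inherits(peak, "peak_result"), "`peak` must be a peak_result")
  assert_that(is_scalar_number(noise) && noise >= 0, "`noise` must be >= 0")
  if (noise < eps)
    pk_stop("noise is zero (or below the configured floor); S/N undefined",
            "pkassay_zero_noise_error")
  peak$height / noise
}

#' Determine the LLOQ from signal-to-noise of low-level standards
#'
#' The LLOQ (lower limit of quantification) is the lowest nominal
#' concentration whose chromatographic peak reaches `threshold` in S/N
#' (default 10, the usual quantification-limit convention).
#'
#' @param nominals nominal concentrations, ng/mL (one per trace).
#' @param traces list of [chromatogram_trace] objects.
#' @param window peak integration window `(t_start, t_end)`, min.
#' @param noise_window signal-free window for noise estimation.
#' @param threshold required S/N, > 0.
#' @return lowest qualifying nominal concentration, ng/mL, with the
#'   per-standard S/N values attached as attribute `"snr"`.
#' @export
determine_lloq <- function(nominals, traces, window, noise_window,
                           threshold = 10) {
  assert_that(length(nominals) >= 1 && length(nominals) == length(traces),
              "need >= 1 standard and one trace per nominal")
  assert_that(is_scalar_number(threshold) && threshold > 0,
              "`threshold` must be > 0")
  ord <- order(nominals)
  snr <- vapply(traces, function(tr) {
    signal_to_noise(integrate_peak(tr, window),
                    estimate_noise(tr, noise_window))
  }, numeric(1))
  ok <- which(snr[ord] >= threshold)
  if (!length(ok))
    pk_stop(sprintf("no standard reaches S/N >= %g; LLOQ not established",
                    threshold),
            "pkassay_no_lloq_error")
  structure(nominals[ord][ok[1]], snr = stats::setNames(snr[ord], nominals[ord]))
}
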