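# Synthetic-data generator: one-compartment PK profiles, calibration/QC
# plates and MRM chromatograms with known ground truth, so every
# downstream stage is testable without instrument data.

#' Simulation configuration for plasma concentration-time profiles
#'
#' Describes a one-compartment simulation arm: IV bolus
#' (`C(t) = Dose/V * exp(-k t)`) or first-order oral absorption
#' (Bateman function). Doses are in mg/kg; the absolute dose amount is
#' `dose_per_kg * body_weight`, expressed in ng, so concentrations come
#' out in ng/mL when `V` is in mL. Measurement error is multiplicative
#' lognormal with coefficient of variation `error_cv`, median-preserving
#' (the noise-free curve is the median of the noisy draws; the mean is
#' inflated by `exp(sigma^2/2)` with `sigma^2 = log(1 + cv^2)`).
#'
#' @param route `"iv_bolus"` or `"oral"`.
#' @param dose_per_kg dose in mg/kg (defaults: 2 IV, 20 oral).
#' @param body_weight animal body weight in kg (default 0.02, an adult
#'   female BALB/c mouse).
#' @param V apparent volume of distribution, mL.
#' @param k first-order elimination rate constant, 1/min.
#' @param ka first-order absorption rate constant, 1/min (oral only;
#'   must differ from `k`).
#' @param f_abs absorbed fraction in (0, 1] (oral only).
#' @param schedule sampling times in min, strictly increasing, all > 0.
#' @param error_cv multiplicative lognormal CV as a fraction (0.05 = 5%).
#' @param n_subjects number of animals to simulate.
#' @param lloq assay lower limit of quantification, ng/mL; simulated
#'   values below it are flagged BLQ but the raw value is retained.
#' @param seed integer RNG seed; mandatory, every draw is reproducible.
#' @return an object of class `pk_sim_config`.
#' @export
pk_sim_config <- function(route = c("iv_bolus", "oral"),
                          dose_per_kg = if (route == "oral") 20 else 2,
                          body_weight = 0.02,
                          V = 14.4,
                          k = 0.014,
                          ka = NULL,
                          f_abs = NULL,
                          schedule = if (route == "oral")
                            c(15, 30, 60, 90, 120, 240) else
                            c(5, 15, 30, 60, 90, 120),
                          error_cv = 0.05,
                          n_subjects = 3,
                          lloq = 4,
                          seed) {
  route <- match.arg(route)
  assert_that(!missing(seed) && is_scalar_number(seed),
              "`seed` is mandatory and must be a single integer")
  assert_that(is_scalar_number(V) && V > 0, "`V` must be > 0")
  assert_that(is_scalar_number(k) && k > 0, "`k` must be > 0")
  assert_that(is_scalar_number(dose_per_kg) && dose_per_kg > 0,
              "`dose_per_kg` must be > 0")
  assert_that(is_scalar_number(body_weight) && body_weight > 0,
              "`body_weight` must be > 0")
  assert_that(is.numeric(schedule) && length(schedule) >= 1 &&
                all(schedule > 0) && !is.unsorted(schedule, strictly = TRUE),
              "`schedule` must be strictly increasing and positive")
  assert_that(is_scalar_number(error_cv) && error_cv >= 0,
              "`error_cv` must be >= 0")
  assert_that(is_scalar_number(n_subjects) && n_subjects >= 1,
              "`n_subjects` must be >= 1")
  if (route == "oral") {
    assert_that(is_scalar_number(ka) && ka > 0, "oral route needs `ka` > 0")
    assert_that(ka != k,
                "`ka` must differ from `k` (flip-flop degenerate case is not supported)")
    assert_that(is_scalar_number(f_abs) && f_abs > 0 && f_abs <= 1,
                "oral route needs `f_abs` in (0, 1]")
  }
  structure(
    list(route = route, dose_per_kg = dose_per_kg, body_weight = body_weight,
         V = V, k = k, ka = ka, f_abs = f_abs, schedule = schedule,
         error_cv = error_cv, n_subjects = as.integer(n_subjects),
         lloq = lloq, seed = as.integer(seed)),
    class = "pk_sim_config"
  )
}

# Absolute dose in ng: mg/kg * kg * 1e6 ng/mg.
dose_amount_ng <- function(dose_per_kg, body_weight) {
  dose_per_kg * body_weight * 1e6
}

#' Noise-free one-compartment concentration curves
#'
#' `conc_iv()` is the mono-exponential IV bolus curve; `conc_oral()` is the
#' Bateman function for first-order absorption with first-order
#' elimination. Both are the simulator's analytic ground truth and are
#' exported so tests and users can compare recovered parameters against
#' the truth.
#'
#' @param t time, min (vectorized).
#' @param dose_amount absolute dose, ng.
#' @param V apparent volume, mL.
#' @param k elimination rate constant, 1/min.
#' @param ka absorption rate constant, 1/min.
#' @param f_abs absorbed fraction.
#' @return concentrations in ng/mL.
#' @export
conc_iv <- function(t, dose_amount, V, k) {
  (dose_amount / V) * exp(-k * t)
}

#' @rdname conc_iv
#' @export
conc_oral <- function(t, dose_amount, V, k, ka, f_abs) {
  (f_abs * dose_amount * ka) / (V * (ka - k)) * (exp(-k * t) - exp(-ka * t))
}

simulate_profiles <- function(cfg, curve_fun) {
  dose <- dose_amount_ng(cfg$dose_per_kg, cfg$body_weight)
  withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_subjects), function(i) {
      true <- curve_fun(cfg$schedule, dose)
      conc <- true * lognormal_cv_noise(length(true), cfg$error_cv)
      conc_profile(
        subject_id = sprintf("%s_%02d", if (cfg$route == "oral") "PO" else "IV", i),
        route = cfg$route,
        dose_per_kg = cfg$dose_per_kg,
        body_weight = cfg$body_weight,
        time = cfg$schedule,
        conc = conc,
        blq = conc < cfg$lloq
      )
    })
  })
}

#' Simulate IV-bolus concentration-time profiles
#'
#' Draws `n_subjects` profiles from the one-compartment IV model
#' `C(t) = Dose/V * exp(-k t)` on the configured sampling schedule, with
#' per-point multiplicative lognormal error. Fixed seed gives
#' bit-identical output.
#'
#' @param cfg a [pk_sim_config()] with `route = "iv_bolus"`.
#' @return a list of [conc_profile] objects.
#' @export
simulate_iv_profile <- function(cfg) {
  assert_that(inherits(cfg, "pk_sim_config"), "`cfg` must be a pk_sim_config")
  assert_that(cfg$route == "iv_bolus",
              "simulate_iv_profile() requires route = 'iv_bolus'")
  simulate_profiles(cfg, function(t, dose) conc_iv(t, dose, cfg$V, cfg$k))
}

#' Simulate oral concentration-time profiles (Bateman model)
#'
#' @param cfg a [pk_sim_config()] with `route = "oral"`.
#' @return a list of [conc_profile] objects.
#' @export
simulate_oral_profile <- function(cfg) {
  assert_that(inherits(cfg, "pk_sim_config"), "`cfg` must be a pk_sim_config")
  assert_that(cfg$route == "oral",
              "simulate_oral_profile() requires route = 'oral'")
  simulate_profiles(cfg, function(t, dose)
    conc_oral(t, dose, cfg$V, cfg$k, cfg$ka, cfg$f_abs))
}

#' Simulate a calibration / QC plate
#'
#' Generates one plate of internal-standard-normalized wells. The
#' noise-free response ratio at nominal concentration `x` is
#' `slope * x + intercept` (defaults are the assay's validated line,
#' y = 0.0053 x - 0.0015 over 4-300 ng/mL). The IS response is drawn
#' around `is_nominal` with its own small CV; the analyte response is
#' `ratio * is_response` so that ratio noise and IS noise are both
#' represented in the raw columns.
#'
#' @param slope,intercept calibration line coefficients (ratio per
#'   ng/mL; ratio).
#' @param levels nominal concentrations, ng/mL, all > 0 (a `0` level is
#'   allowed only via `role = "zero"` wells, not here).
#' @param replicates wells per level, >= 1.
#' @param noise_cv multiplicative lognormal CV applied to the ratio.
#' @param seed integer RNG seed.
#' @param role plate role label for all wells (`cal`, `qc`, `stability`,
#'   `dilution`).
#' @param run_id run label.
#' @param condition condition label (e.g. `fresh`, `freeze_thaw`).
#' @param is_nominal nominal IS response, detector units.
#' @param is_cv CV of the IS response.
#' @return a data.frame in the plate schema: `role`,
#'   `nominal_ng_per_ml`, `analyte_response`, `is_response`, `run_id`,
#'   `condition`.
#' @export
simulate_calibration_plate <- function(slope = 0.0053, intercept = -0.0015,
                                       levels = c(4, 12, 75, 120, 150, 300),
                                       replicates = 1, noise_cv = 0, seed,
                                       role = "cal", run_id = "run1",
                                       condition = "fresh",
                                       is_nominal = 5e4, is_cv = 0.02) {
  assert_that(!missing(seed) && is_scalar_number(seed),
              "`seed` is mandatory and must be a single integer")
  assert_that(all(levels > 0), "all nominal `levels` must be positive")
  assert_that(is_scalar_number(replicates) && replicates >= 1,
              "`replicates` must be >= 1")
  assert_that(noise_cv >= 0, "`noise_cv` must be >= 0")
  nominal <- rep(levels, each = replicates)
  withr::with_seed(as.integer(seed), {
    ratio <- (slope * nominal + intercept) *
      lognormal_cv_noise(length(nominal), noise_cv)
    is_resp <- is_nominal * lognormal_cv_noise(length(nominal), is_cv)
  })
  data.frame(
    role = role,
    nominal_ng_per_ml = nominal,
    analyte_response = ratio * is_resp,
    is_response = is_resp,
    run_id = run_id,
    condition = condition,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for an MRM chromatogram channel
#'
#' A single MRM transition acquired as a uniformly sampled time-intensity
#' trace: one Gaussian peak on a flat baseline with i.i.d. Gaussian noise.
#' Default channel is the analyte transition m/z 425 -> 247; the internal
#' standard channel is 435 -> 339.
#'
#' @param channel length-2 numeric, precursor and product m/z.
#' @param retention_time peak apex, min.
#' @param peak_sigma Gaussian peak SD, min, > 0.
#' @param peak_height apex intensity above baseline, detector units.
#' @param baseline_noise_sd SD of the baseline noise, detector units.
#' @param sampling_interval acquisition spacing, min, > 0.
#' @param run_length total acquisition time, min, > `retention_time`.
#' @param seed integer RNG seed.
#' @return an object of class `chrom_sim_config`.
#' @export
chrom_sim_config <- function(channel = c(425, 247),
                             retention_time = 5.8,
                             peak_sigma = 0.05,
                             peak_height = 1000,
                             baseline_noise_sd = 5,
                             sampling_interval = 0.01,
                             run_length = 12,
                             seed) {
  assert_that(!missing(seed) && is_scalar_number(seed),
              "`seed` is mandatory and must be a single integer")
  assert_that(length(channel) == 2 && all(channel > 0),
              "`channel` must be (precursor m/z, product m/z)")
  assert_that(peak_sigma > 0, "`peak_sigma` must be > 0")
  assert_that(sampling_interval > 0, "`sampling_interval` must be > 0")
  assert_that(run_length > retention_time,
              "`run_length` must exceed `retention_time`")
  assert_that(baseline_noise_sd >= 0, "`baseline_noise_sd` must be >= 0")
  structure(
    list(channel = channel, retention_time = retention_time,
         peak_sigma = peak_sigma, peak_height = peak_height,
         baseline_noise_sd = baseline_noise_sd,
         sampling_interval = sampling_interval, run_length = run_length,
         seed = as.integer(seed)),
    class = "chrom_sim_config"
  )
}

#' Simulate an MRM chromatogram trace
#'
#' @param cfg a [chrom_sim_config()].
#' @return a [chromatogram_trace] with a Gaussian peak of height
#'   `peak_height` centred at `retention_time` plus i.i.d. baseline noise.
#' @export
simulate_chromatogram <- function(cfg) {
  assert_that(inherits(cfg, "chrom_sim_config"),
              "`cfg` must be a chrom_sim_config")
  times <- seq(0, cfg$run_length, by = cfg$sampling_interval)
  signal <- cfg$peak_height *
    exp(-(times - cfg$retention_time)^2 / (2 * cfg$peak_sigma^2))
  noise <- withr::with_seed(cfg$seed,
    stats::rnorm(length(times), sd = cfg$baseline_noise_sd))
  chromatogram_trace(times, signal + noise, channel = cfg$channel)
}
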