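# Bioanalytical validation statistics: accuracy, within/between-run
# precision, matrix factor, carryover, stability, dilution integrity,
# and the hydrolysis-step comparison; each judged against configurable
# acceptance thresholds.

#' Acceptance thresholds for validation statistics
#'
#' Two presets ship. `"paper"` reflects the assay's stated criteria: CV
#' of precision within 5%, accuracy 85-115% (80-120% at the LLOQ).
#' `"ema"` reflects the EMA bioanalytical guideline limits: CV within 15%
#' (20% at the LLOQ), accuracy 85-115% (80-120% at the LLOQ). The
#' statistic is always the same; only the judgment differs.
#'
#' @param preset `"paper"` or `"ema"`.
#' @param cv_max_pct,cv_max_pct_lloq maximum CV, %.
#' @param accuracy_low_pct,accuracy_high_pct accuracy bounds, %.
#' @param accuracy_lloq_low_pct,accuracy_lloq_high_pct LLOQ accuracy
#'   bounds, %.
#' @param carryover_max_frac_of_lloq blank analyte response must stay
#'   strictly below this fraction of the LLOQ sample response.
#' @param carryover_max_frac_of_is blank IS response must stay strictly
#'   below this fraction of the working IS response.
#' @param sd_convention `"population"` (divisor n) or `"sample"`
#'   (divisor n-1).
#' @param rounding_decimals half-up decimals used when reporting.
#' @return an object of class `acceptance_thresholds`.
#' @export
acceptance_thresholds <- function(preset = c("paper", "ema"),
                                  cv_max_pct = NULL,
                                  cv_max_pct_lloq = NULL,
                                  accuracy_low_pct = 85,
                                  accuracy_high_pct = 115,
                                  accuracy_lloq_low_pct = 80,
                                  accuracy_lloq_high_pct = 120,
                                  carryover_max_frac_of_lloq = 0.20,
                                  carryover_max_frac_of_is = 0.05,
                                  sd_convention = c("population", "sample"),
                                  rounding_decimals = 1) {
  preset <- match.arg(preset)
  sd_convention <- match.arg(sd_convention)
  if (is.null(cv_max_pct)) cv_max_pct <- if (preset == "ema") 15 else 5
  if (is.null(cv_max_pct_lloq))
    cv_max_pct_lloq <- if (preset == "ema") 20 else 5
  assert_that(accuracy_low_pct < accuracy_high_pct &&
                accuracy_lloq_low_pct < accuracy_lloq_high_pct,
              "accuracy bounds must satisfy low < high")
  assert_that(cv_max_pct > 0 && cv_max_pct_lloq > 0, "CV limits must be > 0")
  structure(
    list(preset = preset, cv_max_pct = cv_max_pct,
         cv_max_pct_lloq = cv_max_pct_lloq,
         accuracy_low_pct = accuracy_low_pct,
         accuracy_high_pct = accuracy_high_pct,
         accuracy_lloq_low_pct = accuracy_lloq_low_pct,
         accuracy_lloq_high_pct = accuracy_lloq_high_pct,
         carryover_max_frac_of_lloq = carryover_max_frac_of_lloq,
         carryover_max_frac_of_is = carryover_max_frac_of_is,
         sd_convention = sd_convention,
         rounding_decimals = rounding_decimals),
    class = "acceptance_thresholds"
  )
}

#' Mean, standard deviation and coefficient of variation
#'
#' The workhorse summary for every precision statistic. The SD divisor
#' is n (`"population"`) or n-1 (`"sample"`); the population convention
#' is the default because it reproduces the assay's printed triplicate
#' summaries. CV is SD/mean x 100.
#'
#' @param values numeric vector, length >= 2.
#' @param sd_convention `"population"` or `"sample"`.
#' @return list with `mean`, `sd`, `cv_pct`, `n`.
#' @export
mean_sd_cv <- function(values, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  n <- length(values)
  if (n < 2)
    pk_stop("need at least 2 replicates", "pkassay_insufficient_replicates_error")
  m <- mean(values)
  ss <- sum((values - m)^2)
  s <- sqrt(ss / if (sd_convention == "population") n else n - 1)
  if (m == 0)
    pk_stop("mean is zero; CV undefined", "pkassay_undefined_cv_error")
  list(mean = m, sd = s, cv_pct = s / m * 100, n = n)
}

#' Accuracy as percent of nominal
#'
#' `mean_calculated / nominal * 100`: the direction that reproduces the
#' assay's printed tables (e.g. determined 124.3 at nominal 120 gives
#' 103.6%).
#'
#' @param mean_calculated mean determined concentration, ng/mL.
#' @param nominal nominal concentration, ng/mL, > 0.
#' @return accuracy, %.
#' @export
accuracy_pct <- function(mean_calculated, nominal) {
  assert_that(all(nominal > 0), "`nominal` must be > 0",
              class = "pkassay_config_error")
  mean_calculated / nominal * 100
}

judge_level <- function(acc, cv, is_lloq, th) {
  lo <- if (is_lloq) th$accuracy_lloq_low_pct else th$accuracy_low_pct
  hi <- if (is_lloq) th$accuracy_lloq_high_pct else th$accuracy_high_pct
  cvmax <- if (is_lloq) th$cv_max_pct_lloq else th$cv_max_pct
  (acc >= lo && acc <= hi) && (cv <= cvmax)
}

precision_table <- function(qcs, thresholds, lloq_level) {
  levels <- sort(unique(qcs$nominal))
  rows <- lapply(levels, function(lv) {
    v <- qcs$calculated[qcs$nominal == lv]
    s <- mean_sd_cv(v, thresholds$sd_convention)
    acc <- accuracy_pct(s$mean, lv)
    is_lloq <- isTRUE(lv == lloq_level)
    data.frame(nominal = lv, n = s$n, mean = s$mean, sd = s$sd,
               accuracy_pct = acc, cv_pct = s$cv_pct, is_lloq = is_lloq,
               pass = judge_level(acc, s$cv_pct, is_lloq, thresholds))
  })
  do.call(rbind, rows)
}

#' Within-run precision and accuracy
#'
#' Per QC level: mean, SD, accuracy % and CV % over the replicates of a
#' single run, judged against the thresholds (the LLOQ level on its
#' wider accuracy bounds).
#'
#' @param qcs data.frame with `nominal`, `calculated` (ng/mL) and
#'   `run_id`; must contain exactly one run and >= 2 replicates per
#'   level.
#' @param thresholds an [acceptance_thresholds()].
#' @param lloq_level nominal concentration treated as the LLOQ level
#'   (default: the lowest level present).
#' @return data.frame, one row per level: `nominal`, `n`, `mean`, `sd`,
#'   `accuracy_pct`, `cv_pct`, `is_lloq`, `pass`.
#' @export
within_run <- function(qcs, thresholds = acceptance_thresholds(),
                       lloq_level = min(qcs$nominal)) {
  assert_that(length(unique(qcs$run_id)) == 1,
              "within_run() expects a single run_id; use between_run() across runs")
  precision_table(qcs, thresholds, lloq_level)
}

#' Between-run precision and accuracy
#'
#' Pools all replicates of each level across runs (>= 2 distinct runs)
#' and applies the same statistics as [within_run()].
#'
#' @inheritParams within_run
#' @return data.frame as in [within_run()].
#' @export
between_run <- function(qcs, thresholds = acceptance_thresholds(),
                        lloq_level = min(qcs$nominal)) {
  if (length(unique(qcs$run_id)) < 2)
    pk_stop("between_run() needs at least 2 distinct run_ids",
            "pkassay_insufficient_data_error")
  precision_table(qcs, thresholds, lloq_level)
}

#' Matrix factors and the IS-normalized matrix factor
#'
#' Matrix factor = peak area in the presence of matrix / peak area in
#' its absence, per species; the IS-normalized matrix factor is the
#' analyte's divided by the internal standard's, so common-mode ion
#' suppression cancels.
#'
#' @param analyte_in_matrix,analyte_in_solvent,is_in_matrix,is_in_solvent
#'   peak areas (> 0), vectorized elementwise over replicates.
#' @return list with `mf_analyte`, `mf_is`, `is_normalized_mf`.
#' @export
matrix_factor <- function(analyte_in_matrix, analyte_in_solvent,
                          is_in_matrix, is_in_solvent) {
  areas <- c(analyte_in_matrix, analyte_in_solvent, is_in_matrix, is_in_solvent)
  if (any(areas <= 0))
    pk_stop("all peak areas must be positive", "pkassay_config_error")
  mf_a <- analyte_in_matrix / analyte_in_solvent
  mf_is <- is_in_matrix / is_in_solvent
  list(mf_analyte = mf_a, mf_is = mf_is, is_normalized_mf = mf_a / mf_is)
}

#' Stability ratio
#'
#' Mean concentration measured after a storage/stress condition as a
#' percent of nominal, judged on the accuracy bounds.
#'
#' @param stressed_mean mean calculated concentration after stress, ng/mL.
#' @param nominal nominal concentration, ng/mL, > 0.
#' @return stability, %.
#' @export
stability_ratio <- function(stressed_mean, nominal) {
  accuracy_pct(stressed_mean, nominal)
}

#' Carryover check on a blank injected after the ULOQ sample
#'
#' Passes iff the blank's analyte response is strictly below
#' `carryover_max_frac_of_lloq` (default 20%) of the LLOQ sample's
#' analyte response AND the blank's IS response is strictly below
#' `carryover_max_frac_of_is` (default 5%) of the working IS response.
#'
#' @param blank_response_after_uloq analyte response in the post-ULOQ
#'   blank.
#' @param lloq_response analyte response of an LLOQ sample, > 0.
#' @param is_blank_response IS response in the blank.
#' @param is_response working IS response, > 0.
#' @param thresholds an [acceptance_thresholds()].
#' @return list: `pass`, `analyte_frac_of_lloq`, `is_frac_of_working`.
#' @export
carryover_check <- function(blank_response_after_uloq, lloq_response,
                            is_blank_response = 0, is_response = 1,
                            thresholds = acceptance_thresholds()) {
  assert_that(lloq_response > 0, "`lloq_response` must be > 0")
  fa <- blank_response_after_uloq / lloq_response
  fi <- is_blank_response / is_response
  list(pass = fa < thresholds$carryover_max_frac_of_lloq &&
         fi < thresholds$carryover_max_frac_of_is,
       analyte_frac_of_lloq = fa, is_frac_of_working = fi)
}

#' Dilution integrity
#'
#' Samples above the ULOQ are diluted into range and measured; the
#' dilution-corrected concentrations must meet the accuracy and CV
#' bounds at every nominal level.
#'
#' @param diluted_measurements data.frame with `nominal` (the original,
#'   pre-dilution concentration, ng/mL) and `measured` (in-range
#'   measured concentration, ng/mL).
#' @param dilution_factor factor the samples were diluted by, > 1.
#' @param nominal_levels levels that must be present (default 330, 500,
#'   700 ng/mL); a missing level is an error.
#' @param thresholds an [acceptance_thresholds()].
#' @param min_replicates replicates required per level (default 5).
#' @return data.frame, one row per level, as in [within_run()].
#' @export
dilution_integrity <- function(diluted_measurements, dilution_factor = 3,
                               nominal_levels = c(330, 500, 700),
                               thresholds = acceptance_thresholds(),
                               min_replicates = 5) {
  assert_that(dilution_factor > 1, "`dilution_factor` must be > 1")
  missing_lv <- setdiff(nominal_levels, unique(diluted_measurements$nominal))
  if (length(missing_lv))
    pk_stop(sprintf("missing dilution-integrity level(s): %s",
                    paste(missing_lv, collapse = ", ")),
            "pkassay_insufficient_data_error")
  counts <- table(diluted_measurements$nominal)
  if (any(counts < min_replicates))
    pk_stop(sprintf("each level needs >= %d replicates", min_replicates),
            "pkassay_insufficient_replicates_error")
  qcs <- data.frame(
    nominal = diluted_measurements$nominal,
    calculated = diluted_measurements$measured * dilution_factor)
  # dilution levels sit above the curve's LLOQ: no LLOQ-specific bounds
  precision_table(qcs, thresholds, lloq_level = NA_real_)
}

#' Compare sample preparation with and without alkaline hydrolysis
#'
#' Side-by-side mean/SD/CV summaries of replicate plasma concentrations
#' measured with and without the alkaline hydrolysis step, the
#' experiment that justifies hydrolysing steryl esters to free sterol
#' before extraction.
#'
#' @param with_hydrolysis,without_hydrolysis numeric vectors (>= 2
#'   values each), ng/mL.
#' @param sd_convention `"population"` or `"sample"`.
#' @return list of two [mean_sd_cv()] summaries, `with_hydrolysis` and
#'   `without_hydrolysis`.
#' @export
hydrolysis_comparison <- function(with_hydrolysis, without_hydrolysis,
                                  sd_convention = "population") {
  list(with_hydrolysis = mean_sd_cv(with_hydrolysis, sd_convention),
       without_hydrolysis = mean_sd_cv(without_hydrolysis, sd_convention))
}
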