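# Noncompartmental analysis: terminal slope, half-life, Cmax/Tmax,
# trapezoidal AUC/AUMC, MRT, Vd, Cl and absolute bioavailability.

# BLQ policy (standard NCA practice): BLQ points before Tmax are set to
# zero, BLQ points at/after Tmax are excluded.
nca_points <- function(profile) {
  t <- profile$time; c <- profile$conc; blq <- profile$blq
  if (!any(!blq))
    pk_stop("profile has no non-BLQ points", "pkassay_no_data_error")
  tmax <- t[!blq][which.max(c[!blq])]
  keep <- !blq | t < tmax
  c[blq & t < tmax] <- 0
  list(time = t[keep], conc = c[keep])
}

#' Observed Cmax and Tmax
#'
#' Maximum observed (non-BLQ) concentration and its time; ties broken by
#' the earliest time.
#'
#' @param profile a [conc_profile].
#' @return list with `c_max` (ng/mL) and `t_max` (min).
#' @export
cmax_tmax <- function(profile) {
  ok <- !profile$blq
  if (!any(ok))
    pk_stop("all points are BLQ; Cmax undefined", "pkassay_no_data_error")
  i <- which.max(profile$conc[ok])   # earliest on ties
  list(c_max = profile$conc[ok][i], t_max = profile$time[ok][i])
}

# Closed-form simple linear regression of y on x; adjusted R^2 for the
# single-predictor model.
loglin_fit <- function(t, logc) {
  fit <- stats::lm(logc ~ t)
  # adjusted R^2 from the residuals directly: summary.lm() warns on
  # perfect fits, which are routine on noise-free data
  n <- length(t)
  sst <- sum((logc - mean(logc))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

#' Fit the terminal elimination rate constant (lambda_z)
#'
#' Ordinary least squares of log concentration on time over a terminal
#' subset of the profile; lambda_z is the negated slope. Candidate
#' points are the non-BLQ, positive concentrations strictly after Tmax
#' (oral) or after the first sample (IV bolus). The default policy
#' searches all contiguous terminal subsets of >= 3 points ending at the
#' last point and keeps the one with the best adjusted R-squared (ties
#' go to more points); `"last3"` always uses the final three points.
#'
#' @param profile a [conc_profile].
#' @param selection_policy `"best_adj_r2"` or `"last3"`.
#' @return list: `lambda_z` (1/min), `n_points`, `adj_r2`,
#'   `t_first_used` (start of the regression window, min).
#' @export
fit_lambda_z <- function(profile, selection_policy = c("best_adj_r2", "last3")) {
  selection_policy <- match.arg(selection_policy)
  ok <- !profile$blq & profile$conc > 0
  t <- profile$time[ok]; c <- profile$conc[ok]
  if (profile$route == "oral") {
    tmax <- t[which.max(c)]
    cand <- t > tmax
  } else {
    cand <- seq_along(t) > 1
  }
  t <- t[cand]; c <- c[cand]
  n <- length(t)
  if (n < 3)
    pk_stop("fewer than 3 usable terminal points",
            "pkassay_insufficient_terminal_data_error")
  logc <- log(c)
  starts <- if (selection_policy == "last3") n - 2 else seq_len(n - 2)
  best <- NULL
  for (s in starts) {
    f <- loglin_fit(t[s:n], logc[s:n])
    if (f$slope >= 0) next
    f$n_points <- n - s + 1
    f$t_first <- t[s]
    # keep the better adjusted R^2; on (numerical) ties prefer more points
    if (is.null(best) || f$adj_r2 > best$adj_r2 + 1e-10 ||
        (abs(f$adj_r2 - best$adj_r2) <= 1e-10 && f$n_points > best$n_points))
      best <- f
  }
  if (is.null(best))
    pk_stop("no terminal subset with a negative slope: no elimination phase",
            "pkassay_no_elimination_phase_error")
  list(lambda_z = -best$slope, n_points = best$n_points,
       adj_r2 = best$adj_r2, t_first_used = best$t_first)
}

#' Terminal half-life
#'
#' `ln(2) / lambda_z` (at reported precision indistinguishable from the
#' 0.693/lambda_z convention).
#'
#' @param lambda_z terminal rate constant, 1/min, > 0.
#' @return half-life, min.
#' @export
half_life <- function(lambda_z) {
  assert_that(all(lambda_z > 0), "`lambda_z` must be > 0")
  log(2) / lambda_z
}

# Assemble the (time, conc) support for the trapezoids, applying the
# time-zero convention: oral curves start at (0, 0); IV bolus curves are
# back-extrapolated to C(0) = exp(intercept) of the log-linear line
# through the first two observed points when it declines, else (or with
# c0_method = "first_obs") C(0) = the first observed concentration.
auc_support <- function(profile, c0_method = c("backextrapolate", "first_obs")) {
  c0_method <- match.arg(c0_method)
  p <- nca_points(profile)
  t <- p$time; c <- p$conc
  if (length(t) < 2)
    pk_stop("need at least 2 points for a trapezoidal integral",
            "pkassay_insufficient_data_error")
  if (t[1] > 0) {
    if (profile$route == "oral") {
      t <- c(0, t); c <- c(0, c)
    } else {
      c0 <- c[1]   # "first_obs": constant back-extrapolation
      if (c0_method == "backextrapolate" && c[1] > c[2] && c[2] > 0) {
        f <- loglin_fit(t[1:2], log(c[1:2]))
        c0 <- exp(f$intercept)
      }
      t <- c(0, t); c <- c(c0, c)
    }
  }
  list(time = t, conc = c)
}

trapz_to <- function(t, y, t_end) {
  if (t_end > t[length(t)] + 1e-9)
    pk_stop("`t_end` exceeds the last observed time", "pkassay_range_error")
  keep <- t <= t_end
  tt <- t[keep]; yy <- y[keep]
  if (t_end > tt[length(tt)]) {   # linear interpolation at t_end
    y_end <- stats::approx(t, y, xout = t_end)$y
    tt <- c(tt, t_end); yy <- c(yy, y_end)
  }
  trapz(tt, yy)
}

#' Trapezoidal AUC from time zero to t
#'
#' Linear-trapezoidal area under the concentration-time curve up to
#' `t_end` (default: last observation). Oral profiles are prepended with
#' (0, 0); IV bolus profiles are back-extrapolated to C(0) (see
#' [auc_support()] conventions).
#'
#' @param profile a [conc_profile].
#' @param t_end upper limit, min, <= last observed time.
#' @param c0_method `"backextrapolate"` or `"first_obs"` (IV only).
#' @return AUC0-t, ng x min/mL.
#' @export
auc_trapezoid <- function(profile, t_end = NULL,
                          c0_method = c("backextrapolate", "first_obs")) {
  s <- auc_support(profile, c0_method)
  if (is.null(t_end)) t_end <- s$time[length(s$time)]
  trapz_to(s$time, s$conc, t_end)
}

#' Trapezoidal AUMC from time zero to t
#'
#' Linear-trapezoidal area under the first-moment curve `t * C(t)`, with
#' the same time-zero conventions as [auc_trapezoid()].
#'
#' @inheritParams auc_trapezoid
#' @return AUMC0-t, ng x min^2/mL.
#' @export
aumc_trapezoid <- function(profile, t_end = NULL,
                           c0_method = c("backextrapolate", "first_obs")) {
  s <- auc_support(profile, c0_method)
  if (is.null(t_end)) t_end <- s$time[length(s$time)]
  trapz_to(s$time, s$time * s$conc, t_end)
}

#' Mean residence time
#'
#' `AUMC0-t / AUC0-t`.
#'
#' @param auc_0_t AUC0-t, ng x min/mL, > 0.
#' @param aumc_0_t AUMC0-t, ng x min^2/mL.
#' @return MRT0-t, min.
#' @export
mrt <- function(auc_0_t, aumc_0_t) {
  assert_that(all(auc_0_t > 0), "`auc_0_t` must be > 0")
  aumc_0_t / auc_0_t
}

#' Volume of distribution and clearance (IV bolus)
#'
#' `"standard"` convention: `Vd = Dose / (lambda_z * AUC0-t)`;
#' `"auc_inf"` uses the AUC extrapolated to infinity
#' (`AUC0-t + Clast/lambda_z`) instead. Either way
#' `Cl = lambda_z * Vd` holds identically. The absolute dose amount is
#' `dose_per_kg * body_weight` in ng, so Vd is in mL and Cl in mL/min.
#'
#' @param profile an IV-bolus [conc_profile] with dose and body weight.
#' @param lambda_z terminal rate constant, 1/min.
#' @param auc_0_t AUC0-t, ng x min/mL.
#' @param convention `"standard"` or `"auc_inf"`.
#' @return list: `vd` (mL), `cl` (mL/min), `auc_used` (ng x min/mL).
#' @export
vd_cl <- function(profile, lambda_z, auc_0_t,
                  convention = c("standard", "auc_inf")) {
  convention <- match.arg(convention)
  if (profile$route != "iv_bolus")
    pk_stop("Vd/Cl from plasma data apply to the IV bolus route only",
            "pkassay_not_applicable_error")
  assert_that(is_scalar_number(profile$body_weight) && profile$body_weight > 0,
              "profile lacks a usable body weight; dose amount not computable")
  assert_that(lambda_z > 0 && auc_0_t > 0, "`lambda_z` and `auc_0_t` must be > 0")
  dose <- dose_amount_ng(profile$dose_per_kg, profile$body_weight)
  auc_used <- auc_0_t
  if (convention == "auc_inf") {
    p <- nca_points(profile)
    clast <- p$conc[max(which(p$conc > 0))]
    auc_used <- auc_0_t + clast / lambda_z
  }
  vd <- dose / (lambda_z * auc_used)
  list(vd = vd, cl = lambda_z * vd, auc_used = auc_used)
}

#' Absolute oral bioavailability
#'
#' Dose-corrected oral AUC over dose-corrected IV AUC, as a percent:
#' `(auc_oral/dose_oral) / (auc_iv/dose_iv) * 100`. Doses may be in any
#' common unit (mg/kg is fine when the routes share body weights).
#'
#' @param auc_oral,auc_iv AUCs, ng x min/mL, > 0.
#' @param dose_oral_per_kg,dose_iv_per_kg doses, mg/kg, > 0.
#' @return F, %.
#' @export
bioavailability <- function(auc_oral, dose_oral_per_kg, auc_iv,
                            dose_iv_per_kg) {
  assert_that(all(c(auc_oral, dose_oral_per_kg, auc_iv, dose_iv_per_kg) > 0),
              "all AUCs and doses must be > 0")
  (auc_oral / dose_oral_per_kg) / (auc_iv / dose_iv_per_kg) * 100
}

#' Full noncompartmental analysis of one profile
#'
#' Runs Cmax/Tmax, the lambda_z fit, half-life, AUC0-t, AUMC0-t, MRT0-t
#' and (IV only) Vd and Cl. Oral bioavailability needs an IV reference
#' and is computed in [summarize_nca()] / [cmd_nca()].
#'
#' @param profile a [conc_profile].
#' @param lambda_z_policy see [fit_lambda_z()].
#' @param auc_convention see [vd_cl()].
#' @param c0_method see [auc_trapezoid()].
#' @return an object of class `nca_result`.
#' @export
run_nca <- function(profile, lambda_z_policy = "best_adj_r2",
                    auc_convention = "standard",
                    c0_method = "backextrapolate") {
  ct <- cmax_tmax(profile)
  lz <- fit_lambda_z(profile, lambda_z_policy)
  auc <- auc_trapezoid(profile, c0_method = c0_method)
  aumc <- aumc_trapezoid(profile, c0_method = c0_method)
  res <- list(subject_id = profile$subject_id, route = profile$route,
              dose_per_kg = profile$dose_per_kg,
              lambda_z = lz$lambda_z, lambda_z_points = lz$n_points,
              lambda_z_adj_r2 = lz$adj_r2,
              t_half = half_life(lz$lambda_z),
              c_max = ct$c_max, t_max = ct$t_max,
              auc_0_t = auc, aumc_0_t = aumc, mrt_0_t = mrt(auc, aumc),
              vd = NA_real_, cl = NA_real_, f_pct = NA_real_)
  if (profile$route == "iv_bolus") {
    vc <- vd_cl(profile, lz$lambda_z, auc, auc_convention)
    res$vd <- vc$vd
    res$cl <- vc$cl
  }
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s (%s, %g mg/kg)\n", x$subject_id, x$route,
              x$dose_per_kg))
  cat(sprintf("  lambda_z %.4g /min (%d pts, adj R^2 %.4f), T1/2 %.4g min\n",
              x$lambda_z, x$lambda_z_points, x$lambda_z_adj_r2, x$t_half))
  cat(sprintf("  Cmax %.4g ng/mL at %g min; AUC0-t %.6g, MRT0-t %.4g min\n",
              x$c_max, x$t_max, x$auc_0_t, x$mrt_0_t))
  if (!is.na(x$vd))
    cat(sprintf("  Vd %.4g mL, Cl %.4g mL/min\n", x$vd, x$cl))
  invisible(x)
}

nca_param_names <- c("lambda_z", "t_half", "t_max", "c_max", "auc_0_t",
                     "aumc_0_t", "mrt_0_t", "vd", "cl", "f_pct")

#' Summarize NCA results across subjects
#'
#' Arithmetic mean and SD of each parameter over subjects of one route
#' (mixing routes is an error; summaries are reported per route).
#'
#' @param results list of `nca_result` objects (>= 2 subjects).
#' @param sd_convention `"population"` or `"sample"` (default sample:
#'   across-animal variability is the usual between-subject estimate).
#' @return data.frame: `parameter`, `route`, `n`, `mean`, `sd`.
#' @export
summarize_nca <- function(results, sd_convention = "sample") {
  assert_that(length(results) >= 2, "need >= 2 subjects to summarize")
  routes <- unique(vapply(results, `[[`, character(1), "route"))
  if (length(routes) > 1)
    pk_stop("cannot summarize mixed routes; split by route first",
            "pkassay_config_error")
  rows <- lapply(nca_param_names, function(p) {
    v <- vapply(results, function(r) r[[p]] %||% NA_real_, numeric(1))
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NULL)
    s <- mean_sd_cv(v, sd_convention)
    data.frame(parameter = p, route = routes, n = s$n, mean = s$mean,
               sd = s$sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
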