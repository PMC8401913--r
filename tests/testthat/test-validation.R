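# Printed triplicates from the hydrolysis-comparison experiment
# (concentration at 30 min after oral dosing, with/without hydrolysis).
hydro <- list(
  without_40 = c(108, 115, 130), with_40 = c(123, 118, 121),
  without_20 = c(64, 58, 67), with_20 = c(77, 74, 80))

test_that("mean_sd_cv reproduces the printed triplicate summaries", {
  printed <- list(without_40 = c(118, 9, 8), with_40 = c(121, 2, 2),
                  without_20 = c(63, 4, 6), with_20 = c(77, 2, 3))
  for (nm in names(hydro)) {
    s <- mean_sd_cv(hydro[[nm]], "population")
    expect_equal(round_half_up(c(s$mean, s$sd, s$cv_pct)), printed[[nm]])
  }
  s <- mean_sd_cv(c(7, 7, 7))
  expect_equal(s$sd, 0); expect_equal(s$cv_pct, 0)
  expect_error(mean_sd_cv(5), class = "pkassay_insufficient_replicates_error")
  expect_error(mean_sd_cv(c(-1, 1)), class = "pkassay_undefined_cv_error")
})

test_that("mean_sd_cv matches the two-pass oracle; population <= sample SD", {
  set.seed(13)
  for (i in 1:20) {
    v <- rlnorm(sample(2:12, 1), meanlog = 3, sdlog = 0.4)
    o <- msc_oracle(v, population = TRUE)
    s <- mean_sd_cv(v, "population")
    expect_equal(c(s$mean, s$sd, s$cv_pct), unname(o), tolerance = 1e-12)
    ss <- mean_sd_cv(v, "sample")
    expect_equal(ss$sd, msc_oracle(v, FALSE)[["sd"]], tolerance = 1e-12)
    expect_lte(s$sd, ss$sd)
  }
  expect_equal(mean_sd_cv(c(4, 4), "population")$sd,
               mean_sd_cv(c(4, 4), "sample")$sd)
})

test_that("accuracy and CV are scale invariant", {
  set.seed(29)
  for (i in 1:10) {
    v <- rlnorm(6, 4, 0.1); nominal <- 50; c <- runif(1, 0.1, 40)
    expect_equal(accuracy_pct(mean(v), nominal),
                 accuracy_pct(mean(c * v), c * nominal), tolerance = 1e-12)
    expect_equal(mean_sd_cv(v)$cv_pct, mean_sd_cv(c * v)$cv_pct,
                 tolerance = 1e-12)
  }
})

test_that("accuracy_pct reproduces the printed precision-table cells", {
  expect_equal(round_half_up(accuracy_pct(124.3, 120), 1), 103.6)
  expect_equal(round_half_up(accuracy_pct(233.0, 230), 1), 101.3)
  expect_equal(round_half_up(accuracy_pct(4.5, 4), 1), 112.5)  # within-run LLOQ prints 111.9 from unrounded mean
  expect_equal(accuracy_pct(88, 88), 100)
  expect_error(accuracy_pct(10, 0), class = "pkassay_config_error")
})

test_that("within_run judges each level, LLOQ on its own bounds", {
  th <- acceptance_thresholds("paper")
  # means match the printed within-run table; small spreads keep CV < 5%
  qcs <- data.frame(
    nominal = rep(c(4, 10, 120, 230), each = 3),
    calculated = c(4.45, 4.50, 4.48, 9.80, 9.75, 9.85,
                   124.0, 124.3, 124.6, 232.0, 233.0, 234.0),
    run_id = "run1")
  tab <- within_run(qcs, th)
  expect_equal(tab$nominal, c(4, 10, 120, 230))
  expect_equal(tab$is_lloq, c(TRUE, FALSE, FALSE, FALSE))
  # 111-112% at the LLOQ passes only through the 80-120 LLOQ bounds
  expect_gt(tab$accuracy_pct[1], 110)
  expect_true(all(tab$pass))

  # a level whose CV exceeds the 5% limit fails
  bad <- data.frame(nominal = rep(120, 3),
                    calculated = c(110, 120, 130), run_id = "run1")
  expect_false(within_run(bad, th, lloq_level = 4)$pass)

  expect_error(within_run(data.frame(nominal = 10, calculated = 10,
                                     run_id = "r1"), th),
               class = "pkassay_insufficient_replicates_error")
  expect_error(within_run(rbind(qcs, transform(qcs, run_id = "run2")), th),
               class = "pkassay_config_error")
})

test_that("between_run pools replicates across runs and matches the concatenation oracle", {
  set.seed(41)
  qcs <- data.frame(
    nominal = rep(rep(c(4, 120), each = 3), times = 3),
    calculated = c(rlnorm(3, log(4.4), 0.02), rlnorm(3, log(125), 0.02),
                   rlnorm(3, log(4.6), 0.02), rlnorm(3, log(126), 0.02),
                   rlnorm(3, log(4.5), 0.02), rlnorm(3, log(127), 0.02)),
    run_id = rep(c("d1", "d2", "d3"), each = 6))
  tab <- between_run(qcs)
  for (lv in c(4, 120)) {
    o <- msc_oracle(qcs$calculated[qcs$nominal == lv])
    row <- tab[tab$nominal == lv, ]
    expect_equal(row$mean, o[["mean"]], tolerance = 1e-12)
    expect_equal(row$cv_pct, o[["cv"]], tolerance = 1e-12)
    expect_equal(row$n, 9)
  }
  # printed between-run cell: pooled mean 125.7 at nominal 120 -> 104.8%
  expect_equal(round_half_up(accuracy_pct(125.7, 120), 1), 104.8)

  expect_error(between_run(qcs[qcs$run_id == "d1", ]),
               class = "pkassay_insufficient_data_error")
  # identical runs: pooled CV equals the single-run CV
  one <- qcs[qcs$run_id == "d1", ]
  dup <- rbind(one, transform(one, run_id = "d2"))
  expect_equal(between_run(dup)$cv_pct, within_run(one)$cv_pct,
               tolerance = 1e-12)
})

test_that("matrix factors divide matrix by solvent areas and normalize by the IS", {
  expect_equal(matrix_factor(100, 100, 100, 100),
               list(mf_analyte = 1, mf_is = 1, is_normalized_mf = 1))
  # common-mode suppression cancels in the IS-normalized factor
  expect_equal(matrix_factor(90, 100, 90, 100)$is_normalized_mf, 1)
  mf <- matrix_factor(90, 100, 80, 100)
  expect_equal(mf$mf_analyte, 0.9)
  expect_equal(mf$mf_is, 0.8)
  expect_equal(mf$is_normalized_mf, 1.125)
  expect_error(matrix_factor(90, 0, 80, 100), class = "pkassay_config_error")
})

test_that("stability ratios reproduce the printed stability accuracies", {
  expect_equal(round_half_up(stability_ratio(228.1, 230), 1), 99.2)
  expect_equal(round_half_up(stability_ratio(125.2, 120), 1), 104.3)
  expect_equal(round_half_up(stability_ratio(258.8, 230), 1), 112.5)
  expect_equal(stability_ratio(55, 55), 100)
})

test_that("carryover uses strict inequalities at both limits", {
  th <- acceptance_thresholds()
  expect_true(carryover_check(0, 1000, 0, 1e5, th)$pass)
  expect_false(carryover_check(250, 1000, 0, 1e5, th)$pass)  # 25% of LLOQ
  expect_false(carryover_check(200, 1000, 0, 1e5, th)$pass)  # exactly 20%
  expect_true(carryover_check(199.99, 1000, 0, 1e5, th)$pass)
  expect_false(carryover_check(0, 1000, 5000, 1e5, th)$pass) # IS exactly 5%
})

test_that("dilution integrity corrects by the factor and enforces replicates", {
  th <- acceptance_thresholds()
  exact <- data.frame(nominal = rep(c(330, 500, 700), each = 5),
                      measured = rep(c(110, 500 / 3, 700 / 3), each = 5))
  tab <- dilution_integrity(exact, 3, thresholds = th)
  expect_equal(tab$accuracy_pct, rep(100, 3), tolerance = 1e-9)
  expect_equal(tab$cv_pct, rep(0, 3))
  expect_true(all(tab$pass))

  expect_error(dilution_integrity(exact[exact$nominal != 500, ], 3),
               class = "pkassay_insufficient_data_error")
  expect_error(dilution_integrity(exact[-1, ], 3),
               class = "pkassay_insufficient_replicates_error")

  # CV agrees with the shared statistic on the corrected values
  set.seed(55)
  noisy <- transform(exact, measured = measured * exp(rnorm(15, 0, 0.02)))
  tab <- dilution_integrity(noisy, 3, thresholds = th)
  for (lv in c(330, 500, 700)) {
    v <- noisy$measured[noisy$nominal == lv] * 3
    expect_equal(tab$cv_pct[tab$nominal == lv], mean_sd_cv(v)$cv_pct,
                 tolerance = 1e-12)
  }
})

test_that("hydrolysis_comparison mirrors the printed side-by-side summaries", {
  cmp <- hydrolysis_comparison(hydro$with_40, hydro$without_40)
  expect_equal(round_half_up(cmp$with_hydrolysis$mean), 121)
  expect_equal(round_half_up(cmp$without_hydrolysis$cv_pct), 8)
  cmp20 <- hydrolysis_comparison(hydro$with_20, hydro$without_20)
  expect_equal(round_half_up(c(cmp20$without_hydrolysis$mean,
                               cmp20$without_hydrolysis$sd,
                               cmp20$without_hydrolysis$cv_pct)), c(63, 4, 6))
  eq <- hydrolysis_comparison(c(5, 6), c(5, 6))
  expect_identical(eq$with_hydrolysis, eq$without_hydrolysis)
  expect_error(hydrolysis_comparison(5, c(5, 6)),
               class = "pkassay_insufficient_replicates_error")
})

test_that("threshold presets separate statistic from judgment", {
  paper <- acceptance_thresholds("paper")
  ema <- acceptance_thresholds("ema")
  expect_equal(paper$cv_max_pct, 5); expect_equal(ema$cv_max_pct, 15)
  qcs <- data.frame(nominal = rep(120, 6),
                    calculated = 120 * exp(seq(-0.12, 0.13, length.out = 6)),
                    run_id = "r1")  # CV ~ 9%: fails paper, passes ema
  tp <- within_run(qcs, paper, lloq_level = 4)
  te <- within_run(qcs, ema, lloq_level = 4)
  expect_equal(tp$cv_pct, te$cv_pct)       # same statistic
  expect_false(tp$pass); expect_true(te$pass)
})
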