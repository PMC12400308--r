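test_that("linearity on a noiseless line is an exact identity", {
  x <- seq(0.5e-5, 5e-5, length.out = 10)
  cal <- calibration_series(x, 2.56e10 * x + 8.48e3)
  lin <- fit_linearity(cal)
  expect_equal(lin$slope, 2.56e10, tolerance = 1e-12)
  expect_equal(lin$intercept, 8.48e3, tolerance = 1e-9)
  expect_equal(lin$se_slope, 0, tolerance = 1e-6)
  expect_equal(lin$correlation, 1, tolerance = 1e-12)
})

test_that("noisy linearity estimates agree with the sum-formula oracle", {
  cal <- generate_calibration(synthetic_config(seed = 42))
  lin <- fit_linearity(cal)
  o <- ols_oracle(cal$nominal_concs, cal$responses)
  expect_equal(lin$slope, o$slope, tolerance = 1e-12)
  expect_equal(lin$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(lin$se_slope, o$se_slope, tolerance = 1e-12)
  expect_equal(lin$se_intercept, o$se_intercept, tolerance = 1e-12)
  # within 3 SE of the generating parameters
  expect_lt(abs(lin$slope - 2.56e10), 3 * lin$se_slope)
  expect_lt(abs(lin$intercept - 8.48e3), 3 * lin$se_intercept)
})

test_that("ICH limits follow 3.3 and 10 sigma over slope", {
  expect_equal(lod(1.35e4, 1.68e10), 2.65e-6, tolerance = 1e-3)
  expect_equal(loq(1.25e4, 2.56e10), 4.88e-6, tolerance = 1e-3)
  expect_equal(lod(0, 1e10), 0)
  expect_equal(loq(0, 1e10), 0)
  # loq/lod = 10/3.3 exactly, for any inputs
  for (sd in c(1, 5e3, 1.35e4)) {
    l <- ich_limits(sd, 2e10)
    expect_equal(l$loq / l$lod, 10 / 3.3, tolerance = 1e-14)
  }
  expect_error(lod(1e4, 0), "positive")
})

test_that("published alpha and gamma limits recompute; beta is flagged", {
  ck <- check_ich_consistency()
  expect_true(ck$lod_consistent[ck$cd_type == "alpha"])
  expect_true(ck$lod_consistent[ck$cd_type == "gamma"])
  expect_true(ck$loq_consistent[ck$cd_type == "gamma"])
  # 3 significant figures on the recomputed alpha/gamma values
  expect_equal(signif(ck$lod_recomputed[ck$cd_type == "alpha"], 3), 2.65e-6)
  expect_equal(signif(ck$lod_recomputed[ck$cd_type == "gamma"], 3), 1.61e-6)
  expect_equal(signif(ck$loq_recomputed[ck$cd_type == "gamma"], 3), 4.88e-6)
  # beta's printed sigma/slope pair cannot reproduce its printed limits
  expect_false(ck$lod_consistent[ck$cd_type == "beta"])
  expect_match(ck$flag[ck$cd_type == "beta"], "inconsistent")
  # alpha's printed LOQ (8.40e-6) also disagrees with 10 sigma/S (8.04e-6)
  expect_false(ck$loq_consistent[ck$cd_type == "alpha"])
})

test_that("accuracy and precision use recovery means and sample SD", {
  ap <- accuracy_precision(c(98, 100, 102), 100)
  expect_equal(ap$accuracy_percent, 100)
  expect_equal(ap$accuracy_sd, 2)
  expect_equal(ap$precision_rsd, 2)
  ap0 <- accuracy_precision(rep(7, 3), 7)
  expect_equal(ap0$accuracy_percent, 100)
  expect_equal(ap0$precision_rsd, 0)
  expect_error(accuracy_precision(5, 5), "at least 2")
  expect_error(accuracy_precision(c(1, 2), 0), "positive")
})

test_that("the validation report assembles sigma from replicate curves", {
  cal <- generate_calibration(synthetic_config(seed = 1), replicates = 5)
  rep_ <- validation_report(cal)
  expect_equal(rep_$sigma_source, "replicate curves")
  expect_equal(rep_$loq / rep_$lod, 10 / 3.3, tolerance = 1e-12)
  expect_gt(rep_$accuracy_percent, 90)
  expect_lt(rep_$accuracy_percent, 110)

  # supplied sigma propagates to the published gamma limits
  rep2 <- validation_report(cal, sd_intercept = 1.25e4)
  expect_equal(rep2$lod, 3.3 * 1.25e4 / rep2$linearity$slope, tolerance = 1e-12)

  # without replicates the OLS SE stands in, flagged
  cal1 <- generate_calibration(synthetic_config(seed = 2), replicates = 1)
  rep3 <- validation_report(cal1)
  expect_match(rep3$sigma_source, "no replicate curves")
})

test_that("calibration invariants are enforced", {
  expect_error(calibration_series(c(1, 2, 3, 4) * 1e-5, 1:4), "5 distinct")
  expect_error(calibration_series(c(1, 2, 3, 4, 5) * 1e-5, c(1, 2, 3, 4, NA)),
               "non-finite")
})
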