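test_that("an exact exponential is fit perfectly", {
  t <- seq(0, 500, 100)
  tc <- time_course(t, 120 * exp(-2e-3 * t))
  fit <- fit_first_order(tc)
  expect_equal(fit$k, 2e-3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict(fit, t), tc$responses, tolerance = 1e-10)
})

test_that("constant responses give k = 0 with zero standard error", {
  fit <- fit_first_order(time_course(0:5, rep(50, 6)))
  expect_equal(fit$k, 0)
  expect_equal(fit$se_k, 0)
  expect_equal(fit$r_squared, 1)
})

test_that("time-course invariants are enforced with informative errors", {
  expect_error(time_course(c(0, 10), c(1, 2)), "at least 3 points")
  expect_error(time_course(c(0, 10, 5), c(1, 2, 3)), "strictly increasing")
  expect_error(time_course(c(0, 10, 20), c(1, -2, 3)), "non-positive response")
  expect_error(time_course(c(-1, 10, 20), c(1, 2, 3)), "negative sampling time")
})

test_that("noisy rate recovery agrees with a brute-force SSE scan", {
  cfg <- synthetic_config(seed = 42, noise_cv = 0.02, k0_by_pH = c("6" = 2.11e-3))
  tc <- generate_time_course(cfg, 6)
  fit <- fit_first_order(tc)
  expect_lt(abs(fit$k - 2.11e-3), 3 * fit$se_k)
  k_scan <- rate_scan_oracle(tc$times, tc$responses, 1e-3, 4e-3)
  expect_equal(fit$k, k_scan, tolerance = 1e-7)
})

test_that("OLS estimates match the closed-form sum-formula oracle", {
  set.seed(99)
  for (i in 1:5) {
    x <- sort(runif(8, 0, 10))
    y <- 3 - 0.4 * x + rnorm(8, 0, 0.3)
    o <- ols_oracle(x, y)
    tc <- time_course(x, exp(y))
    fit <- fit_first_order(tc)
    expect_equal(fit$k, -o$slope, tolerance = 1e-12)
    expect_equal(fit$ln_intercept, o$intercept, tolerance = 1e-12)
    expect_equal(fit$se_k, o$se_slope, tolerance = 1e-12)

    ifit <- fit_interaction(x * 1e-4, y + 5)
    o2 <- ols_oracle(x * 1e-4, y + 5)
    expect_equal(ifit$k2, -o2$slope, tolerance = 1e-12)
    expect_equal(ifit$se_k2, o2$se_slope, tolerance = 1e-12)
  }
})

test_that("reference kobs rows reproduce the published interaction constants", {
  tab <- fu_rate_table()
  pick <- function(ph, cd) tab[tab$ph == ph & tab$cd_type == cd, ]
  g12 <- pick(12, "gamma")
  expect_equal(round(fit_interaction(g12$cd_conc_M, g12$kobs_per_min)$k2, 2), 2.14)
  a2 <- pick(2, "alpha")
  expect_equal(round(fit_interaction(a2$cd_conc_M, a2$kobs_per_min)$k2, 2), 0.49)
  b12 <- pick(12, "beta")
  expect_equal(round(fit_interaction(b12$cd_conc_M, b12$kobs_per_min)$k2, 2), 1.47)
})

test_that("constant kobs gives k2 = 0 and duplicates are rejected", {
  fit <- fit_interaction(c(1, 2, 3) * 1e-3, rep(2.5e-3, 3))
  expect_equal(fit$k2, 0)
  expect_equal(fit$k_at_zero_cd, 2.5e-3)
  expect_error(fit_interaction(c(1, 1, 2) * 1e-3, c(1, 2, 3) * 1e-3), "singular")
  expect_error(fit_interaction(c(1e-3, 2e-3), c(1e-3, 2e-3)), "at least 3")
})

test_that("noiseless synthetic grid round-trips (k0, k2) exactly", {
  cfg <- synthetic_config(noise_cv = 0)
  for (cd in c("alpha", "beta", "gamma")) {
    ks <- vapply(cfg$cd_concs, function(cc)
      fit_first_order(generate_time_course(cfg, 9, cd, cc))$k, numeric(1))
    ifit <- fit_interaction(cfg$cd_concs, ks, 9, cd)
    expect_equal(ifit$k2, unname(cfg$k2_by_cd[[cd]]), tolerance = 1e-9)
    expect_equal(ifit$k_at_zero_cd, 2.59e-3, tolerance = 1e-9)
  }
})

test_that("profile assembly is order-invariant and rejects conflicts", {
  tab <- fu_rate_table()
  prof <- build_profile(tab)
  expect_s3_class(prof, "ph_profile")
  expect_equal(nrow(prof), nrow(tab))
  expect_equal(sum(prof$cd_type == "none"), 11)

  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(as.data.frame(build_profile(shuffled)), as.data.frame(prof))

  conflict <- rbind(tab, data.frame(ph = 6, cd_type = "none", cd_conc_M = 0,
                                    kobs_per_min = 9e-3))
  expect_error(build_profile(conflict), "conflicting duplicate")

  # exact duplicates collapse silently; missing cells are tolerated
  dup <- rbind(tab, tab[1, ])
  expect_equal(nrow(build_profile(dup)), nrow(tab))
  expect_equal(nrow(build_profile(tab[tab$cd_type %in% c("none", "gamma"), ])),
               11 + 55)
})

test_that("the minimum-rate pH is located with lower-pH tie breaking", {
  prof <- build_profile(fu_rate_table())
  mr <- minimum_rate_ph(prof, "none")
  expect_equal(mr$ph, 6.0)
  expect_false(mr$tie)

  mono <- build_profile(data.frame(ph = 2:5, cd_type = "none", cd_conc_M = 0,
                                   kobs_per_min = c(1, 2, 3, 4) * 1e-3))
  expect_equal(minimum_rate_ph(mono, "none")$ph, 2)

  flat <- build_profile(data.frame(ph = 2:5, cd_type = "none", cd_conc_M = 0,
                                   kobs_per_min = rep(1e-3, 4)))
  tie <- minimum_rate_ph(flat, "none")
  expect_equal(tie$ph, 2)
  expect_true(tie$tie)

  expect_error(minimum_rate_ph(prof, "delta"), "no profile cells")
})

test_that("interaction intercepts stay within 10% of the published k0", {
  tab <- fu_rate_table()
  k0 <- tab[tab$cd_type == "none", ]
  for (ph in unique(tab$ph)) for (cd in c("alpha", "beta", "gamma")) {
    g <- tab[tab$ph == ph & tab$cd_type == cd, ]
    icpt <- fit_interaction(g$cd_conc_M, g$kobs_per_min)$k_at_zero_cd
    k0_ph <- k0$kobs_per_min[k0$ph == ph]
    expect_lt(abs(icpt - k0_ph) / k0_ph, 0.10)
  }
})

test_that("stabilization percent follows its definition", {
  expect_equal(stabilization_percent(2.11e-3, 0.85e-3), 59.7, tolerance = 1e-3)
  expect_equal(stabilization_percent(2e-3, 2e-3), 0)
  expect_equal(stabilization_percent(2e-3, 0), 100)
  expect_lt(stabilization_percent(2e-3, 3e-3), 0)  # destabilization allowed
  expect_error(stabilization_percent(0, 1e-3), "positive")
})
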