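# The generators must be exact closed-form models when noiseless, bit-wise
# reproducible under a fixed seed, and mutually independent streams.

cfg0 <- synthetic_config(noise_cv = 0)

test_that("noiseless time courses follow the exact first-order model", {
  tc <- generate_time_course(cfg0, pH = 6, cd_type = "none")
  expect_equal(tc$responses[1], 100)  # zero-time identity
  k0 <- 2.11e-3
  expect_equal(tc$responses, 100 * exp(-k0 * tc$times), tolerance = 1e-14)

  # half-life: R/R0 = 1/2 at t = ln 2 / k
  cfg_hl <- synthetic_config(noise_cv = 0, k0_by_pH = c("7" = 1e-3),
                             k2_by_cd = c(gamma = 0.5),
                             t_max = 2 * 693.1, n_timepoints = 5)
  tc2 <- generate_time_course(cfg_hl, pH = 7)
  expect_equal(tc2$responses[3] / tc2$responses[1], 0.5000, tolerance = 1e-4)

  # with cyclodextrin: kobs = k0 - k2 [CD]
  tc3 <- generate_time_course(cfg0, pH = 6, cd_type = "gamma", cd_conc = 1.25e-3)
  kobs <- 2.11e-3 - 1.04 * 1.25e-3
  expect_equal(fit_first_order(tc3)$k, kobs, tolerance = 1e-12)
})

test_that("non-positive implied kobs is rejected with a named message", {
  cfg <- synthetic_config(noise_cv = 0, k0_by_pH = c("6" = 1e-3),
                          k2_by_cd = c(gamma = 0.5),
                          cd_concs = c(0.25, 0.5, 1.0) * 1e-3)
  expect_error(generate_time_course(cfg, 6, "gamma", 5e-3),
               "pH 6.*gamma.*0\\.005")
  expect_error(synthetic_config(k0_by_pH = c("6" = 1e-3),
                                k2_by_cd = c(gamma = 2),
                                cd_concs = c(1e-3)),
               "non-positive")
})

test_that("noiseless quenching and binding series match their closed forms", {
  s <- generate_quenching_series(cfg0)
  expect_equal(s$f0 / s$f, 1 + 3.06e3 * s$quencher_concs, tolerance = 1e-14)
  expect_equal((s$f0 / s$f)[5], 4.825, tolerance = 1e-12)  # 1 + 3060 * 1.25e-3

  # Ksv = 0: no quenching
  s0 <- generate_quenching_series(synthetic_config(noise_cv = 0, ksv = 0))
  expect_equal(s0$f, rep(100, 5))

  b <- generate_binding_series(cfg0, concs = c(2.5e-4, 5e-4, 1e-3))
  expect_equal((b$f0 - b$f) / b$f, 3.62e3 * b$quencher_concs^1.03,
               tolerance = 1e-12)
  expect_equal(((b$f0 - b$f) / b$f)[3], 2.943, tolerance = 1e-3)

  # n = 1 reduces the binding model to the Stern-Volmer form exactly
  cfg_n1 <- synthetic_config(noise_cv = 0, bindK = 3.06e3, bindN = 1)
  b1 <- generate_binding_series(cfg_n1)
  q1 <- generate_quenching_series(cfg_n1)
  expect_equal(b1$f, q1$f, tolerance = 1e-14)
})

test_that("noiseless Job series is symmetric and matches the equilibrium oracle", {
  js <- generate_job_series(cfg0, n_points = 9)
  expect_equal(js$delta_a, rev(js$delta_a), tolerance = 1e-12)

  # quadratic root against brute-force equilibrium solve at x = 0.5
  Tt <- 1e-4; K <- 3.62e3
  c_oracle <- equilibrium_oracle(0.5 * Tt, 0.5 * Tt, K)
  expect_equal(js$delta_a[5] / cfg0$job_eps, c_oracle, tolerance = 1e-9)

  # stoichiometric (K -> infinity) limit: c -> min(H, G)
  cfg_inf <- synthetic_config(noise_cv = 0, job_assoc_K = 1e12, n_timepoints = 6)
  js_inf <- generate_job_series(cfg_inf, n_points = 7)
  x <- js_inf$mole_fractions
  expect_equal(js_inf$delta_a / cfg_inf$job_eps, pmin(x, 1 - x) * 1e-4,
               tolerance = 1e-3)
})

test_that("noiseless conductivity series is exactly piecewise linear", {
  cs <- generate_conductivity_series(cfg0)
  fit <- fit_breakpoint(cs)
  expect_equal(fit$breakpoint, 2.0e-3)
  expect_equal(fit$sse, 0, tolerance = 1e-18)
  expect_equal(fit$slope1, -2.4e4, tolerance = 1e-6)
  expect_equal(fit$slope2, -6e3, tolerance = 1e-6)

  # equal slopes degenerate to a single line
  cfg_line <- synthetic_config(noise_cv = 0, cond_slope1 = -5e3, cond_slope2 = -5e3)
  cs_line <- generate_conductivity_series(cfg_line)
  expect_false(fit_breakpoint(cs_line)$significant)
})

test_that("noiseless calibration recovers the generating line exactly", {
  cal <- generate_calibration(synthetic_config(noise_cv = 0, calib_sd = 0))
  lin <- fit_linearity(cal)
  expect_equal(lin$slope, 2.56e10, tolerance = 1e-12)
  expect_equal(lin$intercept, 8.48e3, tolerance = 1e-9)
  expect_equal(lin$correlation, 1, tolerance = 1e-12)
})

test_that("a fixed seed regenerates every series bit-identically", {
  cfg <- synthetic_config(seed = 7, noise_cv = 0.05)
  gens <- list(
    function(c) generate_time_course(c, 6, "gamma", 1e-3),
    function(c) generate_quenching_series(c),
    function(c) generate_binding_series(c),
    function(c) generate_job_series(c),
    function(c) generate_conductivity_series(c),
    function(c) generate_calibration(c)
  )
  for (g in gens) expect_identical(g(cfg), g(cfg))
  # a different seed changes the noise
  cfg2 <- synthetic_config(seed = 8, noise_cv = 0.05)
  expect_false(identical(generate_quenching_series(cfg)$f,
                         generate_quenching_series(cfg2)$f))
})

test_that("series use independent streams and leave the global RNG alone", {
  cfg <- synthetic_config(seed = 11, noise_cv = 0.05)
  tc_a <- generate_time_course(cfg, 6, "gamma", 1e-3)
  invisible(generate_calibration(cfg))  # interleaved generation
  tc_b <- generate_time_course(cfg, 6, "gamma", 1e-3)
  expect_identical(tc_a, tc_b)

  set.seed(123)
  expected_draw <- rnorm(1)
  set.seed(123)
  invisible(generate_quenching_series(cfg))
  expect_identical(rnorm(1), expected_draw)
})

test_that("generated kobs grid is ordered in [CD] and across cyclodextrins", {
  cfg <- synthetic_config(noise_cv = 0)
  for (cd in c("alpha", "beta", "gamma")) {
    ks <- vapply(cfg$cd_concs, function(cc)
      fit_first_order(generate_time_course(cfg, 6, cd, cc))$k, numeric(1))
    expect_true(all(diff(ks) < 0))  # strictly decreasing in [CD]
  }
  # k2(alpha) < k2(beta) < k2(gamma) => kobs(alpha) > kobs(beta) > kobs(gamma)
  at_max <- vapply(c("alpha", "beta", "gamma"), function(cd)
    fit_first_order(generate_time_course(cfg, 6, cd, 1.25e-3))$k, numeric(1))
  expect_true(all(diff(at_max) < 0))
})
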