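make_sv_series <- function(ksv, concs = seq(2.5e-4, 1.25e-3, 2.5e-4), f0 = 100) {
  quenching_series(concs, f0 / (1 + ksv * concs), f0)
}

test_that("Stern-Volmer fit recovers the generating constant exactly", {
  fit <- stern_volmer_fit(make_sv_series(3.06e3))
  expect_equal(fit$ksv, 3.06e3, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # no quenching: slope 0
  s_flat <- quenching_series(c(1e-4, 2e-4, 3e-4), rep(100, 3), 100)
  expect_equal(stern_volmer_fit(s_flat)$ksv, 0)

  # two-point interpolation check against a hand OLS (3 points, exact line)
  q <- c(1e-4, 5e-4, 1e-3)
  s_line <- quenching_series(q, 100 / (1 + 1000 * q), 100)
  expect_equal(stern_volmer_fit(s_line)$ksv, 1000, tolerance = 1e-10)
})

test_that("an off-unity Stern-Volmer intercept triggers the diagnostic warning", {
  q <- c(1e-4, 5e-4, 1e-3)
  ratio <- 1.3 + 1000 * q  # baseline error pushes the intercept to 1.3
  s <- quenching_series(q, 100 / ratio, 100)
  expect_warning(stern_volmer_fit(s), "deviates from 1")
})

test_that("binding fit recovers (K, n) and nests the Stern-Volmer model", {
  cfg <- synthetic_config(noise_cv = 0)
  bf <- binding_fit(generate_binding_series(cfg))
  expect_equal(bf$bigK, 3.62e3, tolerance = 1e-9)
  expect_equal(bf$n_sites, 1.03, tolerance = 1e-12)

  # alpha-CD parameter set round-trips too
  cfg_a <- synthetic_config(noise_cv = 0, bindK = 2.89e3, bindN = 0.94)
  bf_a <- binding_fit(generate_binding_series(cfg_a, concs = c(2.5e-4, 5e-4, 1e-3)))
  expect_equal(bf_a$bigK, 2.89e3, tolerance = 1e-9)
  expect_equal(bf_a$n_sites, 0.94, tolerance = 1e-12)

  # n = 1 data: binding fit and Stern-Volmer fit agree
  s1 <- make_sv_series(1.69e3)
  expect_equal(binding_fit(s1)$bigK, stern_volmer_fit(s1)$ksv, tolerance = 1e-9)
  expect_equal(binding_fit(s1)$n_sites, 1, tolerance = 1e-9)

  # unit point: K = 1, n = 1, Q = 1 gives (F0-F)/F = 1 hence log 0
  expect_equal(log10((100 - 100 / (1 + 1 * 1)) / (100 / 2)), 0)
})

test_that("binding fit rejects points at F = F0 naming the concentration", {
  s <- quenching_series(c(1e-4, 5e-4, 1e-3), c(100, 80, 60), 100)
  expect_error(binding_fit(s), "0\\.0001")
})

test_that("fluorescence loss and entrapment efficiency follow their formulas", {
  expect_equal(percent_fluorescence_loss(100, 25), 75)
  expect_equal(percent_fluorescence_loss(100, 100), 0)
  expect_equal(percent_fluorescence_loss(100, 0), 100)
  expect_equal(entrapment_efficiency(100, 23), 77)
  expect_equal(entrapment_efficiency(100, 42), 58)
  expect_equal(entrapment_efficiency(100, 100), 0)
  expect_error(entrapment_efficiency(100, 120), "exceeds")
  expect_error(percent_fluorescence_loss(0, 1), "positive")
})

test_that("loss and efficiency stay within [0, 100] for any valid series", {
  cfg <- synthetic_config(seed = 3, noise_cv = 0.05)
  for (i in 1:20) {
    s <- generate_quenching_series(synthetic_config(seed = i, noise_cv = 0.05))
    loss <- percent_fluorescence_loss(s$f0, s$f)
    expect_true(all(loss >= 0 & loss <= 100))
    expect_true(all(entrapment_efficiency(s$f0, s$f) >= 0))
  }
})

test_that("quenching series invariants are enforced", {
  expect_error(quenching_series(numeric(0), numeric(0), 100), "empty")
  expect_error(quenching_series(c(2e-4, 1e-4), c(90, 80), 100), "increasing")
  expect_error(quenching_series(c(1e-4, 2e-4), c(90, 110), 100), "exceeds")
  expect_error(quenching_series(c(1e-4, 2e-4), c(90, 0), 100), "positive")
})
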