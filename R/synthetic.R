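# Seeded synthetic-data generators. Every input series the pipeline consumes
# can be generated with the statistical structure the analysis assumes:
# first-order decay with a cyclodextrin-concentration-dependent rate,
# Stern-Volmer quenching, power-law binding, the symmetric 1:1
# continuous-variation signal, two-segment conductivity, and linear
# calibration. Noise on spectroscopic/chromatographic responses is
# multiplicative lognormal (scale-proportional); calibration noise is
# additive Gaussian. Each series draws from its own seeded stream derived
# from the master seed and the series' identifying parameters, so series are
# mutually independent and individually reproducible.

#' Configuration for the synthetic-data generators
#'
#' Default parameters are the published 5-fluorouracil/cyclodextrin reference
#' values: the cyclodextrin-free rate constants `k0_by_pH` across pH 2--12,
#' the pH-6 interaction constants `k2_by_cd` (the recommended formulation pH),
#' the gamma-cyclodextrin quenching constant `ksv`, binding constant `bindK`
#' and site number `bindN`, a 1.00e-4 M total Job concentration, and the
#' gamma-cyclodextrin calibration slope/intercept with an intercept SD
#' matching the published value.
#'
#' @param seed Master seed (integer, default 42). Each generated series uses
#'   a stream derived from this seed and the series' own key.
#' @param noise_cv Coefficient of variation of the multiplicative response
#'   noise, >= 0 (default 0.02).
#' @param n_timepoints Number of photolysis sampling times, >= 4 (default 6).
#' @param t_max Last sampling time in minutes; `NULL` (default) means two
#'   half-lives of the series being generated.
#' @param r0,f0 Initial photolysis response and quencher-free fluorescence
#'   (arbitrary units, default 100).
#' @param k0_by_pH Named numeric vector, pH -> k0 in min^-1.
#' @param k2_by_cd Named numeric vector, cyclodextrin -> k2 in M^-1 min^-1.
#' @param cd_concs Cyclodextrin concentration grid in mol/L.
#' @param ksv Stern--Volmer constant in L/mol.
#' @param bindK,bindN Binding constant (L/mol) and site number.
#' @param job_total_conc Total host+guest concentration for the Job series
#'   (mol/L, default 1.00e-4).
#' @param job_assoc_K 1:1 association constant for the Job series (L/mol).
#' @param job_eps Proportionality between complex concentration and the
#'   absorbance change (L mol^-1 cm^-1 scale factor, default 8000).
#' @param cond_intercept,cond_slope1,cond_slope2,cond_break Conductivity
#'   baseline (uS/cm), segment slopes (uS cm^-1 M^-1) and breakpoint (mol/L,
#'   default 2.0e-3, the conductometric equivalence point).
#' @param calib_slope,calib_intercept,calib_sd Calibration line and the
#'   additive Gaussian response SD.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L,
                             noise_cv = 0.02,
                             n_timepoints = 6L,
                             t_max = NULL,
                             r0 = 100,
                             f0 = 100,
                             k0_by_pH = NULL,
                             k2_by_cd = c(alpha = 0.28, beta = 0.71, gamma = 1.04),
                             cd_concs = c(0.25, 0.50, 0.75, 1.00, 1.25) * 1e-3,
                             ksv = 3.06e3,
                             bindK = 3.62e3,
                             bindN = 1.03,
                             job_total_conc = 1.00e-4,
                             job_assoc_K = 3.62e3,
                             job_eps = 8000,
                             cond_intercept = 180,
                             cond_slope1 = -2.4e4,
                             cond_slope2 = -6e3,
                             cond_break = 2.0e-3,
                             calib_slope = 2.56e10,
                             calib_intercept = 8.48e3,
                             calib_sd = 1.25e4) {
  if (is.null(k0_by_pH)) {
    k0_by_pH <- c("2" = 3.51, "3" = 3.10, "4" = 2.61, "5" = 2.36, "6" = 2.11,
                  "7" = 2.22, "8" = 2.45, "9" = 2.59, "10" = 2.78,
                  "11" = 3.81, "12" = 5.22) * 1e-3
  }
  cfg <- list(seed = as.integer(seed), noise_cv = noise_cv,
              n_timepoints = as.integer(n_timepoints), t_max = t_max,
              r0 = r0, f0 = f0, k0_by_pH = k0_by_pH, k2_by_cd = k2_by_cd,
              cd_concs = cd_concs, ksv = ksv, bindK = bindK, bindN = bindN,
              job_total_conc = job_total_conc, job_assoc_K = job_assoc_K,
              job_eps = job_eps, cond_intercept = cond_intercept,
              cond_slope1 = cond_slope1, cond_slope2 = cond_slope2,
              cond_break = cond_break, calib_slope = calib_slope,
              calib_intercept = calib_intercept, calib_sd = calib_sd)
  if (cfg$noise_cv < 0) stopf("noise_cv must be >= 0")
  if (cfg$n_timepoints < 4L) stopf("n_timepoints must be >= 4")
  for (nm in c("r0", "f0", "ksv", "bindK", "bindN", "job_total_conc",
               "job_assoc_K", "job_eps", "calib_slope", "calib_sd")) {
    if (cfg[[nm]] < 0) stopf("%s must be non-negative", nm)
  }
  if (any(cfg$k0_by_pH <= 0)) stopf("all k0 values must be strictly positive")
  if (any(cfg$k2_by_cd < 0)) stopf("k2 values must be non-negative")
  if (any(cfg$cd_concs <= 0)) stopf("cd_concs must be strictly positive")
  # every (pH, CD, conc) cell of the default grid must imply a positive kobs
  for (ph in names(cfg$k0_by_pH)) for (cd in names(cfg$k2_by_cd)) {
    kobs <- cfg$k0_by_pH[[ph]] - cfg$k2_by_cd[[cd]] * max(cfg$cd_concs)
    if (kobs <= 0)
      stopf("implied kobs non-positive at pH %s, %s-CD, [CD] = %g M",
            ph, cd, max(cfg$cd_concs))
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic config: seed %d, noise CV %.3g, %d pH levels x %d [CD]\n",
              x$seed, x$noise_cv, length(x$k0_by_pH), length(x$cd_concs)))
  invisible(x)
}

lookup_k0 <- function(config, pH) {
  idx <- match(pH, as.numeric(names(config$k0_by_pH)))
  if (is.na(idx)) stopf("no k0 configured for pH %g", pH)
  config$k0_by_pH[[idx]]
}

#' Generate a photolysis time course
#'
#' First-order decay `R(t) = R0 exp(-kobs t)` with
#' `kobs = k0(pH) - k2(CD) [CD]` and multiplicative lognormal noise of the
#' configured coefficient of variation. Sampling times are `n_timepoints`
#' uniform points from 0 to `t_max` (default two half-lives of the generated
#' series).
#'
#' @param config A [synthetic_config()].
#' @param pH A pH present in `config$k0_by_pH`.
#' @param cd_type `"none"` or a name of `config$k2_by_cd`.
#' @param cd_conc Cyclodextrin concentration in mol/L.
#' @return A [time_course()].
#' @export
#' @examples
#' cfg <- synthetic_config(noise_cv = 0)
#' tc <- generate_time_course(cfg, pH = 6, cd_type = "gamma", cd_conc = 1.25e-3)
#' fit_first_order(tc)$k  # 2.11e-3 - 1.04 * 1.25e-3 = 8.1e-4
generate_time_course <- function(config, pH, cd_type = "none", cd_conc = 0) {
  stopifnot(inherits(config, "synthetic_config"))
  k0 <- lookup_k0(config, pH)
  k2 <- if (cd_type == "none") 0 else {
    if (!cd_type %in% names(config$k2_by_cd))
      stopf("no k2 configured for cyclodextrin '%s'", cd_type)
    config$k2_by_cd[[cd_type]]
  }
  kobs <- k0 - k2 * cd_conc
  if (kobs <= 0)
    stopf("implied kobs = %.3g min^-1 is non-positive at pH %g, %s-CD, [CD] = %g M",
          kobs, pH, cd_type, cd_conc)
  t_max <- if (is.null(config$t_max)) 2 * log(2) / kobs else config$t_max
  times <- seq(0, t_max, length.out = config$n_timepoints)
  eps <- with_seed(series_seed(config$seed, paste("tc", pH, cd_type, cd_conc)),
                   lognormal_noise(length(times), config$noise_cv))
  time_course(times, config$r0 * exp(-kobs * times) * eps,
              pH = pH, cd_type = cd_type, cd_conc = cd_conc)
}

#' Generate a Stern--Volmer quenching series
#'
#' `F = F0 / (1 + Ksv [Q])` with multiplicative lognormal noise.
#'
#' @param config A [synthetic_config()].
#' @param cd_type Label carried into the series key (stream separation only).
#' @param concs Quencher concentrations in mol/L, positive and strictly
#'   increasing; default `config$cd_concs`.
#' @return A [quenching_series()].
#' @export
generate_quenching_series <- function(config, cd_type = "gamma",
                                      concs = config$cd_concs) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!length(concs)) stopf("empty concentration list")
  f_true <- config$f0 / (1 + config$ksv * concs)
  eps <- with_seed(series_seed(config$seed, paste("sv", cd_type)),
                   lognormal_noise(length(concs), config$noise_cv))
  f <- pmin(f_true * eps, config$f0)
  quenching_series(concs, f, f0 = config$f0)
}

#' Generate a power-law binding series
#'
#' `(F0 - F)/F = K [Q]^n`, i.e. `F = F0 / (1 + K [Q]^n)`, with multiplicative
#' lognormal noise. With `n = 1` this reduces exactly to the Stern--Volmer
#' form.
#'
#' @inheritParams generate_quenching_series
#' @return A [quenching_series()].
#' @export
generate_binding_series <- function(config, cd_type = "gamma",
                                    concs = config$cd_concs) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!length(concs)) stopf("empty concentration list")
  if (any(concs <= 0)) stopf("concentrations must be positive")
  f_true <- config$f0 / (1 + config$bindK * concs^config$bindN)
  eps <- with_seed(series_seed(config$seed, paste("bind", cd_type)),
                   lognormal_noise(length(concs), config$noise_cv))
  f <- pmin(f_true * eps, config$f0)
  quenching_series(concs, f, f0 = config$f0)
}

#' Equilibrium 1:1 complex concentration
#'
#' Smaller root of `c^2 - c (H + G + 1/K) + H G = 0` for host concentration
#' H, guest concentration G and association constant K; the physically
#' admissible complex concentration (0 <= c <= min(H, G)).
#' @noRd
complex_conc_1to1 <- function(H, G, K) {
  b <- H + G + 1 / K
  (b - sqrt(b^2 - 4 * H * G)) / 2
}

#' Generate a Job's continuous-variation series
#'
#' For host mole fraction x on the uniform grid `(1:n)/(n+1)` at constant
#' total concentration T, the 1:1 equilibrium complex concentration c(x)
#' (smaller quadratic root with `H = x T`, `G = (1-x) T`) is scaled to an
#' absorbance change and perturbed by multiplicative noise. The noiseless
#' signal is exactly symmetric about x = 0.5.
#'
#' @param config A [synthetic_config()].
#' @param n_points Number of grid points, >= 5 (default 9, placing a point at
#'   x = 0.5).
#' @return A [job_series()].
#' @export
generate_job_series <- function(config, n_points = 9L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_points < 5L) stopf("a Job's series needs at least 5 points")
  if (config$job_assoc_K <= 0) stopf("association constant must be positive")
  if (config$job_total_conc <= 0) stopf("total concentration must be positive")
  x <- seq_len(n_points) / (n_points + 1)
  Tt <- config$job_total_conc
  cc <- complex_conc_1to1(x * Tt, (1 - x) * Tt, config$job_assoc_K)
  eps <- with_seed(series_seed(config$seed, paste("job", n_points)),
                   lognormal_noise(n_points, config$noise_cv))
  job_series(x, config$job_eps * cc * eps)
}

#' Generate a conductometric titration series
#'
#' Continuous two-segment piecewise-linear conductivity with distinct slopes
#' meeting at the configured breakpoint, plus multiplicative noise.
#'
#' @param config A [synthetic_config()].
#' @param concs Concentration grid in mol/L, increasing, with at least 3
#'   points on each side of the breakpoint; default 0--3.2 mM in 0.4 mM
#'   steps.
#' @return A [conductivity_series()].
#' @export
generate_conductivity_series <- function(config,
                                         concs = seq(0, 3.2e-3, by = 4e-4)) {
  stopifnot(inherits(config, "synthetic_config"))
  n_left <- sum(concs <= config$cond_break)
  n_right <- sum(concs >= config$cond_break)
  if (n_left < 3L || n_right < 3L)
    stopf("need at least 3 points on each side of the breakpoint (%g M)",
          config$cond_break)
  y <- config$cond_intercept + config$cond_slope1 * pmin(concs, config$cond_break) +
    config$cond_slope2 * pmax(concs - config$cond_break, 0)
  if (any(y <= 0)) stopf("configured segments drive conductivity non-positive")
  eps <- with_seed(series_seed(config$seed, "conduct"),
                   lognormal_noise(length(concs), config$noise_cv))
  conductivity_series(concs, y * eps)
}

#' Generate a calibration series
#'
#' `response = slope * conc + intercept + N(0, calib_sd)`, with the replicate
#' structure preserved (each replicate is a full curve over the nominal
#' levels).
#'
#' @param config A [synthetic_config()].
#' @param nominal_concs Nominal levels in mol/L, at least 5 (default
#'   0.5--5.0e-5 M, the validated assay range).
#' @param replicates Number of replicate curves, >= 1 (default 3).
#' @return A [calibration_series()].
#' @export
generate_calibration <- function(config,
                                 nominal_concs = seq(0.5e-5, 5.0e-5, length.out = 10),
                                 replicates = 3L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (replicates < 1L) stopf("replicates must be >= 1")
  if (length(unique(nominal_concs)) < 5L)
    stopf("calibration needs at least 5 nominal levels")
  x <- rep(nominal_concs, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(nominal_concs))
  noise <- with_seed(series_seed(config$seed, paste("calib", replicates)),
                     stats::rnorm(length(x), 0, config$calib_sd))
  calibration_series(x, config$calib_slope * x + config$calib_intercept + noise,
                     replicate = rep_id)
}
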