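# Published reference values for 5-fluorouracil photodegradation in the
# presence of cyclodextrins. These tables are inputs to worked examples and to
# the acceptance checks: the kobs grid feeds the secondary regression that
# recovers the second-order interaction constants, and the calibration
# statistics feed the ICH detection/quantification limits.

# kobs (x 10^3 min^-1) for each CD at [CD] = 0.25, 0.50, 0.75, 1.00, 1.25 mM,
# plus k0 (no CD), by pH.
.fu_kobs_raw <- list(
  "2"  = list(alpha = c(3.38, 3.26, 3.15, 3.01, 2.89),
              beta  = c(3.30, 3.15, 2.96, 2.85, 2.64),
              gamma = c(3.19, 2.85, 2.49, 2.16, 1.85), k0 = 3.51),
  "3"  = list(alpha = c(3.01, 2.89, 2.76, 2.64, 2.56),
              beta  = c(2.89, 2.72, 2.50, 2.29, 2.10),
              gamma = c(2.75, 2.42, 2.15, 1.87, 1.50), k0 = 3.10),
  "4"  = list(alpha = c(2.50, 2.41, 2.29, 2.19, 2.10),
              beta  = c(2.48, 2.26, 2.17, 1.97, 1.80),
              gamma = c(2.31, 2.06, 1.75, 1.49, 1.14), k0 = 2.61),
  "5"  = list(alpha = c(2.25, 2.15, 2.04, 1.94, 1.86),
              beta  = c(2.19, 2.01, 1.85, 1.69, 1.54),
              gamma = c(2.09, 1.75, 1.48, 1.16, 0.92), k0 = 2.36),
  "6"  = list(alpha = c(2.03, 1.95, 1.84, 1.80, 1.75),
              beta  = c(1.92, 1.75, 1.56, 1.40, 1.21),
              gamma = c(1.89, 1.67, 1.36, 1.15, 0.85), k0 = 2.11),
  "7"  = list(alpha = c(2.12, 2.05, 1.98, 1.89, 1.82),
              beta  = c(2.04, 1.85, 1.72, 1.59, 1.38),
              gamma = c(1.98, 1.75, 1.50, 1.32, 1.05), k0 = 2.22),
  "8"  = list(alpha = c(2.34, 2.27, 2.13, 2.06, 1.94),
              beta  = c(2.24, 2.11, 1.92, 1.72, 1.57),
              gamma = c(2.17, 1.96, 1.72, 1.49, 1.22), k0 = 2.45),
  "9"  = list(alpha = c(2.49, 2.38, 2.29, 2.13, 2.04),
              beta  = c(2.45, 2.28, 2.09, 1.95, 1.80),
              gamma = c(2.39, 2.17, 1.89, 1.65, 1.51), k0 = 2.59),
  "10" = list(alpha = c(2.69, 2.61, 2.51, 2.44, 2.36),
              beta  = c(2.60, 2.45, 2.31, 2.09, 1.98),
              gamma = c(2.52, 2.39, 2.09, 1.99, 1.73), k0 = 2.78),
  "11" = list(alpha = c(3.74, 3.68, 3.62, 3.56, 3.49),
              beta  = c(3.69, 3.48, 3.27, 3.06, 2.85),
              gamma = c(3.54, 3.26, 2.89, 2.50, 2.21), k0 = 3.81),
  "12" = list(alpha = c(5.12, 5.03, 4.96, 4.88, 4.81),
              beta  = c(4.89, 4.52, 4.06, 3.69, 3.47),
              gamma = c(4.69, 4.26, 3.69, 3.06, 2.62), k0 = 5.22)
)

#' Reference first-order photodegradation rate constants of 5-fluorouracil
#'
#' Apparent first-order rate constants (`kobs_per_min`, min^-1) for UV
#' photodegradation of 5-fluorouracil at pH 2--12 in the presence of alpha-,
#' beta- and gamma-cyclodextrin at 0.25--1.25 mM, and without cyclodextrin
#' (`cd_type = "none"`, `cd_conc_M = 0`, giving k0). This grid is the standard
#' worked example for [fit_interaction()].
#'
#' @return A data frame with columns `ph`, `cd_type`, `cd_conc_M`,
#'   `kobs_per_min`, one row per grid cell (11 pH values x (3 CDs x 5
#'   concentrations + 1 k0 row) = 176 rows).
#' @seealso [fu_interaction_table()] for the corresponding second-order
#'   constants, [build_profile()] for rate--pH profiles.
#' @export
#' @examples
#' tab <- fu_rate_table()
#' sub <- tab[tab$ph == 12 & tab$cd_type == "gamma", ]
#' fit_interaction(sub$cd_conc_M, sub$kobs_per_min, pH = 12, cd_type = "gamma")
fu_rate_table <- function() {
  concs <- c(0.25, 0.50, 0.75, 1.00, 1.25) * 1e-3
  rows <- lapply(names(.fu_kobs_raw), function(ph) {
    x <- .fu_kobs_raw[[ph]]
    rbind(
      data.frame(ph = as.numeric(ph), cd_type = "none", cd_conc_M = 0,
                 kobs_per_min = x$k0 * 1e-3),
      do.call(rbind, lapply(c("alpha", "beta", "gamma"), function(cd) {
        data.frame(ph = as.numeric(ph), cd_type = cd, cd_conc_M = concs,
                   kobs_per_min = x[[cd]] * 1e-3)
      }))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference second-order interaction constants k2
#'
#' Published second-order rate constants (M^-1 min^-1) for the photochemical
#' interaction of 5-fluorouracil with each cyclodextrin at pH 2--12, i.e. the
#' negated slopes of kobs against cyclodextrin concentration. Used as the
#' expected values when the grid from [fu_rate_table()] is refit with
#' [fit_interaction()].
#'
#' @return A data frame with columns `ph`, `cd_type`, `k2`.
#' @export
fu_interaction_table <- function() {
  k2 <- list(
    "2" = c(0.49, 0.65, 1.35), "3" = c(0.46, 0.80, 1.22),
    "4" = c(0.41, 0.66, 1.16), "5" = c(0.40, 0.65, 1.17),
    "6" = c(0.28, 0.71, 1.04), "7" = c(0.30, 0.63, 0.92),
    "8" = c(0.40, 0.69, 0.95), "9" = c(0.46, 0.65, 0.91),
    "10" = c(0.33, 0.64, 0.79), "11" = c(0.25, 0.84, 1.37),
    "12" = c(0.31, 1.47, 2.14)
  )
  out <- do.call(rbind, lapply(names(k2), function(ph) {
    data.frame(ph = as.numeric(ph), cd_type = c("alpha", "beta", "gamma"),
               k2 = k2[[ph]])
  }))
  rownames(out) <- NULL
  out
}

#' Reference fluorescence quenching and binding constants
#'
#' Stern--Volmer quenching constants, binding constants and binding-site
#' numbers of 5-fluorouracil with each cyclodextrin at 25 degrees C.
#'
#' @return A data frame with columns `cd_type`, `ksv` (L/mol), `bigK` (L/mol),
#'   `n_sites`.
#' @export
fu_quenching_table <- function() {
  data.frame(
    cd_type = c("alpha", "beta", "gamma"),
    ksv     = c(1.10e3, 1.69e3, 3.06e3),
    bigK    = c(2.89e3, 3.11e3, 3.62e3),
    n_sites = c(0.94, 0.95, 1.03)
  )
}

#' Reference HPLC calibration statistics for the 5-fluorouracil assay
#'
#' Published calibration-curve statistics for the HPLC determination of
#' 5-fluorouracil in the presence of each cyclodextrin: slope and intercept of
#' the straight-line fit with their standard errors, standard deviation of the
#' intercept (the sigma entering the ICH detection limits), correlation
#' coefficient, accuracy, precision, and the printed LOD/LOQ. All values in
#' native units (response units and molar).
#'
#' @return A data frame, one row per cyclodextrin.
#' @seealso [ich_limits()], [check_ich_consistency()]
#' @export
fu_calibration_table <- function() {
  data.frame(
    cd_type       = c("alpha", "beta", "gamma"),
    slope         = c(1.68e10, 2.13e10, 2.56e10),
    se_slope      = c(6.26e3, 4.90e3, 5.78e3),
    intercept     = c(0.40e3, 6.39e3, 8.48e3),
    se_intercept  = c(4.28e3, 3.35e3, 3.95e3),
    sd_intercept  = c(1.35e4, 0.16e4, 1.25e4),
    correlation   = c(0.9997, 0.9998, 0.9999),
    accuracy_pct  = c(100.0, 100.1, 99.65),
    accuracy_sd   = c(1.54, 1.24, 1.56),
    precision_rsd = c(1.54, 1.23, 1.57),
    lod_M         = c(2.65e-6, 1.64e-6, 1.61e-6),
    loq_M         = c(8.40e-6, 4.97e-6, 4.88e-6)
  )
}
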