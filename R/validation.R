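# ICH-style calibration validation: linearity with standard errors, detection
# and quantification limits (3.3 sigma/S, 10 sigma/S), accuracy and precision.

#' Construct a calibration series
#'
#' Detector responses at nominal analyte concentrations, optionally with
#' replicates per level.
#'
#' @param nominal_concs Nominal concentrations in mol/L; at least 5 distinct
#'   levels.
#' @param responses Detector responses, same length.
#' @param replicate Optional integer replicate index per row (used to compute
#'   the standard deviation of the intercept across replicate curves).
#' @param label Context label (e.g. which cyclodextrin is present).
#' @return An object of class `calibration_series`.
#' @export
calibration_series <- function(nominal_concs, responses, replicate = NULL,
                               label = "") {
  nominal_concs <- as.numeric(nominal_concs)
  responses <- as.numeric(responses)
  if (length(nominal_concs) != length(responses))
    stopf("concs and responses differ in length")
  if (length(unique(nominal_concs)) < 5L)
    stopf("calibration needs at least 5 distinct concentration levels, got %d",
          length(unique(nominal_concs)))
  if (any(!is.finite(responses))) stopf("non-finite response in calibration series")
  if (!is.null(replicate) && length(replicate) != length(responses))
    stopf("replicate index length mismatch")
  structure(list(nominal_concs = nominal_concs, responses = responses,
                 replicate = replicate, label = label),
            class = "calibration_series")
}

#' @export
print.calibration_series <- function(x, ...) {
  cat(sprintf("Calibration series%s: %d points, %d levels, %.3g-%.3g M\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              length(x$responses), length(unique(x$nominal_concs)),
              min(x$nominal_concs), max(x$nominal_concs)))
  invisible(x)
}

#' Linearity fit of a calibration curve
#'
#' Ordinary least squares `y = m x + c` with standard errors from the usual
#' OLS formulas and the Pearson correlation coefficient.
#'
#' @param series A [calibration_series()].
#' @return An object of class `linearity_fit`: `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `correlation`, `r_squared`, `n_points`.
#' @export
fit_linearity <- function(series) {
  stopifnot(inherits(series, "calibration_series"))
  x <- series$nominal_concs
  y <- series$responses
  if (length(unique(x)) < 2L) stopf("all concentrations identical; slope undefined")
  fit <- stats::lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients
  ses <- cf[, "Std. Error"]
  ses[!is.finite(ses)] <- 0
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[["x"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 se_slope = unname(ses["x"]),
                 se_intercept = unname(ses["(Intercept)"]),
                 correlation = stats::cor(x, y),
                 r_squared = if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss)),
                 n_points = length(x), lm = fit),
            class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf("Linearity: y = %.4g x + %.4g (SE %.3g / %.3g), r = %.5f, n = %d\n",
              x$slope, x$intercept, x$se_slope, x$se_intercept,
              x$correlation, x$n_points))
  invisible(x)
}

#' @export
coef.linearity_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
predict.linearity_fit <- function(object, nominal_concs, ...) {
  object$intercept + object$slope * nominal_concs
}

#' ICH detection and quantification limits
#'
#' `lod = 3.3 sigma / S` and `loq = 10 sigma / S`, with sigma the standard
#' deviation of the intercept (from replicate calibration curves) and S the
#' calibration slope. By construction `loq = (10/3.3) lod` exactly.
#'
#' @param sd_intercept Standard deviation of the intercept, >= 0.
#' @param slope Calibration slope, > 0.
#' @return `lod()` and `loq()` return the limit in mol/L; `ich_limits()`
#'   returns both as a named list.
#' @export
#' @examples
#' lod(1.35e4, 1.68e10)  # 2.65e-6
#' loq(1.25e4, 2.56e10)  # 4.88e-6
lod <- function(sd_intercept, slope) {
  if (any(slope <= 0)) stopf("slope must be positive")
  if (any(sd_intercept < 0)) stopf("sd_intercept cannot be negative")
  3.3 * sd_intercept / slope
}

#' @rdname lod
#' @export
loq <- function(sd_intercept, slope) {
  if (any(slope <= 0)) stopf("slope must be positive")
  if (any(sd_intercept < 0)) stopf("sd_intercept cannot be negative")
  10 * sd_intercept / slope
}

#' @rdname lod
#' @export
ich_limits <- function(sd_intercept, slope) {
  list(lod = lod(sd_intercept, slope), loq = loq(sd_intercept, slope))
}

#' Accuracy and precision of replicate determinations
#'
#' Accuracy is the mean recovery `100 * measured / nominal` with its sample
#' standard deviation; precision is the relative standard deviation
#' `100 * SD / mean` of the measurements (sample SD, n - 1).
#'
#' @param measured Replicate measured values, at least 2.
#' @param nominal The nominal (true) value, > 0.
#' @return A list: `accuracy_percent`, `accuracy_sd`, `precision_rsd`.
#' @export
#' @examples
#' accuracy_precision(c(98, 100, 102), 100)  # 100% +/- 2, RSD 2%
accuracy_precision <- function(measured, nominal) {
  measured <- as.numeric(measured)
  if (length(measured) < 2L) stopf("need at least 2 replicate measurements")
  if (!is_number(nominal) || nominal <= 0) stopf("nominal must be positive")
  rec <- 100 * measured / nominal
  m <- mean(measured)
  list(accuracy_percent = mean(rec),
       accuracy_sd = stats::sd(rec),
       precision_rsd = 100 * stats::sd(measured) / m)
}

#' Full ICH-style validation report for a calibration series
#'
#' Combines the linearity fit, the intercept standard deviation (across
#' replicate curves when a replicate index is present, otherwise the supplied
#' or OLS value), the derived LOD/LOQ, and back-calculated accuracy/precision.
#'
#' @param series A [calibration_series()].
#' @param sd_intercept Optional externally determined standard deviation of
#'   the intercept. When `NULL` and the series has replicate structure, each
#'   replicate curve is fit separately and the SD of their intercepts is used;
#'   otherwise the OLS standard error of the intercept stands in (flagged in
#'   the report).
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(series, sd_intercept = NULL) {
  stopifnot(inherits(series, "calibration_series"))
  lin <- fit_linearity(series)
  sigma_source <- "supplied"
  if (is.null(sd_intercept)) {
    if (!is.null(series$replicate) && length(unique(series$replicate)) >= 2L) {
      icpts <- vapply(split(seq_along(series$responses), series$replicate),
                      function(idx) {
                        f <- stats::lm(series$responses[idx] ~ series$nominal_concs[idx])
                        unname(stats::coef(f)[[1]])
                      }, numeric(1))
      sd_intercept <- stats::sd(icpts)
      sigma_source <- "replicate curves"
    } else {
      sd_intercept <- lin$se_intercept
      sigma_source <- "OLS SE of intercept (no replicate curves available)"
    }
  }
  lims <- ich_limits(sd_intercept, lin$slope)
  # back-calculated concentrations -> recovery per point, RSD per level
  back <- (series$responses - lin$intercept) / lin$slope
  rec <- 100 * back / series$nominal_concs
  rsd_by_level <- vapply(split(back, series$nominal_concs), function(v) {
    if (length(v) < 2L) NA_real_ else 100 * stats::sd(v) / mean(v)
  }, numeric(1))
  structure(list(linearity = lin,
                 sd_intercept = sd_intercept, sigma_source = sigma_source,
                 lod = lims$lod, loq = lims$loq,
                 accuracy_percent = mean(rec),
                 accuracy_sd = stats::sd(rec),
                 precision_rsd = mean(rsd_by_level, na.rm = TRUE),
                 label = series$label),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("ICH validation report%s\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  print(x$linearity)
  cat(sprintf("  sigma(intercept) = %.4g [%s]\n", x$sd_intercept, x$sigma_source))
  cat(sprintf("  LOD = %.3g M, LOQ = %.3g M\n", x$lod, x$loq))
  cat(sprintf("  accuracy = %.2f%% +/- %.2f, precision RSD = %.2f%%\n",
              x$accuracy_percent, x$accuracy_sd,
              x$precision_rsd))
  invisible(x)
}

#' Cross-check published calibration limits against the ICH formulas
#'
#' Recomputes LOD and LOQ from each row's intercept standard deviation and
#' slope and flags rows whose printed limits disagree with the recomputation
#' by more than `tol` (relative). For the 5-fluorouracil reference table the
#' beta-cyclodextrin column is internally inconsistent (its printed
#' sigma/slope pair cannot yield its printed LOD under 3.3 sigma/S) and is
#' flagged, not corrected; the alpha LOQ shows a smaller printed/recomputed
#' mismatch and is flagged too.
#'
#' @param stats_df A data frame with columns `cd_type`, `slope`,
#'   `sd_intercept`, `lod_M`, `loq_M` (default [fu_calibration_table()]).
#' @param tol Relative tolerance for agreement, default 0.02.
#' @return The input with columns `lod_recomputed`, `loq_recomputed`,
#'   `lod_consistent`, `loq_consistent`, `flag`.
#' @export
#' @examples
#' check_ich_consistency()[, c("cd_type", "lod_recomputed", "flag")]
check_ich_consistency <- function(stats_df = fu_calibration_table(), tol = 0.02) {
  out <- stats_df
  out$lod_recomputed <- lod(stats_df$sd_intercept, stats_df$slope)
  out$loq_recomputed <- loq(stats_df$sd_intercept, stats_df$slope)
  out$lod_consistent <- abs(out$lod_recomputed - stats_df$lod_M) <= tol * stats_df$lod_M
  out$loq_consistent <- abs(out$loq_recomputed - stats_df$loq_M) <= tol * stats_df$loq_M
  out$flag <- ifelse(out$lod_consistent & out$loq_consistent, "",
                     "printed limits inconsistent with 3.3/10 sigma/S from printed sigma and slope")
  out
}
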