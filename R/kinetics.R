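# First-order photolysis kinetics: primary log-linear fits of single time
# courses, secondary regression of kobs on cyclodextrin concentration, and
# rate--pH profiles.

#' Construct a photolysis time course
#'
#' A single irradiation experiment: remaining-drug responses sampled over time
#' at fixed pH, cyclodextrin type and concentration. Responses must be
#' strictly positive because the first-order fit works in log space.
#'
#' @param times Sampling times in minutes, non-negative and strictly
#'   increasing, at least 3 points.
#' @param responses Remaining-drug signal (peak area, absorbance, ...),
#'   strictly positive, same length as `times`.
#' @param pH Solution pH (0--14).
#' @param cd_type One of `"none"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @param cd_conc Cyclodextrin concentration in mol/L.
#' @param initial_conc Nominal drug concentration in mol/L (default 5e-5).
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, responses, pH = 7, cd_type = "none",
                        cd_conc = 0, initial_conc = 5e-5) {
  times <- as.numeric(times)
  responses <- as.numeric(responses)
  if (length(times) < 3L) stopf("a time course needs at least 3 points, got %d", length(times))
  if (length(times) != length(responses))
    stopf("times (%d) and responses (%d) differ in length", length(times), length(responses))
  if (any(times < 0)) stopf("negative sampling time: %g min", min(times))
  if (any(diff(times) <= 0)) stopf("sampling times must be strictly increasing")
  if (any(responses <= 0))
    stopf("non-positive response at t = %g min; log-linear fitting requires responses > 0",
          times[which(responses <= 0)[1]])
  if (pH < 0 || pH > 14) stopf("pH %g outside [0, 14]", pH)
  cd_type <- match.arg(cd_type, c("none", "alpha", "beta", "gamma"))
  if (cd_conc < 0) stopf("negative cyclodextrin concentration")
  structure(list(times = times, responses = responses, pH = pH,
                 cd_type = cd_type, cd_conc = cd_conc,
                 initial_conc = initial_conc),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Photolysis time course: %d points over %g min (pH %g, %s%s)\n",
              length(x$times), max(x$times), x$pH, x$cd_type,
              if (x$cd_type == "none") "" else sprintf(" %.3g M", x$cd_conc)))
  invisible(x)
}

#' Fit a first-order photodegradation rate constant
#'
#' Ordinary least squares of log response on time; the apparent first-order
#' rate constant kobs is the negated slope (k0 when no cyclodextrin is
#' present). The standard error of kobs comes from the usual OLS slope
#' variance.
#'
#' @param tc A [time_course()].
#' @return An object of class `rate_fit` with elements `k` (min^-1),
#'   `ln_intercept`, `r_squared`, `se_k`, `n_points`, plus the identifying
#'   metadata (`pH`, `cd_type`, `cd_conc`) carried over from the time course.
#' @seealso [fit_interaction()] for the secondary regression of kobs on
#'   cyclodextrin concentration.
#' @export
#' @examples
#' tc <- time_course(seq(0, 500, 100), 100 * exp(-2e-3 * seq(0, 500, 100)))
#' fit <- fit_first_order(tc)
#' coef(fit)
fit_first_order <- function(tc) {
  if (!inherits(tc, "time_course")) tc <- do.call(time_course, as.list(tc))
  df <- data.frame(t = tc$times, y = log(tc$responses))
  fit <- stats::lm(y ~ t, data = df)
  cf <- suppressWarnings(summary(fit))$coefficients
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((df$y - mean(df$y))^2)
  r2 <- if (tss < .Machine$double.eps * max(1, abs(mean(df$y)))^2) 1 else 1 - rss / tss
  se <- cf["t", "Std. Error"]
  if (!is.finite(se)) se <- 0
  structure(list(k = -unname(stats::coef(fit)[["t"]]),
                 ln_intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = max(0, min(1, r2)),
                 se_k = se,
                 n_points = nrow(df),
                 pH = tc$pH, cd_type = tc$cd_type, cd_conc = tc$cd_conc,
                 lm = fit),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("First-order rate fit (pH %g, %s%s)\n", x$pH, x$cd_type,
              if (x$cd_type == "none") "" else sprintf(" %.3g M", x$cd_conc)))
  cat(sprintf("  k = %.4g min^-1 (SE %.3g), r^2 = %.5f, n = %d\n",
              x$k, x$se_k, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(k = object$k, ln_intercept = object$ln_intercept)
}

#' @export
predict.rate_fit <- function(object, times, ...) {
  exp(object$ln_intercept - object$k * times)
}

#' @export
residuals.rate_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
summary.rate_fit <- function(object, ...) {
  cat(sprintf(
    "First-order photodegradation fit\n  kobs       %.6g min^-1\n  SE(kobs)   %.3g\n  half-life  %.4g min\n  r^2        %.6f\n  points     %d\n",
    object$k, object$se_k, log(2) / object$k, object$r_squared, object$n_points))
  invisible(object)
}

#' Fit the second-order photochemical interaction constant k2
#'
#' Secondary regression: ordinary least squares of kobs on cyclodextrin
#' concentration. The stabilization model is kobs = k0 - k2 [CD], so k2 is the
#' negated slope and the intercept estimates the cyclodextrin-free rate
#' constant. Values are kept unrounded; round only for display.
#'
#' @param cd_concs Cyclodextrin concentrations in mol/L, at least 3, distinct.
#' @param kobs Apparent first-order rate constants (min^-1), same length.
#' @param pH,cd_type Identifying metadata carried into the result.
#' @return An object of class `interaction_fit` with elements `k2`
#'   (M^-1 min^-1), `k_at_zero_cd` (min^-1), `r_squared`, `se_k2`, `pH`,
#'   `cd_type`.
#' @export
#' @examples
#' tab <- fu_rate_table()
#' g12 <- tab[tab$ph == 12 & tab$cd_type == "gamma", ]
#' fit <- fit_interaction(g12$cd_conc_M, g12$kobs_per_min, 12, "gamma")
#' round(fit$k2, 2)  # 2.14
fit_interaction <- function(cd_concs, kobs, pH = NA_real_, cd_type = NA_character_) {
  cd_concs <- as.numeric(cd_concs)
  kobs <- as.numeric(kobs)
  if (length(cd_concs) < 3L)
    stopf("k2 regression needs at least 3 (conc, kobs) pairs, got %d", length(cd_concs))
  if (length(cd_concs) != length(kobs)) stopf("cd_concs and kobs differ in length")
  if (anyDuplicated(cd_concs))
    stopf("duplicate cyclodextrin concentration %.3g M makes the design singular",
          cd_concs[duplicated(cd_concs)][1])
  fit <- stats::lm(kobs ~ cd_concs)
  cf <- suppressWarnings(summary(fit))$coefficients
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((kobs - mean(kobs))^2)
  r2 <- if (tss <= 0) 1 else 1 - rss / tss
  se <- cf["cd_concs", "Std. Error"]
  if (!is.finite(se)) se <- 0
  structure(list(k2 = -unname(stats::coef(fit)[["cd_concs"]]),
                 k_at_zero_cd = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = max(0, min(1, r2)),
                 se_k2 = se,
                 n_points = length(kobs),
                 pH = pH, cd_type = cd_type, lm = fit),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Interaction fit%s%s: k2 = %.2f M^-1 min^-1 (SE %.3g), k(0 CD) = %.3g min^-1, r^2 = %.4f\n",
              if (is.na(x$pH)) "" else sprintf(" pH %g", x$pH),
              if (is.na(x$cd_type)) "" else sprintf(" %s-CD", x$cd_type),
              x$k2, x$se_k2, x$k_at_zero_cd, x$r_squared))
  invisible(x)
}

#' @export
coef.interaction_fit <- function(object, ...) {
  c(k2 = object$k2, k_at_zero_cd = object$k_at_zero_cd)
}

#' @export
predict.interaction_fit <- function(object, cd_concs, ...) {
  object$k_at_zero_cd - object$k2 * cd_concs
}

#' Assemble a rate--pH profile
#'
#' Collects first-order rate fits (or a plain kobs table) into a profile
#' indexed by pH, cyclodextrin type and concentration. Missing grid cells are
#' permitted; duplicated cells must agree or an error names the conflict.
#'
#' @param rate_fits Either a list of `rate_fit` objects or a data frame with
#'   columns `ph`, `cd_type`, `cd_conc_M`, `kobs_per_min` (the kobs CSV
#'   schema).
#' @return An object of class `ph_profile`: a data frame sorted by pH with one
#'   row per (pH, cd_type, cd_conc_M) cell.
#' @export
#' @examples
#' prof <- build_profile(fu_rate_table())
#' minimum_rate_ph(prof, cd_type = "none")
build_profile <- function(rate_fits) {
  if (is.data.frame(rate_fits)) {
    need <- c("ph", "cd_type", "cd_conc_M", "kobs_per_min")
    miss <- setdiff(need, names(rate_fits))
    if (length(miss)) stopf("profile table lacks column(s): %s", paste(miss, collapse = ", "))
    df <- rate_fits[need]
  } else {
    if (!length(rate_fits) || !all(vapply(rate_fits, inherits, TRUE, "rate_fit")))
      stopf("build_profile expects rate_fit objects or a kobs data frame")
    df <- do.call(rbind, lapply(rate_fits, function(f) {
      data.frame(ph = f$pH, cd_type = f$cd_type, cd_conc_M = f$cd_conc,
                 kobs_per_min = f$k)
    }))
  }
  key <- paste(df$ph, df$cd_type, signif(df$cd_conc_M, 12))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    vals <- split(df$kobs_per_min, key)
    bad <- names(vals)[vapply(vals, function(v) max(v) - min(v) > 1e-12 * max(abs(v), 1), TRUE)]
    if (length(bad))
      stopf("conflicting duplicate kobs entries for cell (%s)", bad[1])
    df <- df[!duplicated(key), ]
  }
  if (length(unique(df$ph)) < 2L)
    stopf("a pH profile needs at least 2 distinct pH values")
  df <- df[order(df$ph, df$cd_type, df$cd_conc_M), ]
  rownames(df) <- NULL
  class(df) <- c("ph_profile", "data.frame")
  df
}

#' @export
print.ph_profile <- function(x, ...) {
  cat(sprintf("Rate-pH profile: %d cells, pH %g-%g, series: %s\n",
              nrow(x), min(x$ph), max(x$ph),
              paste(unique(x$cd_type), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' @export
plot.ph_profile <- function(x, ...) {
  sel <- split(as.data.frame(x), paste(x$cd_type, x$cd_conc_M))
  cols <- seq_along(sel)
  plot(NA, xlim = range(x$ph), ylim = range(x$kobs_per_min) * c(0, 1.05),
       xlab = "pH", ylab = expression(k[obs] ~ (min^-1)),
       main = "Rate-pH profile", ...)
  for (i in seq_along(sel)) {
    s <- sel[[i]][order(sel[[i]]$ph), ]
    graphics::lines(s$ph, s$kobs_per_min, col = cols[i], type = "b", pch = 16)
  }
  invisible(x)
}

#' Locate the pH of minimum photodegradation rate
#'
#' Picks the grid pH with the smallest rate constant for one series of a
#' profile (e.g. the cyclodextrin-free k0 column). Ties are broken toward the
#' lower pH and reported via the `tie` flag — the practically relevant answer
#' for choosing a formulation pH.
#'
#' @param profile A [build_profile()] result.
#' @param cd_type Series selector, default `"none"` (the k0 column).
#' @param cd_conc Optional concentration selector; when `NULL` all
#'   concentrations of the chosen cyclodextrin are pooled by their per-pH
#'   minimum.
#' @return A list of class `min_rate_ph`: `ph`, `k`, `tie`.
#' @export
minimum_rate_ph <- function(profile, cd_type = "none", cd_conc = NULL) {
  stopifnot(inherits(profile, "ph_profile"))
  df <- as.data.frame(profile)
  df <- df[df$cd_type == cd_type, ]
  if (!is.null(cd_conc)) df <- df[abs(df$cd_conc_M - cd_conc) < 1e-15, ]
  if (!nrow(df)) stopf("no profile cells match cd_type = '%s'", cd_type)
  k_by_ph <- tapply(df$kobs_per_min, df$ph, min)
  if (length(k_by_ph) < 2L) stopf("selected series present at fewer than 2 pH values")
  ph <- as.numeric(names(k_by_ph))
  kmin <- min(k_by_ph)
  at <- ph[k_by_ph <= kmin * (1 + 1e-12)]
  structure(list(ph = min(at), k = kmin, tie = length(at) > 1L),
            class = "min_rate_ph")
}

#' @export
print.min_rate_ph <- function(x, ...) {
  cat(sprintf("Minimum photodegradation rate at pH %g (k = %.4g min^-1)%s\n",
              x$ph, x$k, if (x$tie) " [tie; lowest pH reported]" else ""))
  invisible(x)
}

#' Percent photostabilization relative to the cyclodextrin-free rate
#'
#' `100 * (k0 - kobs) / k0`; negative when the additive accelerates
#' degradation.
#'
#' @param k0 Rate constant without cyclodextrin (min^-1), > 0.
#' @param kobs Apparent rate constant with cyclodextrin (min^-1).
#' @return Percent stabilization (vectorized over `kobs`).
#' @export
#' @examples
#' stabilization_percent(2.11e-3, 0.85e-3)  # ~59.7
stabilization_percent <- function(k0, kobs) {
  if (any(k0 <= 0)) stopf("k0 must be positive")
  100 * (k0 - kobs) / k0
}
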