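# Complex stoichiometry: Job's continuous-variation analysis and the
# conductometric breakpoint.

#' Construct a Job's continuous-variation series
#'
#' Absorbance change of host/guest mixtures at constant total concentration,
#' as a function of host mole fraction.
#'
#' @param mole_fractions Host mole fractions in (0, 1), strictly increasing,
#'   at least 5 points.
#' @param delta_a Absorbance change at each fraction, >= 0.
#' @return An object of class `job_series`.
#' @export
job_series <- function(mole_fractions, delta_a) {
  mole_fractions <- as.numeric(mole_fractions)
  delta_a <- as.numeric(delta_a)
  if (length(mole_fractions) < 5L)
    stopf("a Job's series needs at least 5 points, got %d", length(mole_fractions))
  if (length(mole_fractions) != length(delta_a)) stopf("fractions and delta_a differ in length")
  if (any(mole_fractions <= 0 | mole_fractions >= 1))
    stopf("mole fractions must lie strictly inside (0, 1)")
  if (any(diff(mole_fractions) <= 0)) stopf("mole fractions must be strictly increasing")
  if (any(delta_a < 0)) stopf("delta_a must be non-negative")
  structure(list(mole_fractions = mole_fractions, delta_a = delta_a),
            class = "job_series")
}

#' @export
print.job_series <- function(x, ...) {
  cat(sprintf("Job's series: %d points, x in [%.3f, %.3f], max dA = %.4g\n",
              length(x$delta_a), min(x$mole_fractions), max(x$mole_fractions),
              max(x$delta_a)))
  invisible(x)
}

#' @export
plot.job_series <- function(x, ...) {
  plot(x$mole_fractions, x$delta_a, type = "b", pch = 16,
       xlab = "host mole fraction", ylab = expression(Delta * A),
       main = "Job's continuous-variation plot", ...)
  invisible(x)
}

#' Locate the Job's-plot maximum and infer complex stoichiometry
#'
#' The grid maximum of the signal, refined by a three-point parabola when the
#' maximum is interior, gives the host mole fraction x at peak complexation;
#' the host:guest ratio follows from `x/(1-x)` (0.5 means 1:1). The peak
#' location is invariant to rescaling the signal.
#'
#' @param series A [job_series()].
#' @return An object of class `job_peak`: `peak_fraction`, `ratio_text`,
#'   `method` (`"grid-max"` or `"parabolic-refine"`).
#' @export
#' @examples
#' cfg <- synthetic_config(noise_cv = 0)
#' jobs_peak(generate_job_series(cfg))
jobs_peak <- function(series) {
  stopifnot(inherits(series, "job_series"))
  x <- series$mole_fractions
  y <- series$delta_a
  if (max(y) - min(y) <= .Machine$double.eps * max(abs(y), 1))
    stopf("signal is flat across all mole fractions; no peak")
  i <- which.max(y)
  method <- "grid-max"
  peak <- x[i]
  if (i > 1L && i < length(x)) {
    # vertex of the parabola through the three points around the grid maximum
    x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
    d1 <- (y3[2] - y3[1]) / (x3[2] - x3[1])
    d2 <- (y3[3] - y3[2]) / (x3[3] - x3[2])
    curv <- (d2 - d1) / (x3[3] - x3[1])
    if (curv < 0) {
      v <- (x3[1] + x3[2]) / 2 - d1 / (2 * curv)
      if (v > x3[1] && v < x3[3]) {
        peak <- v
        method <- "parabolic-refine"
      }
    }
  }
  r <- peak / (1 - peak)
  ratio_text <- if (r >= 1) sprintf("%d : 1", round(r)) else sprintf("1 : %d", round(1 / r))
  structure(list(peak_fraction = peak, ratio_text = ratio_text, method = method),
            class = "job_peak")
}

#' @export
print.job_peak <- function(x, ...) {
  cat(sprintf("Job's-plot peak at mole fraction %.3f (%s) -> %s host : guest complex\n",
              x$peak_fraction, x$method, x$ratio_text))
  invisible(x)
}

#' Construct a conductometric titration series
#'
#' Solution conductivity as a function of cyclodextrin concentration added to
#' a fixed drug concentration.
#'
#' @param concs Cyclodextrin concentrations in mol/L, strictly increasing, at
#'   least 6 points.
#' @param conductivity Conductivity in uS/cm.
#' @return An object of class `conductivity_series`.
#' @export
conductivity_series <- function(concs, conductivity) {
  concs <- as.numeric(concs)
  conductivity <- as.numeric(conductivity)
  if (length(concs) < 6L)
    stopf("a conductivity series needs at least 6 points, got %d", length(concs))
  if (length(concs) != length(conductivity)) stopf("concs and conductivity differ in length")
  if (any(diff(concs) <= 0)) stopf("concentrations must be strictly increasing")
  structure(list(concs = concs, conductivity = conductivity),
            class = "conductivity_series")
}

#' @export
print.conductivity_series <- function(x, ...) {
  cat(sprintf("Conductivity series: %d points, [CD] %.3g-%.3g M\n",
              length(x$concs), min(x$concs), max(x$concs)))
  invisible(x)
}

#' Fit a two-segment conductometric breakpoint
#'
#' Exhaustive search over interior candidate breakpoints (each observed
#' concentration with at least 3 points on either side) of the continuous
#' two-segment piecewise-linear least-squares fit. The SSE-minimizing
#' candidate is the equivalence point of complex formation. When the
#' two-segment model does not reduce the single-line SSE by at least 20%, the
#' break is flagged as not significant (a single line explains the data).
#'
#' @param series A [conductivity_series()].
#' @return An object of class `breakpoint_fit`: `breakpoint` (mol/L),
#'   `slope1`, `slope2` (uS cm^-1 M^-1), `intercept`, `sse`, `sse_single`,
#'   `significant`.
#' @export
#' @examples
#' x <- seq(0, 3.2e-3, 4e-4)
#' y <- 180 - 2.4e4 * pmin(x, 2e-3) - 6e3 * pmax(x - 2e-3, 0)
#' fit_breakpoint(conductivity_series(x, y))
fit_breakpoint <- function(series) {
  stopifnot(inherits(series, "conductivity_series"))
  x <- series$concs
  y <- series$conductivity
  n <- length(x)
  cand_idx <- 3:(n - 2)
  single <- stats::lm(y ~ x)
  sse_single <- sum(stats::residuals(single)^2)
  best <- NULL
  for (i in cand_idx) {
    cb <- x[i]
    hinge <- pmax(x - cb, 0)
    fit <- stats::lm(y ~ x + hinge)
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(breakpoint = cb, sse = sse,
                   intercept = unname(cf[["(Intercept)"]]),
                   slope1 = unname(cf[["x"]]),
                   slope2 = unname(cf[["x"]]) + unname(cf[["hinge"]]))
    }
  }
  scale <- max(sum(y^2), .Machine$double.eps)
  significant <- if (sse_single <= 1e-18 * scale) FALSE else
    (sse_single - best$sse) / sse_single >= 0.20
  structure(c(best, list(sse_single = sse_single, significant = significant,
                         n_points = n)),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$significant) {
    cat(sprintf("Conductometric breakpoint at %.4g M (slopes %.4g / %.4g uS cm^-1 M^-1)\n",
                x$breakpoint, x$slope1, x$slope2))
  } else {
    cat("No significant conductometric break: a single line explains the data\n")
    cat(sprintf("  (best candidate %.4g M; SSE improvement below 20%%)\n", x$breakpoint))
  }
  invisible(x)
}

#' @export
coef.breakpoint_fit <- function(object, ...) {
  c(breakpoint = object$breakpoint, intercept = object$intercept,
    slope1 = object$slope1, slope2 = object$slope2)
}

#' @export
predict.breakpoint_fit <- function(object, concs, ...) {
  object$intercept + object$slope1 * concs +
    (object$slope2 - object$slope1) * pmax(concs - object$breakpoint, 0)
}
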