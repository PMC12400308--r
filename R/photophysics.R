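# Fluorescence-based complexation analysis: Stern-Volmer quenching, the
# double-logarithmic binding model, percent fluorescence loss and entrapment
# efficiency.

#' Construct a fluorescence quenching series
#'
#' Fluorescence intensities of the drug measured at increasing quencher
#' (cyclodextrin) concentrations, together with the quencher-free intensity
#' F0.
#'
#' @param quencher_concs Quencher concentrations in mol/L, strictly
#'   increasing, positive.
#' @param f Fluorescence at each concentration; `0 < f <= f0`.
#' @param f0 Quencher-free fluorescence.
#' @param pH Solution pH.
#' @return An object of class `quenching_series`.
#' @export
quenching_series <- function(quencher_concs, f, f0, pH = 7) {
  quencher_concs <- as.numeric(quencher_concs)
  f <- as.numeric(f)
  if (!length(quencher_concs)) stopf("empty quencher concentration list")
  if (length(quencher_concs) != length(f)) stopf("concs and f differ in length")
  if (any(quencher_concs <= 0)) stopf("quencher concentrations must be positive")
  if (any(diff(quencher_concs) <= 0)) stopf("quencher concentrations must be strictly increasing")
  if (!is_number(f0) || f0 <= 0) stopf("f0 must be a positive number")
  if (any(f <= 0)) stopf("fluorescence must be positive (got %g)", min(f))
  if (any(f > f0 * (1 + 1e-9)))
    stopf("fluorescence exceeds the quencher-free value F0 at [Q] = %g M",
          quencher_concs[which(f > f0)[1]])
  structure(list(quencher_concs = quencher_concs, f = f, f0 = f0, pH = pH),
            class = "quenching_series")
}

#' @export
print.quenching_series <- function(x, ...) {
  cat(sprintf("Quenching series: %d points, [Q] %.3g-%.3g M, F0 = %g (pH %g)\n",
              length(x$f), min(x$quencher_concs), max(x$quencher_concs),
              x$f0, x$pH))
  invisible(x)
}

#' Stern--Volmer quenching fit
#'
#' Ordinary least squares of F0/F on quencher concentration. The Stern--Volmer
#' constant Ksv is the slope; the intercept is estimated freely and should sit
#' near the model value of 1 — a deviation beyond 0.1 triggers a diagnostic
#' warning (possible static/dynamic mixture or baseline error).
#'
#' @param series A [quenching_series()] with at least 3 points.
#' @return An object of class `quenching_fit`: `ksv` (L/mol), `intercept`,
#'   `r_squared`, `se_ksv`.
#' @export
#' @examples
#' q <- seq(2.5e-4, 1.25e-3, 2.5e-4)
#' s <- quenching_series(q, 100 / (1 + 3.06e3 * q), 100)
#' stern_volmer_fit(s)
stern_volmer_fit <- function(series) {
  stopifnot(inherits(series, "quenching_series"))
  if (length(series$f) < 3L) stopf("Stern-Volmer fit needs at least 3 points")
  ratio <- series$f0 / series$f
  q <- series$quencher_concs
  fit <- stats::lm(ratio ~ q)
  cf <- suppressWarnings(summary(fit))$coefficients
  se <- cf["q", "Std. Error"]
  if (!is.finite(se)) se <- 0
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ratio - mean(ratio))^2)
  icpt <- unname(stats::coef(fit)[["(Intercept)"]])
  if (abs(icpt - 1) > 0.1)
    warning(sprintf("Stern-Volmer intercept %.3f deviates from 1 by more than 0.1", icpt),
            call. = FALSE)
  structure(list(ksv = unname(stats::coef(fit)[["q"]]),
                 intercept = icpt,
                 r_squared = if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss)),
                 se_ksv = se, n_points = length(q), lm = fit),
            class = "quenching_fit")
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit: Ksv = %.4g L mol^-1 (SE %.3g), intercept = %.4f, r^2 = %.5f\n",
              x$ksv, x$se_ksv, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.quenching_fit <- function(object, ...) {
  c(ksv = object$ksv, intercept = object$intercept)
}

#' @export
predict.quenching_fit <- function(object, quencher_concs, ...) {
  object$intercept + object$ksv * quencher_concs
}

#' Double-logarithmic binding fit
#'
#' Binding of the drug to equivalent cyclodextrin sites:
#' `log10((F0 - F)/F) = log10(K) + n log10([Q])`. Ordinary least squares on the
#' double-log scale gives the number of binding sites n as the slope and the
#' binding constant K as `10^intercept`. Every F must lie strictly below F0
#' (log domain).
#'
#' @param series A [quenching_series()] with at least 3 points.
#' @return An object of class `binding_fit`: `bigK` (L/mol), `n_sites`,
#'   `r_squared`.
#' @export
#' @examples
#' q <- seq(2.5e-4, 1.25e-3, 2.5e-4)
#' s <- quenching_series(q, 100 / (1 + 3.62e3 * q^1.03), 100)
#' binding_fit(s)
binding_fit <- function(series) {
  stopifnot(inherits(series, "quenching_series"))
  if (length(series$f) < 3L) stopf("binding fit needs at least 3 points")
  at_f0 <- series$f >= series$f0
  if (any(at_f0))
    stopf("F equals F0 at [Q] = %g M; log(F0-F) undefined there",
          series$quencher_concs[which(at_f0)[1]])
  y <- log10((series$f0 - series$f) / series$f)
  x <- log10(series$quencher_concs)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(bigK = 10^unname(stats::coef(fit)[["(Intercept)"]]),
                 n_sites = unname(stats::coef(fit)[["x"]]),
                 r_squared = if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss)),
                 n_points = length(x), lm = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit: K = %.4g L mol^-1, n = %.3f sites, r^2 = %.5f\n",
              x$bigK, x$n_sites, x$r_squared))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(bigK = object$bigK, n_sites = object$n_sites)
}

#' Percent fluorescence loss on complexation
#'
#' `100 * (f0 - f) / f0`: the fraction of drug fluorescence quenched at a
#' given cyclodextrin concentration.
#'
#' @param f0 Quencher-free fluorescence, > 0.
#' @param f Fluorescence in the presence of quencher (vectorized).
#' @return Percent loss in `[0, 100]` for valid series.
#' @export
percent_fluorescence_loss <- function(f0, f) {
  if (any(f0 <= 0)) stopf("f0 must be positive")
  100 * (f0 - f) / f0
}

#' Entrapment efficiency from non-entrapped fluorescence
#'
#' `100 * (f0 - f_free) / f0`, where `f_free` is the fluorescence of the
#' drug remaining free in solution after complexation. Arithmetically the same
#' form as [percent_fluorescence_loss()], but the inputs are distinct
#' measurements: f here is the non-entrapped fraction's signal, not the
#' quenched total.
#'
#' @param f0 Fluorescence before entrapment, > 0.
#' @param f_free Fluorescence of the non-entrapped drug, `0 <= f_free <= f0`.
#' @return Entrapment efficiency in percent.
#' @export
#' @examples
#' entrapment_efficiency(100, 23)  # 77
entrapment_efficiency <- function(f0, f_free) {
  if (any(f0 <= 0)) stopf("f0 must be positive")
  if (any(f_free < 0)) stopf("negative non-entrapped fluorescence")
  if (any(f_free > f0))
    stopf("non-entrapped fluorescence (%g) exceeds the pre-entrapment value (%g)",
          max(f_free), min(f0))
  100 * (f0 - f_free) / f0
}
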