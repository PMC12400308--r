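# Independent oracles used across tests. Deliberately written from first
# principles (sum formulas, root finding, exhaustive scans) so they share no
# code path with the package's lm-based fits.

# Closed-form two-parameter OLS: slope, intercept and their standard errors.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se_slope <- sqrt(n * s2 / denom)
  se_intercept <- sqrt(s2 * sxx / denom)
  list(slope = slope, intercept = intercept,
       se_slope = se_slope, se_intercept = se_intercept)
}

# Profile-likelihood grid scan for the first-order rate constant: for each
# candidate k the intercept is profiled out analytically, and the SSE in log
# space is minimised by golden-section refinement of the best grid cell.
rate_scan_oracle <- function(times, responses, k_lo, k_hi, n_grid = 2000) {
  y <- log(responses)
  sse <- function(k) {
    a <- mean(y + k * times)
    sum((y - (a - k * times))^2)
  }
  ks <- seq(k_lo, k_hi, length.out = n_grid)
  best <- ks[which.min(vapply(ks, sse, numeric(1)))]
  stats::optimize(sse, c(best - diff(range(ks)) / n_grid,
                         best + diff(range(ks)) / n_grid), tol = 1e-12)$minimum
}

# Numeric 1:1 equilibrium: root of K (H - c)(G - c) = c on [0, min(H, G)].
equilibrium_oracle <- function(H, G, K) {
  f <- function(c) K * (H - c) * (G - c) - c
  stats::uniroot(f, c(0, min(H, G)), tol = 1e-15)$root
}

# Exhaustive two-segment piecewise-linear least squares via explicit normal
# equations (3 unknowns: intercept, slope1, slope jump), one solve per
# candidate breakpoint.
breakpoint_oracle <- function(x, y) {
  n <- length(x)
  best <- NULL
  for (i in 3:(n - 2)) {
    h <- pmax(x - x[i], 0)
    X <- cbind(1, x, h)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sse <- sum((y - X %*% beta)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(breakpoint = x[i], sse = sse, beta = drop(beta))
  }
  best
}
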