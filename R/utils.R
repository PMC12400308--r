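# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's `.Random.seed`,
#' so generators are deterministic without disturbing user code.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a per-series seed from a master seed and a series key
#'
#' One independent stream per generated series: the key (series type plus its
#' identifying parameters) is hashed and folded into the master seed. Result
#' is kept below 2^31 so it is a valid R integer seed.
#' @noRd
series_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483587L
}

# Multiplicative lognormal noise with unit mean and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
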