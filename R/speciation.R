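# Monoprotic acid-base speciation. 5-Fluorouracil ionizes at N1 (pKa ~ 8.0)
# to an anion and forms no cationic species, so a two-species treatment
# (neutral vs anionic) covers the whole pH range of interest.

#' Acid-base species fractions of a monoprotic drug
#'
#' Henderson--Hasselbalch fractions of the neutral (protonated) and anionic
#' (deprotonated) forms: `f_anion = 1 / (1 + 10^(pka - pH))` and
#' `f_neutral = 1 - f_anion`. Vectorized over `pH`.
#'
#' @param pH Solution pH (advisory range 0--14); may be a vector.
#' @param pka Ionization constant, default 8.0 (N1 deprotonation of
#'   5-fluorouracil).
#' @return A data frame of class `species_fractions` with columns `pH`,
#'   `pka`, `f_neutral`, `f_anion`.
#' @export
#' @examples
#' species_fractions(12, pka = 8)   # anion fraction 0.9999
#' species_fractions(2:12)
species_fractions <- function(pH, pka = 8.0) {
  pH <- as.numeric(pH)
  if (!is_number(pka)) stopf("pka must be a single finite number")
  r <- 10^(pka - pH)
  out <- data.frame(pH = pH, pka = pka,
                    f_neutral = r / (1 + r),
                    f_anion = 1 / (1 + r))
  class(out) <- c("species_fractions", "data.frame")
  out
}

#' @export
print.species_fractions <- function(x, ...) {
  df <- as.data.frame(x)
  df$f_neutral <- signif(df$f_neutral, 6)
  df$f_anion <- signif(df$f_anion, 6)
  cat(sprintf("Monoprotic speciation (pKa %.2f):\n", x$pka[1]))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
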