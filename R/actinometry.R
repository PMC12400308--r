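# Actinometric photon-flux bookkeeping and quantum-yield computation. The
# lamp is characterised by the emission areas of its five mercury bands; the
# drug absorbs the 254 and 313 nm bands.

LAMP_BANDS <- c(254, 313, 366, 405, 436)
AVOGADRO <- 6.02214076e23

#' Construct a lamp emission spectrum summary
#'
#' Emission-band areas of a low-pressure mercury (TUV) tube at the five
#' standard lines, plus the actinometrically measured total intensity in
#' quanta per second.
#'
#' @param band_areas Numeric vector of 5 non-negative areas (arbitrary units)
#'   for the 254, 313, 366, 405 and 436 nm bands, in that order (or named).
#' @param intensity_quanta Photon flux Q in quanta/s, > 0. Default 5.50e18, a
#'   typical ferrioxalate-actinometry value for a 30 W TUV tube.
#' @return An object of class `lamp_spectrum`.
#' @export
lamp_spectrum <- function(band_areas, intensity_quanta = 5.50e18) {
  band_areas <- as.numeric(band_areas)
  if (length(band_areas) != 5L)
    stopf("expected 5 band areas (254, 313, 366, 405, 436 nm), got %d", length(band_areas))
  if (any(band_areas < 0)) stopf("band areas must be non-negative")
  if (all(band_areas == 0)) stopf("at least one band area must be positive")
  if (!is_number(intensity_quanta) || intensity_quanta <= 0)
    stopf("intensity_quanta must be positive")
  structure(list(band_wavelengths = LAMP_BANDS, band_areas = band_areas,
                 intensity_quanta = intensity_quanta),
            class = "lamp_spectrum")
}

#' @export
print.lamp_spectrum <- function(x, ...) {
  cat(sprintf("Lamp spectrum: Q = %.3g quanta/s (%.3g einstein/s)\n",
              x$intensity_quanta, quanta_to_einstein(x$intensity_quanta)))
  cat("  band areas:", paste(sprintf("%gnm=%.3g", x$band_wavelengths, x$band_areas),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Convert a photon flux from quanta/s to einstein/s
#'
#' One einstein is one mole of photons, so this divides by the Avogadro
#' constant. Note that 5.50e18 quanta/s corresponds to 9.13e-6 einstein/s;
#' actinometric intensities quoted as order-of-magnitude-1 "einstein/s" values
#' usually carry an implicit 1e-6 scale.
#'
#' @param q Photon flux in quanta/s, >= 0.
#' @return Flux in einstein/s.
#' @export
#' @examples
#' quanta_to_einstein(5.50e18)  # 9.13e-6
quanta_to_einstein <- function(q) {
  if (any(q < 0)) stopf("photon flux cannot be negative")
  q / AVOGADRO
}

#' Fraction of lamp emission absorbed by the drug
#'
#' The ratio R of the summed areas of the absorbed emission bands to the total
#' area of all five bands. For 5-fluorouracil (absorption maximum 266 nm) the
#' absorbed bands are 254 and 313 nm.
#'
#' @param spec A [lamp_spectrum()].
#' @param absorbed_bands Wavelengths (nm) of the absorbed bands, a subset of
#'   the five lamp bands. Default `c(254, 313)`.
#' @return The absorbed fraction R in `[0, 1]`.
#' @export
absorbed_ratio <- function(spec, absorbed_bands = c(254, 313)) {
  stopifnot(inherits(spec, "lamp_spectrum"))
  bad <- setdiff(absorbed_bands, spec$band_wavelengths)
  if (length(bad)) stopf("unknown emission band(s): %s nm", paste(bad, collapse = ", "))
  total <- sum(spec$band_areas)
  if (total <= 0) stopf("total emission area is zero")
  sum(spec$band_areas[spec$band_wavelengths %in% absorbed_bands]) / total
}

#' Quantum yield of photodegradation
#'
#' Standard photochemical definition: the initial degradation rate in moles
#' per second divided by the absorbed photon flux in einstein per second,
#'
#' \deqn{\Phi = \frac{(k/60)\, C\, V}{(Q/N_A)\, R}}
#'
#' with k the first-order rate constant (min^-1), C the drug concentration
#' (mol/L), V the irradiated volume (L), Q the lamp intensity (quanta/s) and R
#' the absorbed-band area fraction. Published quantum-yield tables computed
#' from unreported band areas cannot be regenerated from rate constants alone;
#' the result's `note` field records that caveat for reports.
#'
#' @param rate A `rate_fit` or a bare rate constant in min^-1, > 0.
#' @param drug_conc Drug concentration in mol/L, > 0. Default 5e-5.
#' @param volume Irradiated volume in litres, > 0. Default 0.1 (100 ml
#'   beaker).
#' @param spec A [lamp_spectrum()].
#' @param absorbed_bands Passed to [absorbed_ratio()].
#' @return An object of class `quantum_yield_result`: `phi`, `r_ratio`,
#'   `absorbed_flux` (einstein/s), `note`.
#' @export
#' @examples
#' spec <- lamp_spectrum(rep(1, 5))
#' quantum_yield(1.85e-3, drug_conc = 5e-5, volume = 0.1, spec = spec)
quantum_yield <- function(rate, drug_conc = 5e-5, volume = 0.1, spec,
                          absorbed_bands = c(254, 313)) {
  k <- if (inherits(rate, "rate_fit")) rate$k else as.numeric(rate)
  if (!is_number(k) || k <= 0) stopf("rate constant must be positive")
  if (!is_number(drug_conc) || drug_conc <= 0) stopf("drug_conc must be positive")
  if (!is_number(volume) || volume <= 0) stopf("volume must be positive")
  r <- absorbed_ratio(spec, absorbed_bands)
  if (r <= 0) stopf("absorbed fraction R is zero; quantum yield undefined")
  flux <- quanta_to_einstein(spec$intensity_quanta) * r
  phi <- (k / 60) * drug_conc * volume / flux
  structure(list(phi = phi, r_ratio = r, absorbed_flux = flux, k = k,
                 note = paste("Phi computed as initial rate over absorbed photon",
                              "flux; published Phi values derived from unreported",
                              "band areas are not reproducible from k alone.")),
            class = "quantum_yield_result")
}

#' @export
print.quantum_yield_result <- function(x, ...) {
  cat(sprintf("Quantum yield: Phi = %.4g (R = %.3f, absorbed flux = %.3g einstein/s)\n",
              x$phi, x$r_ratio, x$absorbed_flux))
  cat(" ", strwrap(x$note, 70, prefix = " "), sep = "\n")
  invisible(x)
}
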