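# photostab

Quantitative analysis of drug photostabilization by cyclodextrin inclusion
complexation, built for the 5-fluorouracil (5-FU) / α-, β-, γ-cyclodextrin
system but applicable to any photolabile drug stabilized by a host additive.

Photolabile drugs such as 5-FU degrade under UV light by first-order
kinetics. Entrapment in a cyclodextrin cavity slows the photoreaction, and
the whole stabilization story is quantified by a small family of linear
models:

- **Kinetics.** Each irradiation time course gives an apparent first-order
  rate constant from the log-linear fit `ln R(t) = ln R₀ − kobs·t`. Across a
  cyclodextrin concentration series, `kobs = k₀ − k₂·[CD]`: the negated slope
  k₂ (M⁻¹·min⁻¹) is the second-order photochemical interaction constant —
  larger k₂, stronger photostabilization. Rate constants assembled across pH
  give the U-shaped kobs–pH profile whose minimum is the formulation pH.
- **Photophysics.** Cyclodextrins quench 5-FU fluorescence: the Stern–Volmer
  fit `F₀/F = 1 + Ksv·[Q]` gives the quenching constant, and the double-log
  binding model `log₁₀((F₀−F)/F) = log₁₀K + n·log₁₀[Q]` gives the binding
  constant K and site number n. Entrapment efficiency is
  `100·(F₀ − F_free)/F₀`.
- **Stoichiometry.** Job's continuous-variation series (signal maximum at
  host mole fraction 0.5 ⇒ 1:1 complex) and the conductometric two-segment
  breakpoint, found by exhaustive continuous piecewise-linear least squares.
- **Actinometry.** Photon flux in quanta/s converts to einstein/s via the
  Avogadro constant; the quantum yield is the initial degradation rate over
  the absorbed photon flux, `Φ = (k/60)·C·V / ((Q/N_A)·R)`, with R the
  absorbed fraction of the lamp's emission-band areas.
- **Speciation.** Henderson–Hasselbalch fractions of the neutral and anionic
  forms (pKa 8.0 by default).
- **Assay validation.** ICH-style calibration statistics: OLS linearity with
  standard errors, LOD = 3.3σ/S, LOQ = 10σ/S, accuracy and precision.

Every fitting function returns a classed S3 object with `print`, `coef` and
(where meaningful) `predict` methods. A seeded synthetic-data generator
(`synthetic_config()` + `generate_*()`) emulates every input series, so the
full pipeline runs and is testable without instrument data. Reference tables
for the 5-FU/cyclodextrin system ship as `fu_rate_table()`,
`fu_interaction_table()`, `fu_quenching_table()` and
`fu_calibration_table()`.

## Worked example

Refit the γ-cyclodextrin kobs series at pH 12 from the reference grid, and
recover the complexation parameters from noiseless synthetic series:

```r
library(photostab)

tab <- fu_rate_table()
g12 <- tab[tab$ph == 12 & tab$cd_type == "gamma", ]
fit_interaction(g12$cd_conc_M, g12$kobs_per_min, pH = 12, cd_type = "gamma")
#> Interaction fit pH 12 gamma-CD: k2 = 2.14 M^-1 min^-1 (SE 0.0792),
#>   k(0 CD) = 0.00527 min^-1, r^2 = 0.9959

minimum_rate_ph(build_profile(tab), cd_type = "none")
#> Minimum photodegradation rate at pH 6 (k = 0.00211 min^-1)

stabilization_percent(2.11e-3, 0.85e-3)   # pH 6, gamma-CD 1.25 mM
#> [1] 59.71564

cfg <- synthetic_config(noise_cv = 0)
stern_volmer_fit(generate_quenching_series(cfg))
#> Stern-Volmer fit: Ksv = 3060 L mol^-1 (SE 5.28e-13), intercept = 1.0000, r^2 = 1.00000
binding_fit(generate_binding_series(cfg))
#> Binding fit: K = 3620 L mol^-1, n = 1.030 sites, r^2 = 1.00000
jobs_peak(generate_job_series(cfg))
#> Job's-plot peak at mole fraction 0.500 (parabolic-refine) -> 1 : 1 host : guest complex

lod(1.35e4, 1.68e10)   # alpha-CD calibration sigma and slope
#> [1] 2.651786e-06
```

Reading these numbers: k₂ = 2.14 M⁻¹·min⁻¹ is the strongest interaction in
the grid (γ-cyclodextrin at pH 12); the drug is most photostable at pH 6,
where 1.25 mM γ-cyclodextrin cuts the degradation rate by ~60%; the
noiseless generators round-trip the quenching constant (3.06 × 10³ L/mol),
binding constant (3.62 × 10³ L/mol) and site number (1.03) exactly, and the
Job's maximum at mole fraction 0.5 confirms the 1:1 complex; the α-CD
detection limit recomputes to 2.65 × 10⁻⁶ M.

The full synthetic pipeline — kinetics through validation, with CSV outputs
and a run log — is one call:

```r
run_pipeline("out/", synthetic_config(seed = 42))
```

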