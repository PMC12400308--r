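---
title: "Models and methods in photostab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in photostab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photostab)
```

photostab quantifies the photostabilization of a photolabile drug — 5-fluorouracil
(5-FU) in the shipped reference tables — by cyclodextrin (CD) inclusion
complexation. This vignette explains each model, its assumptions, the
numerical choices behind the implementation, and what the synthetic-data
generator does and does not emulate.

## Photolysis kinetics

UV photodegradation of 5-FU is first order in the remaining drug, so a time
course obeys $R(t) = R_0 e^{-k_{\mathrm{obs}} t}$. `fit_first_order()`
estimates $k_{\mathrm{obs}}$ by ordinary least squares of $\ln R$ on $t$.
The fit is deliberately **unweighted log-linear OLS** rather than weighted
or nonlinear least squares: apparent rate constants for this system are
conventionally reported from log-linear plots, and the same convention keeps
the primary fit coherent with the secondary regression below, which
validates quantitatively against the published interaction constants.
Nonlinear fitting would weight early time points more heavily and shift
constants by more than the cross-study comparability is worth. Responses
must be strictly positive (log domain); a non-positive response is an error
naming the offending time point, never silently dropped.

Degenerate inputs: a constant series returns $k = 0$ with zero standard
error and $r^2$ defined as 1 (a perfect fit of a constant; the usual
$1 - \mathrm{RSS}/\mathrm{TSS}$ is 0/0 there). Standard errors come from the
standard OLS slope variance; tests check them against closed-form
$\Sigma$-formulas to $10^{-12}$ relative.

Stabilization is linear in CD concentration:
$k_{\mathrm{obs}} = k_0 - k_2\,[\mathrm{CD}]$. `fit_interaction()` regresses
$k_{\mathrm{obs}}$ on $[\mathrm{CD}]$ over the full concentration series
(0.25–1.25 mM in the reference grid) and reports $k_2$ as the negated slope
and the intercept as a consistency check on $k_0$ — across the shipped
reference grid every intercept lands within 10% of the directly measured
$k_0$. Values are never rounded inside computation; the conventional 2-decimal
presentation of $k_2$ is left to display code.

`build_profile()` assembles fits into a rate–pH profile. Duplicate grid
cells must agree to within numerical noise (conflicting duplicates are an
error naming the cell); missing cells are tolerated without imputation, as
partially observed grids are the norm. `minimum_rate_ph()` returns the grid
pH with the smallest rate constant — pH 6.0 for the reference system, the
pH recommended for photostable formulations. Ties break toward lower pH
(the conservative formulation choice, more buffer capacity margin below the
ionization region) and are flagged rather than hidden.

## Fluorescence quenching and binding

CD complexation quenches 5-FU fluorescence. The Stern–Volmer model
$F_0/F = 1 + K_{sv}[Q]$ is fit by OLS with a **free intercept**: the model
value is 1, and estimating it provides a diagnostic — a deviation beyond 0.1
triggers a warning (baseline error, or mixed static/dynamic quenching, which
this package does not attempt to separate). Forcing the intercept would hide
exactly the miscalibration the diagnostic catches.

Binding to $n$ equivalent sites follows the double-logarithmic form
$\log_{10}\frac{F_0-F}{F} = \log_{10}K + n \log_{10}[Q]$. Logarithms are
base 10, the convention for this plot; the slope is the site number and
$10^{\mathrm{intercept}}$ the binding constant. With $n = 1$ the model nests
the Stern–Volmer form exactly, and the tests assert that both fits then
agree to $10^{-9}$ relative. Points with $F = F_0$ have no defined
double-log transform and raise an error naming the concentration.

`percent_fluorescence_loss()` and `entrapment_efficiency()` share the
arithmetic $100\,(F_0 - F)/F_0$ but are distinct operations because their
inputs are distinct measurements: quenched total fluorescence in the first,
the free (non-entrapped) drug's fluorescence in the second. Conflating them
would invite passing the wrong $F$.

## Stoichiometry

`jobs_peak()` locates the maximum of a continuous-variation (Job's) series.
The grid argmax is refined by the vertex of the parabola through the three
surrounding points whenever the maximum is interior and the local curvature
is negative; the refined vertex is trusted only inside the bracketing
interval. On a symmetric noiseless 1:1 series the refinement returns exactly
0.5 — including on even grids with no point at 0.5, where the two equal
maxima flanking 0.5 give a vertex at their midpoint. The host:guest ratio is
read as $\mathrm{round}(x/(1-x)):1$ (inverted below 0.5). A flat signal has
no peak and errors out.

`fit_breakpoint()` finds the conductometric equivalence point by exhaustive
search: every observed concentration with at least 3 points on each side is
a candidate breakpoint, and each candidate gets a continuous two-segment
piecewise-linear least-squares fit (intercept, left slope, slope change at
the hinge). Continuity is enforced because the physical titration curve is a
single curve with a kink, not two disconnected lines. Exhaustive enumeration
over candidates *is* the algorithm — with ≤ 20 points there is nothing to
gain from anything cleverer, and the test oracle re-solves the same normal
equations independently. A two-segment fit that fails to reduce the
single-line SSE by at least 20% is flagged "no significant break"; the 20%
threshold is a logged heuristic, chosen once to reject noise-level
improvements on realistic series, not a formal test.

## Actinometry and quantum yield

`quanta_to_einstein()` divides a photon flux by the Avogadro constant.
Quoted actinometric intensities of order 9.1 "einstein/s" alongside
5.50 × 10¹⁸ quanta/s are dimensionally consistent only with an implicit
10⁻⁶ scale; the package reports 9.13 × 10⁻⁶ einstein/s and the pipeline log
records the unit note.

`quantum_yield()` implements the standard photochemical definition — initial
degradation rate over absorbed photon flux:
$\Phi = \frac{(k/60)\,C\,V}{(Q/N_A)\,R}$, with the absorbed fraction $R$
computed by `absorbed_ratio()` from the lamp's five mercury emission-band
areas (254, 313, 366, 405, 436 nm; 5-FU absorbs the first two). $\Phi$ is
invariant under common rescaling of band areas and scales linearly in $k$,
$C$, $V$ and inversely in $Q$ and $R$; both properties are tested. Published
quantum-yield tables for this system rest on emission-band areas that are
not printed anywhere, so those values are **not claimed reproducible** from
rate constants alone; every `quantum_yield()` result carries a note saying
so, and reports surface it. The default volume is 0.1 L (the 100 ml
irradiation beaker) and the default intensity 5.50 × 10¹⁸ quanta/s.

## Speciation

5-FU ionizes once in the relevant range (N1 deprotonation, pKa 8.0 default)
and forms no cation, so `species_fractions()` is the two-species
Henderson–Hasselbalch form $f_{\mathrm{anion}} = 1/(1+10^{pK_a-\mathrm{pH}})$.
At pH 12 the anion fraction is 99.99%; at pH 2 it is ~10⁻⁴ % — a figure
sometimes mislabelled "cationic" in descriptions of this system; the package
models it as the anion fraction. The second, strongly alkaline uracil
ionization is ignored, matching the two-species treatment the rate–pH
discussion relies on.

## Assay validation

`fit_linearity()` is plain OLS with standard errors and Pearson correlation.
`lod()`/`loq()` are ICH-style $3.3\sigma/S$ and $10\sigma/S$, so
$\mathrm{LOQ} = (10/3.3)\,\mathrm{LOD}$ exactly. The $\sigma$ entering the
limits is the **standard deviation of the intercept across replicate
calibration curves**, not the single-curve standard error of the intercept —
the reference table lists both, and only the SD choice reproduces its
printed α- and γ-CD limits (2.65 × 10⁻⁶ and 1.61 × 10⁻⁶ M). When a series
has replicate structure, `validation_report()` fits each replicate curve and
takes the SD of the intercepts; without replicates the OLS SE stands in and
the report says so. Sample (n−1) standard deviations are used throughout.

`check_ich_consistency()` recomputes the limits from each row's σ and slope
and flags disagreements instead of correcting them. In the shipped reference
table the β-CD row is internally inconsistent (its printed σ of 0.16 × 10⁴
yields LOD 2.5 × 10⁻⁷ M, not the printed 1.64 × 10⁻⁶; a σ of 1.06 × 10⁴
would reproduce both limits, suggesting a transposition), and the α-CD LOQ
prints 8.40 × 10⁻⁶ where 10σ/S gives 8.04 × 10⁻⁶. Both are flagged in the
consistency table and the pipeline log; no silent correction is ever
applied.

## The synthetic-data generator

`synthetic_config()` fixes the study conditions; the `generate_*()` family
draws every series type from them. Defaults are the published reference
values for this system: the full k₀-by-pH column (11 values, pH 2–12), the
pH-6 interaction constants (α 0.28, β 0.71, γ 1.04 M⁻¹·min⁻¹ — the
formulation-relevant pH), the γ-CD quenching and binding parameters
(Ksv = 3.06 × 10³ L/mol, K = 3.62 × 10³ L/mol, n = 1.03), the 0.25–1.25 mM
CD grid, 1.00 × 10⁻⁴ M total Job concentration, a 2.00 mM conductometric
breakpoint, and the γ-CD calibration line (slope 2.56 × 10¹⁰, intercept
8.48 × 10³) with response SD 1.25 × 10⁴ matching the published intercept SD.
Values no reference states were chosen once as field-realistic and are not
tuned: response scales R₀ = F₀ = 100 (arbitrary units), conductivity
baseline 180 µS/cm with segment slopes −2.4 × 10⁴ / −6 × 10³ µS·cm⁻¹·M⁻¹
(decreasing, kink at the equivalence point), Job Δε scale 8000, 6 sampling
points over two half-lives (a sensible design when only "appropriate
intervals" is specified), noise CV 2%, 3 calibration replicates over ten
levels spanning 0.5–5.0 × 10⁻⁵ M.

Noise is **multiplicative lognormal with unit mean** on spectroscopic and
chromatographic responses — such signals have scale-proportional error and
must stay positive, which additive Gaussian noise cannot guarantee in log
space. Calibration responses instead get additive Gaussian noise, because
the intercept-SD-based detection limits are defined for that error model.
Each series hashes its identifying parameters into a per-series seed folded
with the master seed: series are mutually independent streams, any one
series is reproducible in isolation, and generation never perturbs the
caller's global RNG state (all tested).

What the generator does **not** emulate: full UV spectra or chromatograms
(responses are scalar per point), replicate kinetic runs, drifting
baselines, heteroscedasticity beyond the constant-CV model,
non-1:1 equilibria, and buffer-specific catalysis. Passing tests therefore
demonstrate correct model recovery under the stated error model — not
robustness to the pathologies of real instrument data.

## Problem sizes and test design

The suite runs entirely on generated data at the study's own scale: 5-point
concentration series, 6-point time courses, 9-point Job grids, 9-point
conductivity series, 30-point calibrations, with 200-seed repetitions for
the coverage properties (estimates within 3 standard errors of truth at
least 90% of the time under 2% CV noise). Oracles are independent of the
fitting path: closed-form Σ-formula OLS, a profiled grid-scan minimizer for
the rate constant, a root-finding equilibrium solver for the Job signal, and
an explicit normal-equation re-solve for the breakpoint search. The central
worked example — refitting the published 11 × 3 × 5 kobs grid and comparing
all 33 recovered k₂ values against the published table — runs in well under
a second.

## Known limitations

- No weighted or nonlinear kinetic fitting; heteroscedastic series will
  understate uncertainty at late time points.
- No static-vs-dynamic quenching discrimination or temperature dependence.
- No multi-equilibrium (1:2, 2:1) Job analysis; only the 1:1 hypothesis is
  located and labelled.
- Quantum yields use the initial-rate definition; other conventions (mean
  rate, per-photon conversion) would scale results.
- The rate–pH profile is descriptive: no decomposition into
  species-specific or buffer-catalysis rate terms.
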