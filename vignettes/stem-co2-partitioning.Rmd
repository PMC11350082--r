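---
title: "Partitioning net stem CO2 flux: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning net stem CO2 flux: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the measurement design

The CO2 flux measured at the surface of a tree stem is the net result of
three simultaneous processes. Living stem tissue respires, releasing CO2;
chlorophyll-containing bark refixes part of that CO2 using the light that
penetrates the outer bark; and CO2 dissolved in xylem sap is carried
axially with the transpiration stream, so that a stem section can export
or import dissolved CO2 depending on the axial concentration gradient.
None of the three is observable alone at the stem surface — only their
balance is.

The measurement design this package supports separates them with a pair of
chambers on the same stem: one transparent, one darkened. Under the
efflux-negative sign convention (`FCO2 < 0` when CO2 leaves the stem) the
mass balance reads

    -R + P + T = FCO2

with respiration `R > 0`, photosynthesis `P >= 0`, and transport `T` of
either sign. The dark chamber suppresses photosynthesis, so it observes
`-R + T`; the transparent chamber observes the full balance. Two further
conditions complete the identification: photosynthesis is the *daytime
difference* between the chambers, and respiration is isolated in the dark
chamber *when sap flow is near zero*, because the transport term scales
with sap flux density.

## Component models

Each component is parameterized per calendar month (June–September by
default), reflecting the seasonal drift of tissue physiology:

* **Respiration** follows an exponential temperature response,
  `R' = R0 exp(b * temp)`, with `R0` (µmol m⁻² s⁻¹) the respiration at
  0 °C and `b` (°C⁻¹) the temperature sensitivity (`Q10 = exp(10 b)`;
  `b = 0.07` corresponds to the textbook `Q10 = 2`). `temp` is xylem
  temperature.
* **Bark photosynthesis** follows a Michaelis–Menten light response,
  `P' = Pmax f PPFD / (f PPFD + Pmax)`, with `Pmax` (µmol m⁻² s⁻¹) the
  light-saturated rate and `f` (µmol CO2 per µmol quanta) the quantum
  yield, the initial slope at low light.
* **Transport** is linear in sap flux density through the origin,
  `T' = e J`; the slope `e` absorbs the axial CO2 concentration gradient
  across the chamber section. `T` is computed as the *residual*
  `dFCO2 + R'`, so it also collects every minor process not modeled
  explicitly (PEP-carboxylase fixation, storage changes), which is why
  negative values are retained and reported rather than clipped.

The monthly procedure (`fit_stem_partition()`) is: (1) fit `R0, b` by
nonlinear least squares on the dark-chamber rows with `J` below the
low-flow threshold; (2) predict `R'` over the whole month from xylem
temperature; (3) form `T = dFCO2 + R'` everywhere and
`P = tFCO2 - dFCO2` on daytime rows; (4) fit the light-response and
transport models to these series. By construction
`-R' + P + T = tFCO2` holds exactly on every row where all components are
defined — the package asserts this identity to 1e-12 rather than assuming
it.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| RH removal threshold | 85 % | condensation risk in sampling lines above this humidity |
| outlier rule | 3 SD, per tree × chamber, season-pooled | removes instrument spikes while touching only ~0.3 % of Gaussian data |
| low-sap-flow threshold | 5 (J units; ≈ 5 % of the seasonal maximum) | below this the transport term is negligible relative to respiration |
| daytime mask | PPFD > 10 µmol m⁻² s⁻¹ | separates true darkness from twilight; the chamber difference is meaningless without light |
| minimum n per fit | 30 | monthly fits below this are refused rather than reported with meaningless inference |
| train fraction | 0.8 | the 8:2 validation scheme, stratified by month |

All of these are arguments of `pipeline_config()` and of the individual
functions.

## Statistical choices

Nonlinear fits use Levenberg–Marquardt least squares (`minpack.lm::nlsLM`,
wrapped by `nls_fit()`) with tolerances tightened to 1e-15 so that
exact-data fits resolve parameters to numerical precision. Initial values
are data-driven: a log-linear regression for the exponential model
(excluding non-positive effluxes from the initialization only, falling
back to `b0 = 0.07` if too few rows remain), the 95th percentile of `P`
for `Pmax`, and an origin-constrained slope over the lowest PPFD quartile
for `f`. The transport slope needs no iteration at all:
`e = Σ(T·J)/Σ(J²)` is closed-form, and the test suite checks that the
iterative route agrees to 1e-10. A 200×200 grid search over `(R0, b)`
serves as an independent oracle: the fitted objective must never exceed
the best grid point.

Inference is Wald-type: `t = estimate/SE`, two-sided p-values against the
t distribution with `n - p` degrees of freedom, 95 % intervals
`estimate ± t(0.975, dof)·SE`. Unweighted least squares is used
throughout; no weighting scheme is reported for this design and the
simulated noise is homoscedastic.

One propagation detail matters for honest intervals. The transport series
is built with *plug-in* respiration parameters, so the slope `e` inherits
their estimation uncertainty. Since the respiration fit uses only
near-zero-flow rows and the slope only weights rows with `J > 0`, the two
error sources are independent and their variances add; the package adds
the delta-method term `gᵀ Cov(R0, b) g` (with `g` the gradient of the
slope with respect to the respiration parameters) to the slope's variance.
In simulation this moves the 95 % CI coverage of `e` from roughly 50 %
(nominal-SE-only) to 93–97 %.

Contribution accounting is reported in two normalizations: ratios of each
component to the monthly mean transparent-chamber flux (which sum to 1 by
the mass balance) and absolute-value shares summing to 100 %. The default
forms ratios from monthly means of the components divided by the monthly
mean flux; averaging per-row ratios is available as an option but explodes
whenever the net flux crosses zero, which it does daily in late summer.
Both normalizations conserve exactly under either option; which one a
study reports should be stated, as the numbers differ.

## The synthetic-data generator

No field data ship with the package; the generator
(`sim_config()`, `sim_truth()`, `generate_drivers()`,
`generate_true_fluxes()`) emulates a boreal June–September season at
61.85° N on a half-hourly grid (5856 records per season — the problem
size used throughout the tests and the acceptance study):

* **PPFD** from a solar-elevation model with a per-day clearness factor,
  exactly zero at night;
* **xylem temperature** with a seasonal course, a diurnal cycle peaking
  mid-afternoon (15:30) and a random day-to-day offset;
* **relative humidity** anti-phased with temperature, peaking at night;
* **sap flux density** as a daytime hump lagging solar elevation by 1.5 h
  and peaking in mid-July, with a seasonal maximum near 100 in the
  pipeline's J unit convention;
* **true fluxes** obeying the three component models with monthly step
  parameters inside realistic ranges (`R0` declining 0.8 → 0.35 over the
  season, `b` rising 0.08 → 0.115, `Pmax` declining 1.4 → 0.6, `f`
  declining 0.015 → 0.006, `e` declining 0.012 → 0.006), plus additive
  i.i.d. Gaussian measurement noise (default sd 0.1 µmol m⁻² s⁻¹) drawn
  independently per chamber.

Two generator details are deliberate:

* **Detection floor on J.** Computed sap flux below the low-flow threshold
  is reported as exactly zero. This mirrors the physics of
  thermal-dissipation probes — at near-zero flow the probe temperature
  difference reaches its zero-flow baseline and the flow index is clipped
  at zero — and it makes the low-sap-flow respiration subset exactly
  transport-free, so parameter recovery on noiseless data is limited only
  by floating point.
* **Closure traces from the closed form.** The flow-through chamber obeys
  the linear ODE `V dC/dt = S A + q (C_in - C)` with chamber-frame source
  `S = -FCO2` (stem efflux raises the chamber concentration). Traces are
  sampled from the exact solution
  `C(t) = C_eq + (C0 - C_eq) exp(-q t / V)`, so the least-squares
  inversion in `compute_closure_flux()` is exact on noiseless traces; the
  tests verify the forward model independently against a numerical ODE
  integrator. The inversion fits the full solution rather than the initial
  slope because the chamber turnover time (~60 s at 1.1 L min⁻¹ through
  ~1.25 L) makes dilution non-negligible within a 100 s closure; the
  plain slope estimator is retained as an option and is biased low by
  roughly 10–20 % under these defaults.

The generator's additive Gaussian noise model supports the
standard-error and coverage claims of the fits, but real chamber data are
messier: noise is likely heteroscedastic, drivers carry sensor error, the
two chambers are not at identical temperature, and within-crown shading
decouples above-canopy PPFD from the light actually reaching the bark.
Passing recovery tests therefore demonstrate the *estimators* are correct
and calibrated under the stated model, not that field estimates would be
unbiased.

## QC architecture

Filters never delete or modify rows: each one adds a named flag
(`TECH_FAIL`, `OUTLIER_3SD`, `RH_HIGH`, `RH_MISSING`), and rows are
dropped once, at assembly of the aligned table, where the exclusion tally
is recorded so counts telescope (rows in = flagged + rows out). The 3-SD
statistics are computed over the measured dataset excluding only technical
failures — not rows flagged by the other environmental filters — so the
filters commute and the result does not depend on the order they run in.
A sequential procedure that re-estimated the SD after each removal would
differ marginally; the order-independent design was chosen for
auditability.

The zero-flow sap baseline uses the *nightly maximum* probe temperature
difference averaged over a centered window of seven consecutive nights
(truncated at the season edges), a night being PPFD below
10 µmol m⁻² s⁻¹; each calendar day inherits the baseline of the night
that ended on its morning.

## Degenerate inputs and tie-breaks

* Constant temperature makes `(R0, b)` unidentifiable; the fit refuses
  with a rank-deficiency error rather than returning an arbitrary point.
* A light-response fit that fails to converge is returned flagged invalid
  and excluded from downstream prediction, not raised as an error, so one
  bad month cannot abort a season.
* `All J = 0` leaves the transport slope undefined (error); `J` above the
  baseline in the probe conversion is clipped to zero flow and counted.
* Months absent from a parameter table, misaligned series, and empty
  month subsets all raise errors naming the month or series concerned.

## Known limitations

* The in-chamber stem temperature estimate
  (`estimate_chamber_stem_temperature()`) is a one-parameter linear
  coupling between ambient, chamber-air and outside-stem temperatures —
  a documented stand-in, not a heat-transfer model.
* Monthly step parameters cannot follow sub-monthly physiology; the month
  boundaries are calendar, not phenological.
* The transport term is a residual: it inherits every unmodeled process
  and the respiration model error. Its interpretation as purely advective
  transport rests on the assumptions listed above.
* The package does not model xylem CO2 concentration, carbonate
  chemistry, or storage dynamics, and performs no gap-filling.
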