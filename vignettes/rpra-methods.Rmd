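---
title: "Methods: probabilistic multi-route hazard quotients for heavy metals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic multi-route hazard quotients for heavy metals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpra)
```

## The assessment model

rpra estimates non-carcinogenic health risk from heavy metals (As, Hg, Cd,
Zn, Pb, Cu, Cr, Ni) in environmental media as hazard quotients: the ratio
of the chronic daily intake through one exposure route to the route-specific
chronic reference dose, HQ = CDI / RfD. Values above 1 flag potential risk.
Per scenario (a medium or land use with its sensitive receptor), the
per-route and per-metal quotients add into a total hazard quotient (THQ).

The route models are the standard chronic-intake forms:

* **Ingestion** of soil, sediment or water:
  `HQ = C · IR · EF · ED · UF / (BW · AT · RfD_oral)`, where the unit
  transfer factor UF is 1e-6 for solids (concentration in mg/kg, intake in
  mg/d) and 1e-3 for waters (µg/L, L/d).
* **Groundwater source term**: metals leach from the 0–100 cm soil profile
  into pore water by linear equilibrium partitioning and are attenuated
  during transport, `C_gw = 1000 · C_ts / ((K_d + θ_w/ρ_b) · DF)` in µg/L.
  This is the standard soil-to-groundwater screening model; its point
  estimates sit in the same range as measured river-water concentrations of
  the bundled survey, which is the behaviour expected for a well-connected
  alluvial aquifer.
* **Vegetable consumption** from cultivated soil:
  `HQ = C_as · PUF · IR_v · (1−θ_v) · EF · ED / (BW · AT · RfD_oral)`.
  PUF is a dry-weight plant:soil concentration ratio while IR_v is a
  fresh-weight intake, so the vegetable water content θ_v converts between
  the two; this (1−θ_v) dry-matter conversion is a modelling choice we state
  explicitly.
* **Dermal contact** with solids:
  `HQ = C · (SA·1e4) · AF · ABS · EF · ED · 1e-6 / (BW · AT · RfD_dermal)`
  (skin area SA in m², adherence AF in mg/cm²); and with water:
  `HQ = C · K_p · (SA·1e4) · ET · EF_sw · ED · 1e-6 / (BW · AT · RfD_dermal)`.
  Because the permeability constant K_p is a rate (cm/h), the water route
  needs an exposure time per event, ET (h/event), alongside the event
  frequency EF_sw (events/yr); the combined 1e-6 is the explicit
  µg→mg (1e-3) times L→cm³ (1e-3) conversion, not a free unit factor.
* **Inhalation** of soil dust and vapor:
  `HQ = C · IR_a · EF · ED · (1/PEF + 1/VF) / (BW · AT · RfD_inhalation)`.
  Dust and vapor pathways combine additively in the exposure concentration;
  the volatilization factor exists only for elemental Hg (32,376.4 m³/kg),
  so for the other metals the 1/VF term is zero and dust dominates.

Averaging time follows the non-carcinogenic convention `AT = ED · 365` per
iteration, so ED cancels from every route; it is retained as a declared
parameter for transparency.

## Scenarios and receptors

`build_default_study()` assembles seven scenarios: four surface-soil land
uses — riverbank vegetable plots (RVS) and private vegetable plots (PVS)
worked by farmers (ingestion, dermal, inhalation, vegetable routes), and
riverbank/public green spaces (RGS, PGS) used by residents (no vegetable
route) — plus groundwater (drinking-water ingestion of the leachate-derived
concentration), surface water (daily water intake plus dermal contact while
swimming) and river sediments (incidental ingestion and dermal contact
while swimming). Route frequencies are bound accordingly: daily-intake
routes use EF_ia (350 d/yr), outdoor soil contact uses EF_oa (225 d/yr),
and swimming-mediated routes use the event frequency EF_sw.

Farmers and residents carry different soil adherence factors (`AF_sa` =
0.22 vs `AF_sr` = 0.12 mg/cm²), mirroring the gardener-versus-resident
distinction in standard exposure-factor compilations; swimmers contacting
wet sediment use a higher `AF_sd` = 0.33 mg/cm² over whole-body skin area.

## Monte Carlo machinery

Every uncertain quantity is declared as a `parameter_spec()`: a point
value, a lognormal (by arithmetic mean and sd, optionally truncated), or a
triangular (min, mode, max). Lognormals are parameterized through the
moment identities `meanlog = ln(m²/√(m²+s²))`, `sdlog² = ln(1+s²/m²)`, so
the *untruncated* distribution matches the declared moments exactly;
truncation is by rejection with a guard that raises an error, naming the
parameter, if acceptance falls below 1%. Truncation shifts the realized
mean — for a heavily clipped summary such as the RVS arsenic row the
realized mean is about 7% below the declared one — and the package accepts
this shift rather than re-centring, because the declared bounds are hard
survey minima/maxima.

Each parameter draws from a private stream seeded deterministically from
`(run seed, parameter name)`, so adding or removing a parameter never
perturbs the others and any draw matrix is bit-reproducible from its seed.

Dependence between parameters is imposed by Iman–Conover reordering:
columns named in the correlation specification are re-sequenced to follow
the ranks of a correlated normal-score matrix, preserving every marginal
exactly (each output column is a permutation of its input). Spearman
targets are mapped to normal-score Pearson correlations via
`2·sin(πρ/6)`; the implied matrix must be positive semi-definite or the
offending pairs are reported. The default dependence set is BW~SA_o,
BW~SA_sw and SA_o~SA_sw at +0.7 (body size drives all three; the third
pair is required for joint attainability and is physically sensible) and
PUF~K_d at −0.7 per metal (strongly sorbed metals are less plant-available).
The ±0.7 magnitudes are defaults, configurable per run.

The default run length is 10,000 iterations; at that size the achieved
rank correlations land within ±0.02 of target and the bootstrap standard
error of a scenario p95 is on the order of 1–2%. `summarize_risk()` can
attach that bootstrap SE so cross-run scatter is quantified rather than
guessed.

## Default parameter tables and their calibration

The exposure-factor table bundled as `default_exposure_parameters()` is a
stand-in compiled from literature-typical values for an adult Chinese
receptor (e.g. BW 60 kg, IR_w 2 L/d, IR_v 0.3 kg/d fresh weight, IR_a
16 m³/d, IR_s 67 mg/d, swimming 35 events/yr); it is not a set of site
measurements, and any study with survey data should override it. The
metal table (`default_metal_properties()`) uses standard oral reference
doses (e.g. As 3e-4, Cd 1e-3, Cr(VI) 3e-3 mg/kg/d), dermal doses via the
usual gastrointestinal-absorption adjustment, inhalation doses from
reference concentrations where validated (Hg, Cr) and the oral value
otherwise, ABS of 0.03 for As and 0.001 for the other metals, and K_p of
1e-3 cm/h.

Soil K_d and PUF vary over orders of magnitude between soils, so their
bundled means were *calibrated by moment matching*: they were chosen, once,
so that the pipeline's mean hazard quotients on the bundled survey
summaries reproduce the published screening pattern for that survey —
vegetable uptake and groundwater leaching as the dominant transfer routes,
As and Cd as the priority metals, and groundwater quotients in the same
range as surface-water quotients. Two details of that calibration matter:

* The resulting PUF ordering (Cd 0.36 ≫ Zn 0.11 > Cu 0.074 > Ni 0.048 ≫
  Pb 0.012, Cr 0.010, Hg 0.0064, As 0.0045) reproduces the well-known
  uptake hierarchy of leafy vegetables without further tuning.
* Because the leaching term enters as a reciprocal, its Monte Carlo mean
  exceeds the point-value reciprocal by roughly `(1+CV²_Kd)(1+CV²_DF)` ≈ 2
  (Jensen's inequality); the K_d means target the *Monte Carlo* mean, not
  the point evaluation. Both coefficients of variation are set to 0.6–0.7
  with wide truncation (K_d on [mean/8, 5·mean]), reflecting that K_d and
  DF are the least constrained inputs, which is also why the groundwater
  scenario shows the largest output CV (~110%).

## Risk characterization and sensitivity conventions

Percentiles use linear interpolation between order statistics (R's type-7
default) — the convention is stated because different software disagrees at
exactly the reported quantiles. Exceedance probability is the direct count
of iterations above the threshold (default 1), in percent. Contribution
shares are computed on means, not medians, so they are exactly additive to
100% within each scenario-route cell. A zero-mean group with nonzero
spread has an undefined CV and is flagged rather than silently zeroed.

Sensitivity ranking correlates each input column with the scenario THQ.
Spearman rank correlation is the default — it is invariant to monotone
transforms, robust to the lognormal skew, and matches the convention of
commercial risk packages — with Pearson available as an option; the method
used is recorded on the result. Significance is a two-tailed t
approximation at the 0.01 level with no multiplicity correction (the
ranking, not the inference, is the product). Point-valued inputs have
undefined correlation and are excluded with a warning.

## The synthetic field survey

`generate_field_data()` emulates a riverine multi-land-use survey: per
stratum (RVS n=7, RGS n=13, PVS n=11, PGS n=20, soil profiles n=6, water
and sediment n=10 each) it draws site concentrations from the truncated
lognormal implied by the bundled summary row, and imposes a within-site
rank correlation of 0.5 among the co-sourced metals As, Cd, Zn, Pb and Cu
(a modelling choice standing in for unreported co-contamination strength;
Hg, Cr and Ni are left independent as their inputs are dominated by
atmospheric and geogenic sources). Soil pH is carried as a uniform(5.5,
7.5) placeholder — the models do not yet use it, but the column keeps the
schema ready for pH-dependent partitioning.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring sites, depth structure within the 0–100 cm profile,
analytical measurement error, and any pH–K_d dependence. Tests that pass
on generated data therefore validate the pipeline's statistical machinery
and the survey's marginal structure, not geostatistical realism.

## Numerical choices and degenerate inputs

* Rejection sampling guard: acceptance < 1% after 10,000 proposals is an
  error naming the parameter (bounds that tight indicate a mis-declared
  summary).
* PSD tolerance for the correlation target: smallest eigenvalue ≥ −1e-8;
  the symmetric eigen square root is used instead of Cholesky so exactly
  semi-definite targets (correlation ±1) still work.
* Rank ties during reordering break by first occurrence
  (`ties.method = "first"`), which keeps the operation a permutation even
  for discrete or point-valued columns.
* A lognormal with sd 0, and any point parameter, collapse to exact
  constants; with a fully point-valued draw matrix every route reproduces
  its closed-form hand calculation to double precision, which is the
  package's deterministic regression anchor.
* THQ addition is plain elementwise summation; rows are summed in table
  order and reordering perturbs totals only at float-associativity level.

## Problem sizes used in the checks

The bundled checks run the full seven-scenario study at 10,000 iterations
(a few seconds per run), repeat the end-to-end ordering check over 20
seeds, and use 1e5 draws for distribution-moment checks; unit tests use a
few hundred iterations where distributional accuracy is not the point.
These sizes were chosen so the complete suite exercises the default study
conditions while staying comfortably interactive.

## Known limitations

* Carcinogenic (slope-factor) risk is out of scope by design.
* Receptors are single adult archetypes; no age stratification.
* The vegetable route uses a single PUF per metal rather than
  crop-specific factors; speciation and bioaccessibility are not modelled.
* The leaching model is a screening-level equilibrium form; it will
  overestimate groundwater transfer where transport is kinetically limited.
* The bundled exposure and soil-coefficient tables are calibrated
  stand-ins; conclusions for a real site require site-specific tables,
  which drop in via `run_config()` without code changes.
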