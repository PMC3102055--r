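---
title: "Occupational activity trends and energy-balance weight prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupational activity trends and energy-balance weight prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metshift)
```

## The problem

U.S. employment has shifted, over roughly five decades, from
goods-producing and agricultural work toward service work. Because
goods-producing and farm jobs demand at least moderate-intensity physical
activity while most service jobs are sedentary or light, this shift implies
a secular decline in the energy people expend at work — a candidate
contributor to rising population mean body weight. `metshift` implements
that chain of reasoning as a tested pipeline: sector employment counts →
intensity-weighted occupational energy expenditure by year → an
energy-balance model mapping the expenditure decline to predicted mean
weight → comparison against observed NHANES mean-weight anchors.

## From employment counts to energy expenditure

Employment is resolved to 11 sectors (one agricultural, three
goods-producing, seven service-providing). For each year, sector
*prevalence* is the employed count divided by total employment across all
sectors; prevalences are non-negative and sum to one (the simplex). Each
sector carries a median intensity in METs (1 MET = 1 kcal·kg⁻¹·h⁻¹) from a
packaged assignment table, and an intensity category implied by that
median:

* sedentary: [0, 2) METs
* light: [2, 3) METs
* moderate: [3, 6) METs

The interval convention is half-open on the right — 2.9999 METs is light,
3.0 is moderate — which makes classification total on (0, 6) and puts the
conventional cutpoints where the category definitions state them. Medians
at or above 6 METs are rejected rather than silently bucketed: the scheme
has no vigorous category, and every packaged median is ≤ 4.0 (only
per-sector *maxima* reach 8.0; categories never use them).

The yearly mean occupational intensity is the prevalence-weighted mean of
the sector medians. Daily occupational expenditure converts intensity to
kcal per workday:

EE = hours worked × mean METs × body weight,

with an 8-hour workday and reference weights fixed for **every** year at
the 1960–62 NHANES means — 76.9 kg (men), 64.9 kg (women). Holding the
reference weight fixed is deliberate: the expenditure trend isolates the
occupational-mix effect, and the weight feedback lives only inside the
energy-balance model. Consequently men's and women's EE series differ by
exactly the ratio of reference weights.

Trend strength is summarized by ordinary least squares of the yearly
statistic on calendar year with a two-sided t-test on the slope. No
particular trend test is canonical for this design; OLS is the simplest
defensible choice, the method name is carried in the report so a rank-based
alternative can be slotted in, and the p-value is invariant to affine
re-indexing of years. Perfect fits are handled explicitly: zero residual
variance with zero slope returns p = 1, with nonzero slope p = 0 (the
t-statistic is undefined in both cases).

## The energy-balance model

Weight responds to a sustained change Δ in daily energy expenditure
(kcal/day; negative means a reduction) through a single-compartment linear
ODE:

dW/dt = (−Δ − γ·(W − W₀)) / ρ

* **γ** (kcal·kg⁻¹·day⁻¹): marginal total energy expenditure per kg of body
  weight. As weight rises, total expenditure rises by γ per kg, until it
  offsets the imposed reduction. Defaults: 1/0.090 ≈ 11.11 (men), 1/0.092 ≈
  10.87 (women) — see calibration below.
* **ρ** (kcal/kg): energy density of tissue change, default 7700, the
  conventional figure for mixed adipose/lean tissue. ρ sets only the
  *timescale* of approach (half-life log(2)·ρ/γ ≈ 1.3 years at the male
  defaults); the steady state is independent of it.
* **W₀** (kg): baseline weight, defaulting to the 1960–62 anchors.

The steady state is W\* = W₀ − Δ/γ, so the model's steady-state sensitivity
is exactly 1/γ kg per kcal/day. This is the minimal model consistent with a
first-law derivation, weight-dependent expenditure, simulation to steady
state, and a constant per-gender kg-per-kcal sensitivity; a richer
two-compartment variant could be substituted by replacing the model object,
whose parameters are all surfaced in the constructor.

**Calibration.** `kg_per_kcal_ratio()` reproduces the published calibration
procedure literally: reductions of 50, 100 and 150 kcal/day are each
simulated to steady state and the three ΔW/Δ ratios averaged. Linearity
makes the three analytic ratios identical, so the average equals 1/γ;
`calibrate_gamma()` inverts this in closed form (γ = 1/ratio), and the
default models use γ = 1/0.090 and 1/0.092 so the simulated procedure
returns 0.090 and 0.092 at 3-decimal rounding.

**Numerics.** Integration uses lsoda (deSolve) on a daily grid with
relative/absolute tolerances 1e-10, horizon 30 simulated years. The run
terminates at the first grid point where |dW/dt| < 1e-6 kg/day, which
brackets the terminal weight within tolerance·ρ/γ (≈ 7×10⁻⁴ kg at the male
defaults) of the closed-form steady state — well inside the 1-decimal
rounding used for reported weights. Non-convergence within the horizon is
flagged, not thrown. A zero (or sub-tolerance) initial rate short-circuits
to the baseline at day 0. Tests compare the integrator against the
closed-form exponential solution W(t) = W\* + (W₀ − W\*)·e^(−γt/ρ) across
random parameter draws; high-precision settings (tolerance 1e-11, tight
integrator tolerances, longer horizon) are used where tests demand
parameter recovery to 1e-6.

**The workweek factor.** Trajectory prediction converts a per-workday
expenditure change into a per-calendar-day change. Two conventions are in
circulation: multiply by 5/7 (a five-day work week) or take the workday
change as-is. The headline worked example (142 kcal/day → 89.7 kg from a
76.9 kg baseline) only holds under the as-is convention, while
survey-period trajectory comparisons conventionally use 5/7. Both are
implemented behind the explicit `apply_workweek` flag; the report records
which was used, the worked example runs with the factor off, and the
default trajectory runs with it on.

**Sign convention.** Δ is the change in expenditure, so reductions are
negative internally; user-facing "reduction" magnitudes are negated at the
boundary.

## The synthetic employment generator

Real establishment/household survey extracts are not shipped. The generator
produces series with the statistical structure the analysis assumes:

* Sector prevalences drift **linearly** between anchored 1960 and 2008
  vectors, then (under noise) are renormalized to the simplex. Linearity is
  the weakest assumption consistent with roughly monotone observed drifts;
  no functional form is claimed.
* The anchor vectors pin every published aggregate: moderate-category mass
  0.48 → 0.20, manufacturing 0.30 → 0.12, professional/business +
  education/health + leisure/hospitality 0.20 → 0.43. Sectors not pinned by
  an aggregate are fixed, documented constants chosen for qualitative
  plausibility (construction flat at 0.06; information declining 0.035 →
  0.025; farm 0.08 → 0.01; mining/logging 0.04 → 0.01; trade/transport/
  utilities 0.22 → 0.245; financial 0.045 → 0.065; other services 0.02 →
  0.035). These are configuration, not hard-coded truth: any
  `anchor_set()` can be substituted.
* Noise is multiplicative log-normal per (year, sector) followed by
  renormalization — keeping counts positive and shares on the simplex —
  with relative SD `noise_sd` (default 0 for the reference conditions).
* Total employment interpolates linearly between 52.0 and 137.0 million;
  the absolute scale cancels in every prevalence-based statistic.
* Generation is deterministic given the seed and restores the caller's RNG
  state.

Under the noiseless reference conditions the pipeline yields 1960→2008
declines in daily occupational expenditure of about 170 kcal (men) and
144 kcal (women) — comfortably above the 100 kcal/day benchmark the
analysis is anchored to.

What the generator does **not** emulate: business cycles, survey
redesigns, within-sector compositional change, or the yearly wiggles of
real extracts. Passing tests on synthetic data therefore demonstrate that
the pipeline's arithmetic, invariants and calibration are correct under the
assumed structure — not that any particular published yearly curve is
recovered. Exact published per-gender declines (on the order of 140 and
124 kcal) depend on the real extracts and are deliberately out of reach;
the package treats such figures as *inputs* where needed (e.g. the
142 kcal worked example).

## Pipeline conventions

* **Periodization:** NHANES survey-period expenditure is the unweighted
  mean of yearly EE over the period's calendar years (1960–62, 1971–74,
  1976–80, 1988–94, 1999–2002, 2003–06); no mapping of survey field dates
  onto employment reference periods is attempted.
* **Missing cells:** absent (year, sector) employment cells are zero-filled
  with a warning rather than rejected — early agricultural detail is
  genuinely sparse; a year with no employment at all is an error.
* **Display rounding:** kg to 1 decimal, kcal to 0 decimals, sensitivities
  to 3 decimals; machine-readable outputs keep full precision, and the
  employment CSV writer uses 17 significant digits so series round-trip
  bit-for-bit.
* **Determinism:** the JSON report contains no timestamps; two runs of the
  same configuration are byte-identical, and a rolling hash of the
  effective configuration is embedded for provenance.
* **Observed anchors:** only the three published NHANES cells are shipped
  (men/women 76.9/64.9 kg in 1960–62; men 91.8 kg in 2003–06); all other
  period × gender cells are explicitly absent, and users can attach their
  own.

## Problem sizes

The test suite and acceptance script run on a 49-year × 11-sector series;
property checks use 20 random ODE parameter draws, 50 calibration
round-trips and 100 generator seeds — sizes chosen so the whole suite
completes in well under a minute while exercising every invariant at
meaningful breadth.

## Limitations

* The linear model yields a constant kg-per-kcal sensitivity; whether the
  true sensitivity is mildly weight-dependent cannot be decided from
  per-gender constants, and a weight-dependent variant would need a
  different model object.
* Intake is held fixed: the model attributes all weight change to the
  expenditure side, by design.
* No fat/fat-free partitioning, adaptive thermogenesis, survey weighting,
  or age-standardization of obesity prevalence — the pipeline targets mean
  weight of the 40–50-year-old working population only.
* The single pooled trade/transportation/utilities sector follows the MET
  assignment granularity, not establishment-survey granularity.
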