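# metshift

Secular trends in U.S. occupational physical-activity energy expenditure,
and what they imply for population mean body weight.

Over the past five decades U.S. employment has shifted out of
goods-producing and agricultural sectors — where jobs demand at least
moderate-intensity physical activity — into largely sedentary service
sectors. `metshift` is an R package for quantifying that shift and
translating it into weight change. It is aimed at epidemiologists and
quantitative public-health researchers who want a reproducible,
end-to-end pipeline from sector-level employment counts to a
predicted-versus-observed weight comparison.

## What it computes

**Occupational energy expenditure.** Each of 11 industry sectors carries a
median physical-activity intensity in METs (1 MET = 1 kcal·kg⁻¹·h⁻¹) and an
intensity category — sedentary (< 2 METs), light (2.0–2.9), moderate
(3.0–5.9). For a year with sector prevalences *p₁…p₁₁* (employment shares on
the simplex), the mean occupational intensity is the prevalence-weighted
median MET, and daily occupational expenditure is

    EE (kcal/workday) = hours worked × mean METs × body weight (kg)

with an 8-hour workday and gender-specific reference weights held at the
1960–62 NHANES means (76.9 kg men, 64.9 kg women).

**Energy-balance model.** A sustained change Δ<sub>EE</sub> in daily
expenditure (kcal/day, negative for a reduction) perturbs a
single-compartment energy-balance ODE for mean body weight *W*:

    dW/dt = (−Δ_EE − γ·(W − W₀)) / ρ

where γ (kcal·kg⁻¹·day⁻¹) is the marginal total expenditure per kg of body
weight and ρ = 7700 kcal/kg the energy density of tissue change. The steady
state is W\* = W₀ − Δ<sub>EE</sub>/γ, so the model's kg-per-kcal sensitivity
is 1/γ; γ is calibrated so that simulating 50, 100 and 150 kcal/day
reductions to steady state and averaging the three ΔW/Δ<sub>EE</sub> ratios
reproduces the published sensitivities of 0.090 kg per kcal/day (men) and
0.092 (women).

**Synthetic employment series.** Because the underlying BLS extracts are not
redistributable, a generator produces series with the structure the analysis
assumes: sector prevalences drifting linearly between anchored 1960 and 2008
vectors (moderate-category share 48% → 20%, manufacturing 30% → 12%,
professional/business + education/health + leisure/hospitality 20% → 43%),
with optional multiplicative log-normal noise, renormalized to the simplex.
Any real series in the CSV dialect `year,sector,employed_thousands` can be
substituted.

## Worked example

```r
library(metshift)

m <- energy_balance_model("men")
summary(m)
#> Energy-balance model (single compartment, linear)
#>   gender: men;  baseline weight: 76.9 kg
#>   gamma: 11.1111 kcal/kg/day  (1/gamma = 0.090 kg per kcal/day)
#>   rho:   7700 kcal/kg (tissue energy density)
#>   steady-state sensitivity: 0.090 kg per kcal/day
#>   approach half-life: 480 days (1.3 years)

worked_example_report()
#>   baseline_kg delta_ee_kcal predicted_kg observed_kg gap_kg
#> 1        76.9          -142         89.7        91.8    2.1
```

Reading: a man at the 1960–62 mean weight of 76.9 kg who sustains a
142 kcal/day drop in occupational expenditure is predicted to settle at
89.7 kg — 2.1 kg below the observed 2003–06 NHANES mean of 91.8 kg.

The full pipeline on a synthetic series:

```r
cfg <- pipeline_config(synthetic = list(noise_sd = 0), seed = 1)
rep <- run_pipeline(cfg)
rep$ee_decline
#>      men    women
#> 170.1024 143.5588
```

On the noiseless anchored series, daily occupational expenditure declines by
about 170 kcal (men) and 144 kcal (women) from 1960 to 2008 — both over the
100 kcal/day mark. The report also carries per-sector and per-category OLS
trend tests, per-NHANES-period mean expenditures, and predicted-vs-observed
weight trajectories per gender.

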