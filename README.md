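# borealfire

Carbon accounting and suppression economics for boreal North American
wildfires.

Boreal forests hold roughly two-thirds of global forest carbon, and the
area they burn each year has nearly doubled over six decades. Every
burned hectare releases on the order of 100 t of CO2, most of which is
only re-absorbed slowly — net uptake does not begin until about 14 years
after a fire and takes ~150 years to repay the pulse. Fire agencies
influence burned area through suppression, which raises a policy
question: what does an avoided ton of CO2 cost when bought through fire
management? This package implements that full analysis chain for
researchers in ecosystem carbon accounting and environmental economics:

- **Carbon accounting** — burned area → gross CO2 via a combustion rate
  of 3.325 kg C/m2 and a carbon-specific emission factor derived by
  molecular-weight-adjusted normalization of a boreal species table
  (f_CO2 ≈ 0.84); gross → net at a horizon year via a lag-14/payback-150
  regrowth curve; quartile-bounded burned-area projections to 2050;
  comparison against IPCC remaining carbon budgets.
- **Fire-size modelling** — fire-management zones (FMZ: critical, full,
  modified, limited) proxy suppression effort; a zone-only linear model
  and a 500-tree random forest with conditional permutation importance
  and partial dependence quantify the zone–size association.
- **Suppression econometrics** — two-stage least squares of log fire
  size on the log cost of suppression, instrumented by FMZ (assigned
  before ignition, so free of reverse causality), with LASSO-selected
  controls, robust SEs, alternate specifications and a road-access
  subgroup analysis.
- **Cost-effectiveness** — the hectare-weighted cost per avoided ton,

  cost/t = Σᵢ (Aᵢ/ΣAⱼ) · Cᵢ/(Aᵢ·|β|·eᵢ),

  with SE and bootstrap ranges, a fuel-use emissions scenario, and the
  investment needed to hold emissions at historical levels.
- **Synthetic data** — the agency fire and expenditure records behind
  the original analyses are restricted, so seeded generators emulate
  their statistical structure (zone/weather/cause-driven log-normal fire
  sizes; costs endogenous to size with FMZ as a valid instrument;
  trending burned-area histories), making every stage runnable and
  testable offline.

## Worked example

Estimate the spending elasticity on a synthetic catalog and price an
avoided ton:

```r
library(borealfire)

f <- derive_co2_fraction(boreal_emission_factors())
f
#> [1] 0.8426
e <- per_hectare_emissions(combustion_params(), f)
e
#> [1] 102.66

catalog <- generate_fire_catalog(catalog_config(n_fires = 825), seed = 1)
sim     <- generate_cost_table(catalog, econ_config(), seed = 2)
frame   <- build_econ_frame(apply_exclusions(
             reconstruct_total_cost(sim$costs), sim$catalog)$frame)

controls <- select_controls(frame, seed = 3)
controls
#> [1] "max_temp_c"  "mean_temp_c"

iv <- estimate_elasticity_iv(frame, controls)
iv
#> 2SLS elasticity (primary): -0.214 (robust se 0.049), n = 825
#>   95% CI [-0.311, -0.118]; first-stage F(3, 819) = 17.80

priced <- frame[frame$total_cost_usd > 0, ]
cost_per_ton(priced$total_area_ha, priced$total_cost_usd,
             iv$beta_hat, e)$point_usd_per_tCO2
#> [1] 138.09

budget_share(11.93, target = 1.5, probability = 67)
#> [1] 2.98
```

Reading the output: the emission factor says 84% of combusted carbon
leaves as CO2, giving 102.7 t CO2 per burned hectare. The generator's
true elasticity is −0.21 (a 1% spending increase shrinks burned area by
0.21%); the 2SLS estimate on this catalog is −0.214 with a strong first
stage (F = 17.8 on the excluded zone instruments), while naive OLS on the
same frame is biased by the spending–size simultaneity. At this
catalog's synthetic cost scale, an avoided ton costs about $138; dollar
figures computed from synthetic costs characterize the method, not any
agency's books. The last line: 11.93 Gt of net emissions would consume
2.98% of the 400 Gt remaining budget for 1.5 °C at 67% probability.

## Analysis workflow

`analysis/` holds numbered drivers that run the study end to end on
synthetic data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # catalogs, costs, histories, projections
Rscript analysis/02_carbon_accounting.R   # emission rate, ledgers, budget shares
Rscript analysis/03_fire_size_model.R     # linear model, forest, importance
Rscript analysis/04_suppression_iv.R      # LASSO + 2SLS + alternate specs + roads
Rscript analysis/05_cost_effectiveness.R  # $/t, fuel scenario, investment plan
```

`run_full_pipeline()` performs the same sequence as one call with a
manifest of output checksums. The methods vignette
(`vignettes/boreal-fire-carbon.Rmd`) documents the models, parameter
choices, numerical conventions and limitations.

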