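#!/usr/bin/env Rscript
# Stage 5: what does an avoided ton of CO2 cost? Combines the estimated
# elasticity with per-fire areas/costs and the per-hectare emission rate
# into the hectare-weighted cost per avoided metric ton, with SE and
# bootstrap ranges; then the fuel-use emissions scenario and the
# investment needed to hold burned area at the historical regime.

suppressPackageStartupMessages(library(borealfire))
dir.create("results", showWarnings = FALSE)
seed <- 20260905

iv <- jsonlite::read_json("results/iv_summary.json", simplifyVector = TRUE)
carbon <- jsonlite::read_json("results/carbon_summary.json",
                              simplifyVector = TRUE)
catalog <- read_fire_catalog("results/data/econ_catalog.csv")
costs <- reconstruct_total_cost(read_cost_table("results/data/cost_table.csv"))
frame <- build_econ_frame(apply_exclusions(costs, catalog)$frame)
# priced fires only: zero-cost monitored fires buy no marginal suppression
priced <- frame[frame$total_cost_usd > 0, ]

e <- carbon$e_per_ha_tCO2
unc <- cost_per_ton_uncertainty(priced$total_area_ha, priced$total_cost_usd,
                                iv$beta_hat, iv$se, e,
                                n_boot = 1000, seed = seed)
cat(sprintf("cost per avoided t CO2: $%.2f\n", unc$point_usd_per_tCO2))
cat(sprintf("  SE range (beta +/- 1 se): $%.2f to %s\n",
            unc$se_range[["low"]],
            if (is.finite(unc$se_range[["high"]]))
              sprintf("$%.2f", unc$se_range[["high"]]) else "unbounded"))
cat(sprintf("  95%% bootstrap range: $%.2f to $%.2f (%d fires)\n",
            unc$ci95[["low"]], unc$ci95[["high"]], nrow(priced)))

annual_net_t <- mean(unlist(carbon$alaska$net_GtCO2)) * 1e9 / 30
fuel <- fuel_emissions(133e6, fuel_scenario(),
                       net_emissions_tCO2 = annual_net_t)
cat(sprintf("fuel-use scenario at $133M/season: %.0f t CO2 = %.2f%% of annual net emissions\n",
            fuel$total_tCO2, fuel$share_of_net_pct))

proj <- build_scenario(766000, carbon$alaska$bounds$upper, 2020, 2050,
                       "alaska")
invest <- required_investment(proj, 420000, 133e6, iv$beta_hat,
                              period = c(2021, 2030))
utils::write.csv(invest$plan, "results/investment_plan.csv",
                 row.names = FALSE)
cat(sprintf("holding Alaska at the historical regime, 2021-2030 (upper scenario):\n"))
cat(sprintf("  mean annual spending $%.0fM; cumulative $%.2fB\n",
            mean(invest$plan$spending_usd) / 1e6,
            invest$cumulative_usd / 1e9))

jsonlite::write_json(
  list(cost_per_ton = unc[c("point_usd_per_tCO2", "se_range", "ci95")],
       n_priced_fires = nrow(priced),
       fuel_total_tCO2 = fuel$total_tCO2,
       fuel_share_of_net_pct = fuel$share_of_net_pct,
       investment_cumulative_usd = invest$cumulative_usd,
       investment_mean_annual_usd = mean(invest$plan$spending_usd)),
  "results/cost_effectiveness_summary.json", auto_unbox = TRUE,
  digits = 10, pretty = TRUE)
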