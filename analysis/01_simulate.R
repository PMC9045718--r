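#!/usr/bin/env Rscript
# Stage 1: generate the synthetic inputs every later stage consumes.
#
# Emulates the statistical structure of the agency records the analysis
# needs: a fire catalog (zone/cause/weather-driven log-normal sizes), a
# per-fire cost table with controlled endogeneity and the zone as a valid
# instrument, observed burned-area histories for Alaska and Canada, and
# the table of literature burned-area projection studies.

suppressPackageStartupMessages(library(borealfire))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20260901

catalog <- generate_fire_catalog(catalog_config(), seed)
write_fire_catalog(catalog, "results/data/fire_catalog.csv")
cat(sprintf("fire catalog: %d fires, %d-%d; median size %.1f ha\n",
            nrow(catalog), min(catalog$year), max(catalog$year),
            median(catalog$size_ha)))
cat("  fires by zone:",
    paste(names(table(catalog$fmz)), table(catalog$fmz), sep = "=",
          collapse = ", "), "\n")

# the expenditure sample is smaller than the fire catalog, as cost records
# cover only a subset of seasons
econ_catalog <- generate_fire_catalog(catalog_config(n_fires = 825),
                                      seed + 1)
sim <- generate_cost_table(econ_catalog, econ_config(), seed + 2)
write_fire_catalog(sim$catalog, "results/data/econ_catalog.csv")
write_cost_table(sim$costs, "results/data/cost_table.csv")
cat(sprintf("cost table: %d fires, %.0f%% zero-cost (monitored)\n",
            nrow(sim$costs), 100 * mean(sim$costs$blm_cost_usd == 0)))

for (rg in c("alaska", "canada")) {
  base <- c(alaska = 350000, canada = 1000000)[[rg]]
  hist <- generate_burned_area_history(rg, 1960, 2019, base,
                                       trend_pct_per_decade = 14,
                                       lognormal_cv = 0.4,
                                       seed = seed + match(rg, c("alaska",
                                                                 "canada")))
  write_burned_area_series(hist, sprintf("results/data/history_%s.csv", rg))
  cat(sprintf("%s burned-area history 1960-2019: mean %.0f ha/yr\n",
              rg, mean(hist$burned_ha)))
}

studies <- default_projection_studies()
write_projection_studies(studies, "results/data/projection_studies.csv")
cat(sprintf("projection studies: %d entries across %d regions\n",
            nrow(studies), length(unique(studies$region))))
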