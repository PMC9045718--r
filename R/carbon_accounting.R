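# Carbon accounting: burned area -> gross CO2 via a field-average
# combustion rate and a carbon-specific emission factor; gross -> net via a
# post-fire regrowth curve; literature projections extrapolated to a target
# year and bounded by quartiles; net emissions compared against remaining
# global carbon budgets.

#' Combustion parameters
#'
#' Field-average carbon combusted per unit burned area for boreal North
#' American wildfires. The default (3.325 +/- 1.818 kg C/m2) is the mean
#' and SD across several hundred burned-site measurements in Alaska and
#' western Canada.
#'
#' @param mean_kgC_m2 mean combustion rate, kg C per m2.
#' @param sd_kgC_m2 its standard deviation.
#' @export
combustion_params <- function(mean_kgC_m2 = 3.325, sd_kgC_m2 = 1.818) {
  if (mean_kgC_m2 < 0) stop_config("mean_kgC_m2", "must be >= 0")
  if (sd_kgC_m2 < 0) stop_config("sd_kgC_m2", "must be >= 0")
  structure(list(mean_kgC_m2 = mean_kgC_m2, sd_kgC_m2 = sd_kgC_m2),
            class = "combustion_params")
}

#' Boreal-forest emission-factor species table
#'
#' Carbon-containing species emitted by boreal forest fires with their
#' emission factors (g emitted per kg dry matter combusted), carbon atoms
#' per molecule and molecular weights. Values are transcribed from the
#' boreal-forest column of the Akagi et al. (2011, Atmos. Chem. Phys.)
#' biomass-burning compilation; the list covers CO2, CO, CH4 and the major
#' identified non-methane organic species (a partial transcription of the
#' compilation's much longer species list).
#'
#' @return data.frame with columns species, formula, ef_g_per_kg,
#'   carbon_atoms, mw_g_per_mol.
#' @export
boreal_emission_factors <- function() {
  path <- system.file("extdata", "boreal_emission_factors.csv",
                      package = "borealfire", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Derive the carbon-specific CO2 emission factor
#'
#' Emission factors are reported per kilogram of dry matter combusted;
#' converting combusted *carbon* to CO2 requires the fraction of emitted
#' carbon that leaves as CO2 rather than CO, CH4 or other organic species.
#' For each species the carbon mass per kg dry matter is
#' \code{ef * 12.011 * carbon_atoms / mw}; the factor is the CO2 share of
#' the total.
#'
#' @param table a species table as from \code{\link{boreal_emission_factors}}.
#' @return the CO2 carbon fraction \code{f_co2}, a number in (0, 1].
#' @export
derive_co2_fraction <- function(table) {
  need <- c("species", "ef_g_per_kg", "carbon_atoms", "mw_g_per_mol")
  if (!all(need %in% names(table)))
    stop("species table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$ef_g_per_kg < 0) || any(table$mw_g_per_mol <= 0))
    stop("emission factors must be >= 0 and molecular weights > 0",
         call. = FALSE)
  is_co2 <- toupper(table$species) == "CO2"
  if (!any(is_co2)) stop("species table contains no CO2 row", call. = FALSE)
  cmass <- table$ef_g_per_kg * MM_C * table$carbon_atoms / table$mw_g_per_mol
  total <- sum(cmass)
  if (total <= 0) stop("total emitted carbon is zero", call. = FALSE)
  sum(cmass[is_co2]) / total
}

#' Per-hectare CO2 emission rate
#'
#' Converts the combustion rate (kg C/m2) to metric tons of CO2 per
#' hectare burned: 1 kg C/m2 = 10 t C/ha, scaled by the CO2 carbon
#' fraction and the CO2/C molar-mass ratio 44.009/12.011. With defaults
#' this is about 102.3 t CO2/ha.
#'
#' @param comb a \code{\link{combustion_params}}.
#' @param f_co2 carbon-specific CO2 emission factor in (0, 1].
#' @return emission rate e in t CO2 per hectare.
#' @export
per_hectare_emissions <- function(comb = combustion_params(), f_co2 = 0.84) {
  stopifnot(inherits(comb, "combustion_params"))
  if (f_co2 <= 0 || f_co2 > 1) stop_config("f_co2", "must lie in (0, 1]")
  comb$mean_kgC_m2 * 10 * f_co2 * (MM_CO2 / MM_C)
}

#' Gross CO2 emissions from a burned-area series
#'
#' @param series a \code{\link{burned_area_series}}.
#' @param e per-hectare emission rate, t CO2/ha.
#' @return the series with columns \code{gross_tCO2} and \code{gross_GtCO2}.
#' @export
area_to_gross_co2 <- function(series, e) {
  if (e <= 0) stop("per-hectare rate e must be > 0", call. = FALSE)
  if (any(series$burned_ha < 0))
    stop("burned hectares must be >= 0", call. = FALSE)
  series$gross_tCO2 <- series$burned_ha * e
  series$gross_GtCO2 <- series$gross_tCO2 / 1e9
  series
}

#' Linearly extrapolate a projection study to a target year
#'
#' Literature projections report a total percent increase in burned area
#' over heterogeneous spans. Assuming a linear increase over each study's
#' span, the percent increase at the target year is
#' \code{pct * (target - start) / (end - start)}; a study ending before
#' the target is extended along the same line.
#'
#' @param study one row of a projection-study table.
#' @param target_year year at which to evaluate the increase.
#' @return percent increase in annual burned area at \code{target_year}.
#' @export
extrapolate_projection <- function(study, target_year = 2050) {
  if (target_year <= study$start_year)
    stop("target_year must exceed the study start year", call. = FALSE)
  study$pct_increase * (target_year - study$start_year) /
    (study$end_year - study$start_year)
}

#' Quartile bounds of extrapolated projections
#'
#' Extrapolates every study for a region to the target year and returns
#' the lower and upper quartiles of the percent increases, using linear
#' interpolation between order statistics (the type-7 quantile
#' convention).
#'
#' @param studies projection-study table (all rows used; filter by region
#'   beforehand if needed).
#' @param target_year target year.
#' @return named numeric vector \code{c(lower, upper)}.
#' @export
projection_bounds <- function(studies, target_year = 2050) {
  if (nrow(studies) < 2)
    stop("at least 2 projection studies are required", call. = FALSE)
  pct <- vapply(seq_len(nrow(studies)), function(i)
    extrapolate_projection(studies[i, ], target_year), numeric(1))
  q <- stats::quantile(pct, c(0.25, 0.75), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Build a future burned-area scenario
#'
#' Annual burned area ramps linearly from the baseline at the start year
#' to \code{baseline * (1 + pct/100)} at the end year.
#'
#' @param baseline_ha_per_year baseline annual burned hectares (by
#'   convention the modern-period mean).
#' @param pct_at_end percent increase reached in the final year.
#' @param start_year,end_year scenario span (default 2020--2050).
#' @param region region label.
#' @export
build_scenario <- function(baseline_ha_per_year, pct_at_end,
                           start_year = 2020, end_year = 2050,
                           region = "scenario") {
  assert_positive(baseline_ha_per_year, "baseline_ha_per_year")
  if (pct_at_end <= -100) stop_config("pct_at_end", "must exceed -100")
  years <- seq(start_year, end_year)
  frac <- (years - start_year) / (end_year - start_year)
  burned_area_series(region, years,
                     baseline_ha_per_year * (1 + pct_at_end / 100 * frac))
}

#' Post-fire regrowth (net ecosystem productivity) curve
#'
#' Normalized annual uptake fractions u_t for years t = 0..payback after a
#' fire. Recovering boreal stands are assumed carbon-neutral for the first
#' \code{lag_years} (about 14 years: early decomposition losses and early
#' regrowth are not modelled separately), after which cumulative uptake
#' integrates to exactly the combustion pulse by \code{payback_years}
#' (about 150). The default shape spreads uptake uniformly between lag and
#' payback; "triangular" rises linearly to a peak midway and declines.
#'
#' @param lag_years years of zero net flux after fire.
#' @param payback_years year by which uptake equals the emission pulse.
#' @param shape "constant" or "triangular".
#' @return a \code{regrowth_curve}: list with \code{uptake_fraction}
#'   (indexed t = 0..payback; \code{sum(uptake_fraction) == 1}).
#' @export
make_regrowth_curve <- function(lag_years = 14, payback_years = 150,
                                shape = c("constant", "triangular")) {
  shape <- match.arg(shape)
  if (lag_years < 0 || lag_years >= payback_years)
    stop_config("lag_years", "must satisfy 0 <= lag < payback")
  t <- 0:payback_years
  active <- t >= lag_years
  u <- numeric(length(t))
  if (shape == "constant") {
    u[active] <- 1
  } else {
    # symmetric triangle peaking midway between lag and payback
    u[active] <- pmin(t[active] - lag_years + 1, payback_years - t[active] + 1)
  }
  u <- u / sum(u)
  structure(list(lag_years = lag_years, payback_years = payback_years,
                 shape = shape, uptake_fraction = u),
            class = "regrowth_curve")
}

# cumulative uptake fraction recovered `elapsed` years after fire
recovered_fraction <- function(curve, elapsed) {
  vapply(elapsed, function(k) {
    if (k < 0) 0
    else sum(curve$uptake_fraction[seq_len(min(k, curve$payback_years) + 1)])
  }, numeric(1))
}

#' Net CO2 emissions at a horizon year, by burn cohort
#'
#' For each cohort year y in the series (cohorts after the horizon are
#' excluded), net emissions at the horizon are the gross pulse less the
#' cumulative regrowth uptake over the elapsed horizon - y years:
#' \code{net_y = gross_y * (1 - sum(u_t, t = 0..horizon-y))}.
#'
#' @param series a \code{\link{burned_area_series}}.
#' @param e per-hectare emission rate, t CO2/ha.
#' @param curve a \code{\link{make_regrowth_curve}}.
#' @param horizon horizon year (default 2050).
#' @return an \code{emissions_ledger}: data.frame(year, burned_ha,
#'   gross_tCO2, recovered_fraction, net_tCO2_at_horizon) with the horizon
#'   stored as an attribute.
#' @export
net_emissions_at_horizon <- function(series, e, curve, horizon = 2050) {
  stopifnot(inherits(curve, "regrowth_curve"))
  if (horizon < min(series$year))
    stop("horizon precedes the first cohort year", call. = FALSE)
  keep <- series$year <= horizon
  led <- area_to_gross_co2(series[keep, , drop = FALSE], e)
  rec <- recovered_fraction(curve, horizon - led$year)
  led$recovered_fraction <- rec
  led$net_tCO2_at_horizon <- led$gross_tCO2 * (1 - rec)
  led$gross_GtCO2 <- NULL
  attr(led, "horizon") <- horizon
  class(led) <- c("emissions_ledger", "data.frame")
  led
}

#' Period totals of an emissions ledger
#'
#' @param ledger an \code{emissions_ledger}.
#' @param period inclusive year pair (default 2021--2050, the future
#'   accounting period).
#' @return list with burned hectares, gross and net totals (t and Gt CO2).
#' @export
period_totals <- function(ledger, period = c(2021, 2050)) {
  sel <- ledger$year >= period[1] & ledger$year <= period[2]
  list(burned_ha = sum(ledger$burned_ha[sel]),
       gross_tCO2 = sum(ledger$gross_tCO2[sel]),
       net_tCO2 = sum(ledger$net_tCO2_at_horizon[sel]),
       gross_GtCO2 = sum(ledger$gross_tCO2[sel]) / 1e9,
       net_GtCO2 = sum(ledger$net_tCO2_at_horizon[sel]) / 1e9)
}

#' Avoided emissions between two management regimes
#'
#' Difference of period net totals between a projected ledger (current
#' suppression maintained under an intensifying fire regime) and a
#' counterfactual ledger (e.g. burned area held at the historical regime).
#'
#' @param projected,counterfactual ledgers sharing a horizon.
#' @param period accounting period, default 2021--2050.
#' @return avoided emissions in Gt CO2 (negative if the counterfactual
#'   exceeds the projection).
#' @export
avoided_emissions <- function(projected, counterfactual,
                              period = c(2021, 2050)) {
  if (!identical(attr(projected, "horizon"), attr(counterfactual, "horizon")))
    stop("ledgers have mismatched horizons", call. = FALSE)
  period_totals(projected, period)$net_GtCO2 -
    period_totals(counterfactual, period)$net_GtCO2
}

#' Remaining global CO2 budget table
#'
#' IPCC AR6 remaining carbon budgets (Gt CO2 from 2020) by temperature
#' target and probability of staying below it.
#'
#' @export
ipcc_budget_table <- function() {
  data.frame(
    temperature_target_c = rep(c(1.5, 2.0), each = 3),
    probability_pct = rep(c(33, 50, 67), 2),
    remaining_budget_GtCO2 = c(650, 500, 400, 1700, 1350, 1150))
}

#' Share of a remaining carbon budget
#'
#' @param net_GtCO2 net emissions, Gt CO2.
#' @param budgets a budget table as from \code{\link{ipcc_budget_table}}.
#' @param target temperature target in degrees C.
#' @param probability probability (percent) of staying below the target.
#' @return percent of the remaining budget consumed.
#' @export
budget_share <- function(net_GtCO2, budgets = ipcc_budget_table(),
                         target = 1.5, probability = 67) {
  row <- budgets$temperature_target_c == target &
    budgets$probability_pct == probability
  if (sum(row) != 1)
    stop(sprintf("no unique budget row for %.1f degC at %d%%",
                 target, probability), call. = FALSE)
  100 * net_GtCO2 / budgets$remaining_budget_GtCO2[row]
}
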