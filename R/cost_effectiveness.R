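# Cost-effectiveness of fire suppression as an emissions-reduction
# strategy: the hectare-weighted cost per avoided metric ton of CO2, its
# uncertainty, the fuel-use emissions scenario, and the investment needed
# to hold emissions at historical levels.

#' Hectare-weighted cost per avoided metric ton of CO2
#'
#' For fire i with burned area A_i (ha), management cost C_i (USD),
#' per-hectare emission rate e_i (t CO2/ha) and spending elasticity beta
#' (percent fire-size reduction per percent spending increase), the
#' statistic is the hectare-weighted average of per-fire marginal costs:
#' \deqn{\sum_i \frac{A_i}{\sum_j A_j} \cdot \frac{C_i}{A_i \, |\beta| \, e_i}}
#' A 1 percent spending increase on fire i costs C_i/100 and avoids
#' |beta|/100 x A_i x e_i tons, so each ratio is that fire's marginal
#' cost per ton; hectare weighting aggregates to the per-ton cost of the
#' average burned hectare.
#'
#' @param areas_ha per-fire burned areas (> 0).
#' @param costs_usd per-fire management costs (>= 0).
#' @param beta spending elasticity; only its magnitude is used.
#' @param e_per_ha per-hectare emission rate(s), t CO2/ha (scalar or
#'   per-fire vector).
#' @return list with \code{point_usd_per_tCO2}, \code{n_fires},
#'   \code{weight_check} (sum of hectare weights) and \code{weights}.
#' @export
cost_per_ton <- function(areas_ha, costs_usd, beta, e_per_ha) {
  if (any(areas_ha <= 0)) stop("all areas must be > 0", call. = FALSE)
  if (any(e_per_ha <= 0)) stop("all emission rates must be > 0",
                               call. = FALSE)
  if (beta == 0)
    stop(paste("beta = 0: no spending elasticity of fire size;",
               "estimate it with estimate_elasticity_iv() first"),
         call. = FALSE)
  n <- length(areas_ha)
  stopifnot(length(costs_usd) == n)
  e <- rep_len(e_per_ha, n)
  w <- areas_ha / sum(areas_ha)
  point <- sum(w * costs_usd / (areas_ha * abs(beta) * e))
  list(point_usd_per_tCO2 = point, n_fires = n,
       weight_check = sum(w), weights = w)
}

#' Uncertainty ranges for the cost per avoided ton
#'
#' The standard-error range re-evaluates the statistic at |beta| plus and
#' minus one standard error (larger elasticities mean cheaper avoided
#' tons, so the +1 SE end is the low bound). The 95 percent interval is a
#' seeded joint percentile bootstrap: fires are resampled with
#' replacement while beta is drawn from its sampling distribution. If
#' |beta| - SE is not positive the upper end of the SE range is
#' unbounded and flagged.
#'
#' @inheritParams cost_per_ton
#' @param beta_se standard error of beta (> 0).
#' @param n_boot bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @return list with the point estimate, \code{se_range}, \code{ci95},
#'   \code{unbounded} flag and method metadata.
#' @export
cost_per_ton_uncertainty <- function(areas_ha, costs_usd, beta, beta_se,
                                     e_per_ha, n_boot = 1000, seed = 1) {
  if (beta_se <= 0) stop("beta_se must be > 0", call. = FALSE)
  if (n_boot < 200) stop("n_boot must be >= 200", call. = FALSE)
  point <- cost_per_ton(areas_ha, costs_usd, beta,
                        e_per_ha)$point_usd_per_tCO2
  lo <- cost_per_ton(areas_ha, costs_usd, abs(beta) + beta_se,
                     e_per_ha)$point_usd_per_tCO2
  unbounded <- (abs(beta) - beta_se) <= 0
  hi <- if (unbounded) Inf else
    cost_per_ton(areas_ha, costs_usd, abs(beta) - beta_se,
                 e_per_ha)$point_usd_per_tCO2
  n <- length(areas_ha)
  e <- rep_len(e_per_ha, n)
  boot <- with_local_seed(seed, {
    replicate(n_boot, {
      idx <- sample(n, replace = TRUE)
      b <- stats::rnorm(1, abs(beta), beta_se)
      while (abs(b) < 1e-8) b <- stats::rnorm(1, abs(beta), beta_se)
      cost_per_ton(areas_ha[idx], costs_usd[idx], b,
                   e[idx])$point_usd_per_tCO2
    })
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  list(point_usd_per_tCO2 = point,
       se_range = c(low = lo, high = hi),
       ci95 = c(low = ci[1], high = ci[2]),
       unbounded = unbounded, n_boot = n_boot,
       method = "joint percentile bootstrap over fires and beta")
}

#' Fuel-use emissions scenario
#'
#' Upper-bound scenario for CO2 emitted by the suppression effort itself:
#' a share of total expenditures (default 25 percent) is assumed spent on
#' fuel, split between jet fuel and gasoline, converted to liters at
#' per-liter prices and to CO2 with per-liter emission coefficients.
#'
#' @param fuel_share share of expenditure spent on fuel, in [0, 1].
#' @param split named shares by fuel type (sums to 1).
#' @param price_per_liter named prices, USD per liter.
#' @param kg_co2_per_liter named emission coefficients, kg CO2 per liter.
#' @export
fuel_scenario <- function(fuel_share = 0.25,
                          split = c(jet = 0.5, gasoline = 0.5),
                          price_per_liter = c(jet = 0.55, gasoline = 0.65),
                          kg_co2_per_liter = c(jet = 2.53, gasoline = 2.35)) {
  if (fuel_share < 0 || fuel_share > 1)
    stop_config("fuel_share", "must lie in [0, 1]")
  split <- assert_simplex(split, "split")
  if (any(price_per_liter <= 0)) stop_config("price_per_liter",
                                             "must be positive")
  if (any(kg_co2_per_liter <= 0)) stop_config("kg_co2_per_liter",
                                              "must be positive")
  stopifnot(setequal(names(split), names(price_per_liter)),
            setequal(names(split), names(kg_co2_per_liter)))
  structure(list(fuel_share = fuel_share, split = split,
                 price_per_liter = price_per_liter[names(split)],
                 kg_co2_per_liter = kg_co2_per_liter[names(split)]),
            class = "fuel_scenario")
}

#' CO2 emissions from fuel burned during fire management
#'
#' @param total_expenditure_usd total suppression expenditure (>= 0).
#' @param scenario a \code{\link{fuel_scenario}}.
#' @param net_emissions_tCO2 optional wildfire net emissions against
#'   which to express the result as a percent share.
#' @return list with per-fuel liters and tons, \code{total_tCO2}, and
#'   \code{share_of_net_pct} when a reference total is supplied.
#' @export
fuel_emissions <- function(total_expenditure_usd,
                           scenario = fuel_scenario(),
                           net_emissions_tCO2 = NULL) {
  stopifnot(inherits(scenario, "fuel_scenario"))
  if (total_expenditure_usd < 0)
    stop("expenditure must be >= 0", call. = FALSE)
  liters <- total_expenditure_usd * scenario$fuel_share * scenario$split /
    scenario$price_per_liter
  tons <- liters * scenario$kg_co2_per_liter / 1000
  out <- list(liters = liters, tCO2_by_fuel = tons,
              total_tCO2 = sum(tons))
  if (!is.null(net_emissions_tCO2))
    out$share_of_net_pct <- 100 * out$total_tCO2 / net_emissions_tCO2
  out
}

#' Investment required to hold burned area at historical levels
#'
#' For each year of the period, the percent burned-area reduction needed
#' to bring the projected area down to the historical baseline is
#' \code{r_t = 100 (projected_t - baseline) / projected_t} (floored at
#' zero); via the elasticity, the percent spending increase is
#' \code{r_t / |beta|}, applied to the season-level baseline spending.
#'
#' @param projected a \code{\link{burned_area_series}} covering the
#'   period.
#' @param historical_baseline_ha historical-regime annual burned hectares.
#' @param baseline_spending_usd average annual fire-management spending
#'   (default $133M, the approximate Alaskan season).
#' @param beta spending elasticity (magnitude used).
#' @param period inclusive year pair.
#' @return list with a per-year data.frame (year, projected_ha,
#'   reduction_pct, spending_increase_pct, spending_usd) and
#'   \code{cumulative_usd}.
#' @export
required_investment <- function(projected, historical_baseline_ha,
                                baseline_spending_usd = 133e6,
                                beta = -0.21, period = c(2021, 2030)) {
  if (abs(beta) <= 0) stop("beta must be nonzero", call. = FALSE)
  sel <- projected$year >= period[1] & projected$year <= period[2]
  if (!setequal(projected$year[sel], seq(period[1], period[2])))
    stop("projected series does not cover the period", call. = FALSE)
  df <- projected[sel, c("year", "burned_ha")]
  names(df)[2] <- "projected_ha"
  zero <- df$projected_ha == 0
  if (any(zero)) {
    warning(sprintf("%d year(s) with zero projected area skipped",
                    sum(zero)), call. = FALSE)
    df <- df[!zero, , drop = FALSE]
  }
  df$reduction_pct <- pmax(
    0, 100 * (df$projected_ha - historical_baseline_ha) / df$projected_ha)
  df$spending_increase_pct <- df$reduction_pct / abs(beta)
  df$spending_usd <- baseline_spending_usd *
    (1 + df$spending_increase_pct / 100)
  rownames(df) <- NULL
  list(plan = df,
       cumulative_usd = sum(df$spending_usd),
       baseline_spending_usd = baseline_spending_usd,
       beta = beta)
}
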