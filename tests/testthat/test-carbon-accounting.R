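test_that("CO2 carbon fraction normalizes by molecular-weight-adjusted carbon", {
  only_co2 <- data.frame(species = "CO2", ef_g_per_kg = 1489,
                         carbon_atoms = 1, mw_g_per_mol = 44.009)
  expect_equal(derive_co2_fraction(only_co2), 1.0)

  two <- data.frame(species = c("CO2", "CO"),
                    ef_g_per_kg = c(1489, 127),
                    carbon_atoms = c(1, 1),
                    mw_g_per_mol = c(44.01, 28.01))
  # hand arithmetic: 1489*12.011/44.01 = 406.3; 127*12.011/28.01 = 54.5
  expect_equal(derive_co2_fraction(two), 0.8818, tolerance = 0.0005)

  no_co2 <- two[2, ]
  expect_error(derive_co2_fraction(no_co2), "no CO2 row")
})

test_that("per-hectare emission rate applies the unit chain kgC/m2 -> tCO2/ha", {
  expect_equal(per_hectare_emissions(combustion_params(3.325), 0.84),
               102.33, tolerance = 0.2)
  expect_equal(per_hectare_emissions(combustion_params(0.1), 1),
               0.1 * 10 * 44.009 / 12.011)
  expect_equal(per_hectare_emissions(combustion_params(0), 0.84), 0)
})

test_that("gross emissions are linear in burned area", {
  s <- burned_area_series("x", 2000, 1e6)
  g <- area_to_gross_co2(s, 102.33)
  expect_equal(g$gross_GtCO2, 0.10233, tolerance = 1e-9)
  expect_equal(area_to_gross_co2(burned_area_series("x", 2000, 0),
                                 102.33)$gross_tCO2, 0)
  s2 <- burned_area_series("x", 2000:2004, c(1, 2, 3, 4, 5) * 1e5)
  expect_equal(area_to_gross_co2(burned_area_series("x", 2000:2004,
                                                    2 * s2$burned_ha),
                                 50)$gross_tCO2,
               2 * area_to_gross_co2(s2, 50)$gross_tCO2)
})

test_that("projection extrapolation assumes a linear increase over the span", {
  st <- function(s, e, p) data.frame(start_year = s, end_year = e,
                                     pct_increase = p)
  expect_equal(extrapolate_projection(st(2020, 2100, 300), 2050), 112.5)
  expect_equal(extrapolate_projection(st(2020, 2050, 24), 2050), 24)
  expect_equal(extrapolate_projection(st(2020, 2035, 30), 2050), 60)
  expect_error(extrapolate_projection(st(2050, 2080, 10), 2050),
               "target_year")
})

test_that("projection bounds are type-7 quartiles and match a brute-force oracle", {
  mk <- function(p) data.frame(region = "r", start_year = 2020,
                               end_year = 2050, pct_increase = p)
  expect_equal(projection_bounds(mk(c(24, 50, 100, 169))),
               c(lower = 43.5, upper = 117.25))
  expect_equal(projection_bounds(mk(c(36, 36, 36))),
               c(lower = 36, upper = 36))
  expect_equal(projection_bounds(mk(c(36, 150))),
               c(lower = 64.5, upper = 121.5))
  expect_error(projection_bounds(mk(24)), "at least 2")

  set.seed(7)
  for (i in 1:20) {
    vals <- round(runif(sample(2:12, 1), -50, 300), 2)
    expect_equal(unname(projection_bounds(mk(vals))),
                 oracle_quartiles(vals))
  }
})

test_that("scenario ramps linearly from the baseline", {
  s <- build_scenario(100, 50)
  expect_equal(s$burned_ha[s$year == 2035], 125)
  expect_equal(s$burned_ha[s$year == 2050], 150)
  expect_equal(nrow(s), 31)
  expect_true(all(build_scenario(100, 0)$burned_ha == 100))
  expect_error(build_scenario(100, -100), "-100")
})

test_that("regrowth curves respect the lag and integrate to the pulse", {
  cv <- make_regrowth_curve(14, 150)
  u <- cv$uptake_fraction
  expect_equal(u[1:14], rep(0, 14)) # years 0..13 post-fire
  expect_equal(sum(u), 1)
  expect_equal(unique(u[15:151]), 1 / 137)

  cv2 <- make_regrowth_curve(0, 1)
  expect_equal(cv2$uptake_fraction, c(0.5, 0.5))

  tri <- make_regrowth_curve(14, 150, shape = "triangular")
  expect_equal(sum(tri$uptake_fraction), 1, tolerance = 1e-9)
  expect_equal(tri$uptake_fraction[1:14], rep(0, 14))
  expect_error(make_regrowth_curve(150, 150), "lag")
})

test_that("net emissions at the horizon follow cumulative uptake by cohort", {
  e <- 102.33
  cv <- make_regrowth_curve(14, 150)

  led <- net_emissions_at_horizon(burned_area_series("x", 2040, 1e5), e, cv)
  expect_equal(led$net_tCO2_at_horizon, led$gross_tCO2) # within the lag

  led2 <- net_emissions_at_horizon(burned_area_series("x", 1900, 1e5), e,
                                   cv, horizon = 2050)
  expect_equal(led2$net_tCO2_at_horizon, 0) # beyond payback

  led3 <- net_emissions_at_horizon(burned_area_series("x", 1960, 1e5), e, cv)
  expect_equal(led3$net_tCO2_at_horizon,
               led3$gross_tCO2 * (1 - 77 / 137)) # uptake years 14..90

  expect_error(net_emissions_at_horizon(burned_area_series("x", 2000, 1),
                                        e, cv, horizon = 1990), "horizon")
})

test_that("cohort conservation and monotonicity of the accounting", {
  e <- 100
  cv <- make_regrowth_curve(5, 40)
  yrs <- 1995:2020
  ha <- seq_along(yrs) * 1000
  led <- net_emissions_at_horizon(burned_area_series("x", yrs, ha), e, cv,
                                  2050)
  # gross - net = e * ha * recovered fraction, per cohort
  expect_equal(led$gross_tCO2 - led$net_tCO2_at_horizon,
               e * led$burned_ha * led$recovered_fraction)
  expect_true(all(led$net_tCO2_at_horizon >= 0))
  expect_true(all(led$net_tCO2_at_horizon <= led$gross_tCO2))
  # more elapsed regrowth time means less net
  expect_true(all(diff(led$net_tCO2_at_horizon / led$gross_tCO2) >= 0))
  # net totals non-decreasing in the projection percentage
  nets <- vapply(c(0, 50, 100), function(pct) {
    l <- net_emissions_at_horizon(build_scenario(1e5, pct), e, cv, 2050)
    period_totals(l)$net_GtCO2
  }, numeric(1))
  expect_true(all(diff(nets) > 0))
})

test_that("avoided emissions are the difference of period net totals", {
  e <- 102.33
  cv <- make_regrowth_curve(14, 150)
  proj <- net_emissions_at_horizon(build_scenario(1e6, 100), e, cv)
  base <- net_emissions_at_horizon(build_scenario(5e5, 0), e, cv)
  expect_equal(avoided_emissions(proj, proj), 0)
  av <- avoided_emissions(proj, base)
  expect_equal(av, period_totals(proj)$net_GtCO2 -
                 period_totals(base)$net_GtCO2)
  # linear accounting: doubling both areas doubles avoided emissions
  proj2 <- net_emissions_at_horizon(build_scenario(2e6, 100), e, cv)
  base2 <- net_emissions_at_horizon(build_scenario(1e6, 0), e, cv)
  expect_equal(avoided_emissions(proj2, base2), 2 * av)
  bad <- net_emissions_at_horizon(build_scenario(5e5, 0), e, cv,
                                  horizon = 2049)
  expect_error(avoided_emissions(proj, bad), "horizon")
})

test_that("budget shares match the published worked examples", {
  expect_lt(abs(budget_share(11.93, target = 1.5, probability = 67) - 2.98),
            0.005)
  expect_lt(abs(budget_share(1.33, target = 1.5, probability = 67) - 0.33),
            0.005)
  expect_equal(budget_share(0), 0)
  expect_error(budget_share(1, target = 1.7, probability = 67), "no unique")
  # for a fixed target, higher probability means a smaller budget
  tab <- ipcc_budget_table()
  for (tgt in unique(tab$temperature_target_c)) {
    sub <- tab[tab$temperature_target_c == tgt, ]
    sub <- sub[order(sub$probability_pct), ]
    expect_true(all(diff(sub$remaining_budget_GtCO2) < 0))
  }
})

test_that("Monte-Carlo combustion uncertainty converges near the point rate", {
  # draws of the combustion rate, floored at zero, propagated to t CO2/ha
  set.seed(123)
  mu <- 3.325; sg <- 1.818
  draws <- pmax(rnorm(10000, mu, sg), 0)
  e_draws <- vapply(draws, function(m)
    per_hectare_emissions(combustion_params(m), 0.84), numeric(1))
  # closed-form mean of the floored normal: mu*pnorm(mu/sg) + sg*dnorm(mu/sg)
  m_trunc <- mu * pnorm(mu / sg) + sg * dnorm(mu / sg)
  expected <- per_hectare_emissions(combustion_params(m_trunc), 0.84)
  mc_se <- sd(e_draws) / sqrt(length(e_draws))
  expect_lt(abs(mean(e_draws) - expected), 3 * mc_se)
  # the zero floor shifts the rate by well under 2% of the point estimate
  point <- per_hectare_emissions(combustion_params(mu), 0.84)
  expect_lt(abs(mean(e_draws) - point) / point, 0.02)
})
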