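test_that("total-cost reconstruction applies the limited-zone exception", {
  costs <- data.frame(fire_id = c("a", "b", "c"),
                      blm_cost_usd = c(50000, 50000, 70000),
                      blm_fraction = c(0.5, 0.5, 1.0),
                      fmz = c("full", "limited", "critical"))
  out <- reconstruct_total_cost(costs)
  expect_equal(out$total_cost_usd, c(100000, 50000, 70000))
  costs$blm_fraction[1] <- 0
  expect_error(reconstruct_total_cost(costs), "blm_fraction")
})

test_that("exclusion rules use a strict 1% threshold and keep exact books", {
  ct <- generate_fire_catalog(catalog_config(n_fires = 5), 1)
  costs <- data.frame(fire_id = ct$fire_id,
                      blm_cost_usd = 1000, blm_fraction = 1,
                      fmz = ct$fmz,
                      blm_area_ha = ct$size_ha,
                      total_area_ha = ct$size_ha,
                      total_cost_usd = 1000)
  costs$blm_area_ha[1] <- 1.02 * costs$total_area_ha[1] # violates
  costs$blm_area_ha[2] <- 1.01 * costs$total_area_ha[2] # boundary: retained
  res <- apply_exclusions(costs, ct)
  expect_equal(nrow(res$frame), 4)
  expect_equal(unname(res$log["blm_area_over"]), 1)
  expect_true(any(res$frame$fire_id == costs$fire_id[2]))

  # no violations: identity with an empty exclusion log
  res2 <- apply_exclusions(costs[-1, ], ct)
  expect_equal(nrow(res2$frame), 4)
  expect_true(all(res2$log[c("unmatched", "blm_area_over",
                             "out_of_region")] == 0))

  # unjoinable ids are reported, never silently dropped
  costs$fire_id[3] <- "GHOST"
  expect_warning(res3 <- apply_exclusions(costs, ct), "no catalog match")
  expect_equal(unname(res3$log["unmatched"]), 1)

  # bookkeeping identity under a region mask as well
  mask <- setNames(rep(c(FALSE, TRUE), c(2, 3)), ct$fire_id)
  res4 <- suppressWarnings(apply_exclusions(costs, ct, region_mask = mask))
  lg <- res4$log
  expect_equal(unname(lg["rows_in"]),
               unname(lg["rows_out"] + lg["unmatched"] +
                        lg["blm_area_over"] + lg["out_of_region"]))
})

test_that("LASSO recovers strong controls and stays quiet under the null", {
  hits <- vapply(1:20, function(s) {
    ct <- generate_fire_catalog(catalog_config(n_fires = 5000), s)
    sim <- generate_cost_table(
      ct, econ_config(size_weather_coefs = c(max_temp_c = 0.5,
                                             mean_temp_c = 0.4)), s + 1000)
    fr <- build_econ_frame(apply_exclusions(
      reconstruct_total_cost(sim$costs), sim$catalog)$frame)
    sel <- select_controls(fr, candidates = c("max_temp_c", "mean_temp_c",
                                              "max_dmc", "max_fwi",
                                              "max_isi", "max_bui",
                                              "black_spruce", "white_spruce",
                                              "deciduous", "grass"),
                           seed = s)
    all(c("max_temp_c", "mean_temp_c") %in% sel)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  null_counts <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 400
    fr <- data.frame(log_area = rnorm(n),
                     matrix(rnorm(n * 8), n,
                            dimnames = list(NULL, paste0("x", 1:8))))
    length(suppressWarnings(
      select_controls(fr, candidates = paste0("x", 1:8), seed = s)))
  }, numeric(1))
  expect_lte(mean(null_counts), 1)

  expect_error(select_controls(data.frame(log_area = 1), character()),
               "no candidates")
  expect_error(select_controls(data.frame(log_area = 1, fmz = "full"),
                               c("fmz")), "not eligible")
})

test_that("LASSO tolerates a duplicated active control", {
  ct <- generate_fire_catalog(catalog_config(n_fires = 3000), 77)
  sim <- generate_cost_table(ct, econ_config(), 78)
  fr <- build_econ_frame(apply_exclusions(
    reconstruct_total_cost(sim$costs), sim$catalog)$frame)
  fr$max_temp_dup <- fr$max_temp_c + rnorm(nrow(fr), 0, 1e-6)
  sel <- select_controls(fr, candidates = c("max_temp_c", "max_temp_dup",
                                            "mean_temp_c", "max_fwi"),
                         seed = 79)
  expect_true(any(c("max_temp_c", "max_temp_dup") %in% sel))
})

test_that("IV and OLS agree under exogeneity and 2SLS is consistent in n", {
  ct <- generate_fire_catalog(catalog_config(n_fires = 4000), 51)
  sim <- generate_cost_table(ct, econ_config(endogeneity_corr = 0), 52)
  fr <- build_econ_frame(apply_exclusions(
    reconstruct_total_cost(sim$costs), sim$catalog)$frame)
  ctl <- c("max_temp_c", "mean_temp_c")
  iv <- suppressWarnings(estimate_elasticity_iv(fr, ctl))
  ols <- estimate_elasticity_ols(fr, ctl)
  expect_lt(abs(iv$beta_hat - ols$beta_hat), 2 * iv$se)

  # bias shrinks with n under endogeneity
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      r <- iv_replicate(s, n = n)
      r$iv$beta_hat
    }, numeric(1))) - (-0.21)
  }
  b8000 <- bias_at(8000, 1:3)
  expect_lt(abs(b8000), 0.03) # well within Monte-Carlo tolerance
  b500 <- bias_at(500, 1:3)
  expect_lt(abs(b8000), abs(b500) + 0.03)
})

test_that("OLS bias direction under positive error correlation matches
           simultaneity algebra", {
  # with corr(u, v) > 0 the OLS slope is pulled toward
  # beta + cov(u, v) / var(s | controls), i.e. upward (toward zero here)
  est <- vapply(1:10, function(s) {
    r <- iv_replicate(s, n = 2000, with_ols = TRUE)
    r$ols$beta_hat
  }, numeric(1))
  expect_gt(mean(est), -0.21) # biased upward
  expect_lt(mean(est), 0)     # but not sign-flipped at this strength
})

test_that("an irrelevant instrument is flagged with a null-range F", {
  ct <- generate_fire_catalog(catalog_config(n_fires = 2000), 61)
  cfg <- econ_config(fmz_cost_offsets = c(critical = 0, full = 0,
                                          modified = 0, limited = 0))
  sim <- generate_cost_table(ct, cfg, 62)
  fr <- build_econ_frame(apply_exclusions(
    reconstruct_total_cost(sim$costs), sim$catalog)$frame)
  expect_warning(iv <- estimate_elasticity_iv(fr, c("max_temp_c")),
                 "weak instrument")
  # under the null the F statistic has mean about df2/(df2-2), near 1
  expect_lt(iv$first_stage_F, 5)
})

test_that("first-stage F increases with instrument strength", {
  ct <- generate_fire_catalog(catalog_config(n_fires = 2000), 63)
  fs <- vapply(c(0.5, 1, 2), function(scale) {
    cfg <- econ_config(fmz_cost_offsets = scale *
                         c(critical = 2.2, full = 1.2, modified = 0.5,
                           limited = 0))
    sim <- generate_cost_table(ct, cfg, 64)
    fr <- build_econ_frame(apply_exclusions(
      reconstruct_total_cost(sim$costs), sim$catalog)$frame)
    suppressWarnings(
      estimate_elasticity_iv(fr, c("max_temp_c")))$first_stage_F
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("alternate specifications behave and converge across transforms", {
  r <- iv_replicate(91, n = 3000, specs = TRUE)
  expect_equal(r$specs$spec_label,
               c("primary", "blm_costs", "lightning_only", "plus_0.01",
                 "asinh"))
  expect_equal(nrow(r$specs), 5)

  # log(C+1) vs log(C+0.01): for all-positive costs the gap shrinks as
  # costs grow; compare estimates on a low-cost and a high-cost frame
  gap <- vapply(c(6, 12), function(kappa) {
    ct <- generate_fire_catalog(catalog_config(n_fires = 3000), 92)
    cfg <- econ_config(log_cost_intercept = kappa, zero_cost_rate = 0)
    sim <- generate_cost_table(ct, cfg, 93)
    fr <- build_econ_frame(apply_exclusions(
      reconstruct_total_cost(sim$costs), sim$catalog)$frame)
    sp <- suppressWarnings(run_alternate_specs(fr))
    abs(sp$beta_hat[sp$spec_label == "primary"] -
          sp$beta_hat[sp$spec_label == "plus_0.01"])
  }, numeric(1))
  expect_lt(gap[2], gap[1])

  # no lightning fires: four rows plus a warning
  fr <- r$frame[r$frame$cause != "lightning", ]
  expect_warning(sp <- run_alternate_specs(fr, r$controls),
                 "lightning")
  expect_equal(nrow(sp), 4)
})

test_that("road subgroups share the elasticity unless roads erode the
           instrument", {
  r <- iv_replicate(101, n = 4000)
  road <- suppressWarnings(road_subgroup_analysis(r$frame, r$controls))
  expect_named(road$subgroups, c("with_roads", "without_roads"))
  # generator uses one beta for all fires: no interaction
  expect_lt(abs(road$interaction$z), 2)

  # near-perfect road/zone association starves the roaded subgroup of
  # zone variation and its first-stage F drops below the pooled F
  worse <- vapply(1:20, function(s) {
    cfg <- catalog_config(
      n_fires = 1500,
      road_fmz_assoc = c(critical = 0.995, full = 0.9, modified = 0.05,
                         limited = 0.005))
    ct <- generate_fire_catalog(cfg, s + 300)
    sim <- generate_cost_table(ct, econ_config(), s + 400)
    fr <- build_econ_frame(apply_exclusions(
      reconstruct_total_cost(sim$costs), sim$catalog)$frame)
    pooled <- suppressWarnings(estimate_elasticity_iv(fr))
    rd <- suppressWarnings(road_subgroup_analysis(fr))
    if (is.null(rd$subgroups$with_roads)) return(NA)
    rd$subgroups$with_roads$first_stage_F < pooled$first_stage_F
  }, logical(1))
  expect_gt(mean(worse, na.rm = TRUE), 0.5)

  # all-roadless frame: single subgroup plus a warning
  fr0 <- r$frame
  fr0$road_access <- FALSE
  expect_warning(rd0 <- road_subgroup_analysis(fr0, r$controls),
                 "skipped")
  expect_null(rd0$subgroups$with_roads)
  expect_null(rd0$interaction)
})

test_that("rank-deficient designs are rejected with named columns", {
  r <- iv_replicate(111, n = 1000)
  fr <- r$frame
  fr$dup <- fr$max_temp_c
  expect_error(suppressWarnings(
    estimate_elasticity_iv(fr, c("max_temp_c", "dup"))),
    "collinear")
})
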