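# Shared fixtures: small configs, an independent quantile oracle, and a
# one-shot IV replication used by several tests.

# catalog config with no weather/cause structure and a chosen zone layout
plain_catalog_config <- function(n_fires, offsets = c(critical = 0, full = 0,
                                                      modified = 0,
                                                      limited = 0),
                                 noise_sd = 1, intercept = 2,
                                 probs = c(critical = 0.25, full = 0.25,
                                           modified = 0.25, limited = 0.25)) {
  catalog_config(
    n_fires = n_fires, fmz_probs = probs,
    fmz_log_size_offsets = offsets,
    cause_log_size_offsets = c(human = 0, lightning = 0, undetermined = 0),
    weather_coefs = numeric(0),
    log_size_intercept = intercept, log_size_noise_sd = noise_sd)
}

# explicit order-statistic interpolation quantile (independent of
# stats::quantile): h = (n - 1) p + 1, linear between floor/ceiling
oracle_quartiles <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  one <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  c(one(0.25), one(0.75))
}

# generate one synthetic catalog + cost table and estimate the elasticity
iv_replicate <- function(seed, n = 825, econ = econ_config(),
                         with_ols = FALSE, specs = FALSE) {
  ct <- generate_fire_catalog(catalog_config(n_fires = n), seed)
  sim <- generate_cost_table(ct, econ, seed + 500000)
  fr <- build_econ_frame(
    apply_exclusions(reconstruct_total_cost(sim$costs), sim$catalog)$frame)
  ctr <- suppressWarnings(select_controls(fr, seed = seed))
  iv <- suppressWarnings(estimate_elasticity_iv(fr, ctr))
  out <- list(iv = iv, frame = fr, controls = ctr)
  if (with_ols) out$ols <- estimate_elasticity_ols(fr, ctr)
  if (specs) out$specs <- suppressWarnings(run_alternate_specs(fr, ctr))
  out
}

# deterministic toy frame for fire-size model unit tests
toy_catalog <- function() {
  data.frame(
    fire_id = paste0("T", 1:5),
    year = c(2001, 2005, 2010, 1999, 2010),
    discovery_doy = c(135, 152, 200, 180, 243),
    extinguish_doy = c(140, 160, 230, 200, 250),
    duration_days = c(5, 8, 30, 20, 7),
    cause = c("human", "lightning", "lightning", "human", "undetermined"),
    fmz = c("critical", "full", "modified", "limited", "limited"),
    size_ha = c(1, 10, 100, 1000, 50),
    stringsAsFactors = FALSE)
}
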