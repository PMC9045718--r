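# Synthetic fire catalogs, suppression-cost tables, burned-area histories
# and projection-study tables. The generators emulate the statistical
# structure of agency fire records (log-normal fire sizes driven by
# management zone, weather and cause; suppression costs endogenous to fire
# size with the management zone as a valid instrument) so that every
# downstream stage can be exercised and verified without restricted data.

#' Configuration for the synthetic fire-catalog generator
#'
#' Describes the generative model for individual fires: log fire size is
#' the sum of an intercept, an additive fire-management-zone (FMZ) offset,
#' an additive cause offset, a linear effect of standardized fire-weather
#' covariates, and Gaussian noise. Zone offsets default to the ordering
#' critical < full < modified < limited, i.e. fires in heavily suppressed
#' zones are smaller, mirroring the suppression-priority continuum of
#' Alaskan fire management.
#'
#' @param n_fires number of fires to generate.
#' @param year_range inclusive pair of calendar years.
#' @param fmz_probs named 4-simplex over zones
#'   \code{c(critical, full, modified, limited)}.
#' @param cause_probs named 3-simplex over
#'   \code{c(human, lightning, undetermined)}.
#' @param fmz_log_size_offsets per-zone additive effect on log size (ha).
#' @param cause_log_size_offsets per-cause additive effect on log size.
#' @param weather_coefs named additive effects of standardized weather
#'   covariates on log size (any subset of
#'   \code{max_temp_c, mean_temp_c, max_dmc, max_fwi, max_isi, max_bui}).
#' @param log_size_intercept intercept of the log-size model.
#' @param log_size_noise_sd positive residual standard deviation.
#' @param veg_concentration Dirichlet concentration for vegetation
#'   fractions (larger = less dispersed).
#' @param season_window inclusive day-of-year pair for discovery dates
#'   (default 152--243, i.e. 1 June to 31 August in a non-leap year).
#' @param road_fmz_assoc named per-zone probability of road access.
#' @return an object of class \code{catalog_config}.
#' @export
catalog_config <- function(n_fires = 3411,
                           year_range = c(2000L, 2018L),
                           fmz_probs = c(critical = 0.10, full = 0.30,
                                         modified = 0.15, limited = 0.45),
                           cause_probs = c(human = 0.30, lightning = 0.60,
                                           undetermined = 0.10),
                           fmz_log_size_offsets = c(critical = 0, full = 1.5,
                                                    modified = 2.5,
                                                    limited = 3.5),
                           cause_log_size_offsets = c(human = -1.0,
                                                      lightning = 0,
                                                      undetermined = -0.5),
                           weather_coefs = c(max_temp_c = 0.35,
                                             mean_temp_c = 0.30,
                                             max_dmc = 0.25, max_fwi = 0.15,
                                             max_isi = 0.10, max_bui = 0.10),
                           log_size_intercept = 0.5,
                           log_size_noise_sd = 1.9,
                           veg_concentration = 5,
                           season_window = c(152L, 243L),
                           road_fmz_assoc = c(critical = 0.9, full = 0.5,
                                              modified = 0.3, limited = 0.1)) {
  if (!is.numeric(n_fires) || length(n_fires) != 1 || n_fires < 0 ||
      n_fires != round(n_fires))
    stop_config("n_fires", "must be a nonnegative integer")
  if (length(year_range) != 2 || year_range[2] < year_range[1])
    stop_config("year_range", "must be an inclusive, non-empty year pair")
  fmz_probs <- assert_simplex(fmz_probs, "fmz_probs", FMZ_LEVELS)
  cause_probs <- assert_simplex(cause_probs, "cause_probs", CAUSE_LEVELS)
  if (is.null(names(fmz_log_size_offsets)) ||
      !setequal(names(fmz_log_size_offsets), FMZ_LEVELS))
    stop_config("fmz_log_size_offsets", "must name all four zones")
  if (is.null(names(cause_log_size_offsets)) ||
      !setequal(names(cause_log_size_offsets), CAUSE_LEVELS))
    stop_config("cause_log_size_offsets", "must name all three causes")
  if (length(weather_coefs) &&
      !all(names(weather_coefs) %in% WEATHER_VARS))
    stop_config("weather_coefs", paste0("names must be among {",
                paste(WEATHER_VARS, collapse = ", "), "}"))
  assert_positive(log_size_noise_sd, "log_size_noise_sd")
  assert_positive(veg_concentration, "veg_concentration")
  if (length(season_window) != 2 || season_window[2] < season_window[1])
    stop_config("season_window", "must be an ordered day-of-year pair")
  if (is.null(names(road_fmz_assoc)) ||
      !setequal(names(road_fmz_assoc), FMZ_LEVELS) ||
      any(road_fmz_assoc < 0 | road_fmz_assoc > 1))
    stop_config("road_fmz_assoc", "must be per-zone probabilities in [0,1]")
  structure(list(n_fires = as.integer(n_fires),
                 year_range = as.integer(year_range),
                 fmz_probs = fmz_probs,
                 cause_probs = cause_probs,
                 fmz_log_size_offsets = fmz_log_size_offsets[FMZ_LEVELS],
                 cause_log_size_offsets = cause_log_size_offsets[CAUSE_LEVELS],
                 weather_coefs = weather_coefs,
                 log_size_intercept = log_size_intercept,
                 log_size_noise_sd = log_size_noise_sd,
                 veg_concentration = veg_concentration,
                 season_window = as.integer(season_window),
                 road_fmz_assoc = road_fmz_assoc[FMZ_LEVELS]),
            class = "catalog_config")
}

# Fixed correlation structure of the six fire-weather summaries
# (temperatures strongly inter-correlated; moisture/behaviour indices
# moderately so; temperature and indices positively associated).
weather_correlation <- function() {
  r <- diag(6)
  dimnames(r) <- list(WEATHER_VARS, WEATHER_VARS)
  r["max_temp_c", "mean_temp_c"] <- r["mean_temp_c", "max_temp_c"] <- 0.85
  idx <- c("max_dmc", "max_fwi", "max_isi", "max_bui")
  for (a in c("max_temp_c", "mean_temp_c")) for (b in idx)
    r[a, b] <- r[b, a] <- 0.40
  for (i in seq_along(idx)) for (j in seq_along(idx)) if (i != j)
    r[idx[i], idx[j]] <- 0.50
  r
}

# location/scale used to map standardized weather scores to natural units
WEATHER_LOC <- c(max_temp_c = 22, mean_temp_c = 14, max_dmc = 60,
                 max_fwi = 20, max_isi = 10, max_bui = 80)
WEATHER_SCALE <- c(max_temp_c = 6, mean_temp_c = 5, max_dmc = 30,
                   max_fwi = 10, max_isi = 5, max_bui = 35)
WEATHER_FLOOR <- c(max_temp_c = -Inf, mean_temp_c = -Inf, max_dmc = 0,
                   max_fwi = 0, max_isi = 0, max_bui = 0)

#' Generate a synthetic fire catalog
#'
#' Draws \code{n_fires} fire records under the generative model described
#' in \code{\link{catalog_config}}. All randomness flows from a private
#' stream seeded by \code{seed}; the same configuration and seed yield
#' bit-identical catalogs and the caller's RNG state is left untouched.
#'
#' @param config a \code{\link{catalog_config}}.
#' @param seed integer seed.
#' @return a data.frame with one row per fire: id, year, discovery and
#'   extinguishment day-of-year, duration, cause, fmz, size in hectares,
#'   five vegetation fractions, six fire-weather summaries and road access.
#' @export
generate_fire_catalog <- function(config, seed) {
  stopifnot(inherits(config, "catalog_config"))
  n <- config$n_fires
  empty <- data.frame(fire_id = character(), year = integer(),
                      discovery_doy = integer(), extinguish_doy = integer(),
                      duration_days = integer(), cause = character(),
                      fmz = character(), size_ha = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  with_local_seed(seed, {
    years <- sample(seq(config$year_range[1], config$year_range[2]),
                    n, replace = TRUE)
    fmz <- sample(FMZ_LEVELS, n, replace = TRUE, prob = config$fmz_probs)
    cause <- sample(CAUSE_LEVELS, n, replace = TRUE,
                    prob = config$cause_probs)
    doy <- sample(seq(config$season_window[1], config$season_window[2]),
                  n, replace = TRUE)
    duration <- pmin(stats::rpois(n, 12), 120L)

    # standardized weather scores with fixed correlation, then mapped to
    # natural units and truncated at physical floors
    z <- MASS::mvrnorm(n, mu = rep(0, 6), Sigma = weather_correlation())
    colnames(z) <- WEATHER_VARS
    wx <- sweep(sweep(z, 2, WEATHER_SCALE, `*`), 2, WEATHER_LOC, `+`)
    wx <- pmax(wx, rep(WEATHER_FLOOR, each = n))
    # enforce max temperature >= mean temperature
    wx[, "max_temp_c"] <- pmax(wx[, "max_temp_c"], wx[, "mean_temp_c"])

    veg_alpha <- config$veg_concentration *
      c(0.30, 0.15, 0.20, 0.15, 0.10, 0.10)
    veg <- rdirichlet(n, veg_alpha)[, 1:5, drop = FALSE]
    colnames(veg) <- VEG_CLASSES

    wcoef <- config$weather_coefs
    weff <- if (length(wcoef)) {
      drop(z[, names(wcoef), drop = FALSE] %*% wcoef)
    } else rep(0, n)
    log_size <- config$log_size_intercept +
      config$fmz_log_size_offsets[fmz] +
      config$cause_log_size_offsets[cause] +
      weff + stats::rnorm(n, 0, config$log_size_noise_sd)

    road <- stats::rbinom(n, 1, config$road_fmz_assoc[fmz]) == 1

    out <- data.frame(
      fire_id = sprintf("F%d-%05d", years, seq_len(n)),
      year = years,
      discovery_doy = doy,
      extinguish_doy = doy + duration,
      duration_days = duration,
      cause = cause,
      fmz = fmz,
      size_ha = exp(unname(log_size)),
      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(veg), as.data.frame(wx))
    out$road_access <- road
    rownames(out) <- NULL
    out
  })
}

#' Configuration for the endogenous suppression-cost generator
#'
#' Parameterizes the joint structural model behind the instrumental-variable
#' design: log total cost is driven by the fire-management zone (the
#' instrument), observable controls and a disturbance; log fire size is
#' driven by the cost transform (elasticity \code{beta_true}), the same
#' controls and a second disturbance correlated with the first
#' (\code{endogeneity_corr}). The zone affects size only through cost, so
#' the exclusion restriction holds by construction.
#'
#' @param beta_true structural elasticity of fire size with respect to
#'   suppression cost (default -0.21: a 1\% spending increase shrinks
#'   burned area by 0.21\%).
#' @param fmz_cost_offsets per-zone additive effect on log cost, ordered
#'   critical > full > modified > limited.
#' @param endogeneity_corr correlation between the size and cost
#'   disturbances, in [-1, 1].
#' @param cost_noise_sd,size_noise_sd positive disturbance SDs.
#' @param zero_cost_rate probability that a fire is monitored only and
#'   receives a recorded cost of exactly zero.
#' @param blm_fraction_shape Beta shape parameters for the fraction of a
#'   fire's area under federal (BLM) protection outside limited zones.
#' @param log_cost_intercept,log_size_intercept structural intercepts.
#' @param cost_weather_coefs,size_weather_coefs named effects of
#'   standardized weather covariates in the cost and size equations.
#' @export
econ_config <- function(beta_true = -0.21,
                        fmz_cost_offsets = c(critical = 2.2, full = 1.2,
                                             modified = 0.5, limited = 0),
                        endogeneity_corr = 0.5,
                        cost_noise_sd = 1.0,
                        size_noise_sd = 1.0,
                        zero_cost_rate = 0.05,
                        blm_fraction_shape = c(18, 2),
                        log_cost_intercept = 10.5,
                        log_size_intercept = 5.6,
                        cost_weather_coefs = c(max_temp_c = 0.30,
                                               max_dmc = 0.20),
                        size_weather_coefs = c(max_temp_c = 0.50,
                                               mean_temp_c = 0.40)) {
  if (abs(endogeneity_corr) > 1)
    stop_config("endogeneity_corr", "must lie in [-1, 1]")
  if (zero_cost_rate < 0 || zero_cost_rate > 1)
    stop_config("zero_cost_rate", "must lie in [0, 1]")
  assert_positive(cost_noise_sd, "cost_noise_sd")
  assert_positive(size_noise_sd, "size_noise_sd")
  if (is.null(names(fmz_cost_offsets)) ||
      !setequal(names(fmz_cost_offsets), FMZ_LEVELS))
    stop_config("fmz_cost_offsets", "must name all four zones")
  if (length(blm_fraction_shape) != 2 || any(blm_fraction_shape <= 0))
    stop_config("blm_fraction_shape", "must be two positive Beta shapes")
  structure(list(beta_true = beta_true,
                 fmz_cost_offsets = fmz_cost_offsets[FMZ_LEVELS],
                 endogeneity_corr = endogeneity_corr,
                 cost_noise_sd = cost_noise_sd,
                 size_noise_sd = size_noise_sd,
                 zero_cost_rate = zero_cost_rate,
                 blm_fraction_shape = blm_fraction_shape,
                 log_cost_intercept = log_cost_intercept,
                 log_size_intercept = log_size_intercept,
                 cost_weather_coefs = cost_weather_coefs,
                 size_weather_coefs = size_weather_coefs),
            class = "econ_config")
}

#' Generate a cost table jointly with regenerated fire sizes
#'
#' Simulates the endogenous structural system on top of an existing
#' catalog. Log total cost C and log fire size A are drawn jointly with
#' bivariate-normal disturbances; size responds to the cost transform
#' log(1 + C) with elasticity \code{beta_true}. A \code{zero_cost_rate}
#' share of fires is monitored without intervention (cost exactly zero).
#' In limited zones the BLM covers all costs, so the recorded BLM cost
#' equals the total and the protected fraction is 1; elsewhere the BLM
#' cost is the total scaled by a Beta-distributed protected fraction.
#'
#' Because the size column of the input catalog is replaced by the
#' structural draw, the returned value carries both tables.
#'
#' @param catalog a fire catalog from \code{\link{generate_fire_catalog}}.
#' @param config an \code{\link{econ_config}}.
#' @param seed integer seed.
#' @return list with elements \code{costs} (one row per fire: BLM cost,
#'   protected fraction, zone, areas, true total cost) and \code{catalog}
#'   (the input catalog with regenerated \code{size_ha}).
#' @export
generate_cost_table <- function(catalog, config, seed) {
  stopifnot(inherits(config, "econ_config"))
  if (!is.data.frame(catalog) || nrow(catalog) == 0)
    stop("catalog must be a nonempty fire catalog", call. = FALSE)
  n <- nrow(catalog)
  with_local_seed(seed, {
    zw <- scale(as.matrix(catalog[, WEATHER_VARS, drop = FALSE]))
    zw[is.nan(zw)] <- 0

    rho <- config$endogeneity_corr
    sig <- matrix(c(config$size_noise_sd^2,
                    rho * config$size_noise_sd * config$cost_noise_sd,
                    rho * config$size_noise_sd * config$cost_noise_sd,
                    config$cost_noise_sd^2), 2, 2)
    uv <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = sig)

    dcoef <- config$cost_weather_coefs
    ccontrols <- if (length(dcoef))
      drop(zw[, names(dcoef), drop = FALSE] %*% dcoef) else rep(0, n)
    log_cost <- config$log_cost_intercept +
      config$fmz_cost_offsets[catalog$fmz] + ccontrols + uv[, 2]

    zero <- stats::runif(n) < config$zero_cost_rate
    total_cost <- ifelse(zero, 0, exp(unname(log_cost)))
    s <- log1p(total_cost)

    gcoef <- config$size_weather_coefs
    scontrols <- if (length(gcoef))
      drop(zw[, names(gcoef), drop = FALSE] %*% gcoef) else rep(0, n)
    log_area <- config$log_size_intercept + config$beta_true * s +
      scontrols + uv[, 1]
    catalog$size_ha <- exp(unname(log_area))

    limited <- catalog$fmz == "limited"
    frac <- stats::rbeta(n, config$blm_fraction_shape[1],
                         config$blm_fraction_shape[2])
    frac <- pmin(pmax(frac, 1e-6), 1)
    frac[limited] <- 1
    blm_cost <- ifelse(limited, total_cost, total_cost * frac)

    costs <- data.frame(
      fire_id = catalog$fire_id,
      blm_cost_usd = blm_cost,
      blm_fraction = frac,
      fmz = catalog$fmz,
      blm_area_ha = frac * catalog$size_ha,
      total_area_ha = catalog$size_ha,
      total_cost_usd = total_cost,
      stringsAsFactors = FALSE)
    list(costs = costs, catalog = catalog)
  })
}

#' Generate a trending annual burned-area series
#'
#' Annual expected burned area follows a compounding multiplicative trend
#' from \code{base_ha_per_year} at \code{start_year}; realized values add
#' multiplicative lognormal noise with unit mean and the given coefficient
#' of variation (CV 0 gives the deterministic trend).
#'
#' @param region label, e.g. "alaska", "canada" or "combined".
#' @param start_year,end_year inclusive span.
#' @param base_ha_per_year expected burned hectares at \code{start_year}.
#' @param trend_pct_per_decade percent growth in expectation per decade.
#' @param lognormal_cv coefficient of variation of the noise (>= 0).
#' @param seed integer seed (ignored when \code{lognormal_cv} is 0).
#' @return a \code{burned_area_series}: data.frame(region, year, burned_ha).
#' @export
generate_burned_area_history <- function(region, start_year, end_year,
                                         base_ha_per_year,
                                         trend_pct_per_decade = 0,
                                         lognormal_cv = 0, seed = 1) {
  assert_positive(base_ha_per_year, "base_ha_per_year")
  if (end_year < start_year)
    stop_config("start_year/end_year", "must satisfy start <= end")
  if (lognormal_cv < 0) stop_config("lognormal_cv", "must be >= 0")
  years <- seq(start_year, end_year)
  mu <- base_ha_per_year *
    (1 + trend_pct_per_decade / 100)^((years - start_year) / 10)
  ha <- if (lognormal_cv > 0) {
    with_local_seed(seed, {
      s2 <- log(1 + lognormal_cv^2)
      mu * stats::rlnorm(length(years), meanlog = -s2 / 2, sdlog = sqrt(s2))
    })
  } else mu
  burned_area_series(region, years, ha)
}

#' Construct a burned-area series object
#'
#' @param region region label.
#' @param years contiguous integer years.
#' @param burned_ha nonnegative burned hectares, one per year.
#' @export
burned_area_series <- function(region, years, burned_ha) {
  if (any(burned_ha < 0)) stop("burned hectares must be >= 0", call. = FALSE)
  if (length(years) != length(burned_ha))
    stop("years and burned_ha must have equal length", call. = FALSE)
  if (length(years) > 1 && any(diff(years) != 1))
    stop("years must be contiguous", call. = FALSE)
  structure(data.frame(region = region, year = as.integer(years),
                       burned_ha = as.numeric(burned_ha),
                       stringsAsFactors = FALSE),
            class = c("burned_area_series", "data.frame"))
}

#' Build a validated table of burned-area projection studies
#'
#' Each entry records a literature projection: region, projection span and
#' total percent increase in annual burned area over that span.
#'
#' @param entries a list of entries, each a list or vector with fields
#'   \code{region}, \code{start_year}, \code{end_year},
#'   \code{pct_increase}; or a data.frame with those columns.
#' @return data.frame of validated projection studies.
#' @export
make_projection_studies <- function(entries) {
  if (is.data.frame(entries)) {
    df <- entries
  } else {
    if (length(entries) == 0)
      return(data.frame(region = character(), start_year = integer(),
                        end_year = integer(), pct_increase = numeric(),
                        stringsAsFactors = FALSE))
    df <- do.call(rbind, lapply(entries, function(e) {
      e <- as.list(e)
      data.frame(region = as.character(e$region),
                 start_year = as.integer(e$start_year),
                 end_year = as.integer(e$end_year),
                 pct_increase = as.numeric(e$pct_increase),
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) == 0) return(df)
  if (any(df$end_year <= df$start_year))
    stop("projection study with end_year <= start_year", call. = FALSE)
  if (any(df$pct_increase <= -100))
    stop("pct_increase must exceed -100", call. = FALSE)
  rownames(df) <- NULL
  df
}
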