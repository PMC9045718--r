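# Suppression-cost econometrics: total-cost reconstruction, exclusion
# rules, LASSO control selection, two-stage least squares with
# fire-management-zone instruments, alternate specifications, and the
# road-access subgroup analysis.
#
# Suppression spending and fire size are simultaneously determined (big
# fires attract spending; spending shrinks fires), so OLS of log size on
# log cost is biased. The management zone is assigned before any fire
# starts and is a strong predictor of spending, but plausibly affects
# burned area only through the suppression channel -- the classic
# instrument conditions.

#' Reconstruct total suppression cost from the federal (BLM) share
#'
#' Total cost is approximately the BLM cost divided by the fraction of
#' burned hectares under BLM protection, except in limited zones, where
#' the BLM covers all costs and the BLM cost is the total.
#'
#' @param costs cost table with \code{blm_cost_usd}, \code{blm_fraction},
#'   \code{fmz}.
#' @return the table with a \code{total_cost_usd} column (recomputed).
#' @export
reconstruct_total_cost <- function(costs) {
  if (any(costs$blm_fraction <= 0 | costs$blm_fraction > 1))
    stop("blm_fraction must lie in (0, 1]", call. = FALSE)
  costs$total_cost_usd <- ifelse(costs$fmz == "limited",
                                 costs$blm_cost_usd,
                                 costs$blm_cost_usd / costs$blm_fraction)
  costs
}

#' Apply the per-fire exclusion rules
#'
#' Joins the cost table to the catalog on fire id and removes (1) fires
#' whose reported BLM area exceeds the total area by more than 1 percent
#' (strict inequality: exactly 1.01x is retained), and (2) fires outside
#' the study region when a region mask is supplied. Cost rows with no
#' catalog match are reported and set aside, never silently dropped. The
#' exclusion log satisfies rows_in = rows_out + sum(per-rule counts).
#'
#' @param costs cost table.
#' @param catalog fire catalog.
#' @param region_mask optional logical vector named by fire id; FALSE
#'   marks a fire outside the study region.
#' @return list(frame = merged retained rows, log = named counts).
#' @export
apply_exclusions <- function(costs, catalog, region_mask = NULL) {
  rows_in <- nrow(costs)
  matched <- costs$fire_id %in% catalog$fire_id
  if (any(!matched))
    warning(sprintf("%d cost rows had no catalog match: %s",
                    sum(!matched),
                    paste(utils::head(costs$fire_id[!matched], 5),
                          collapse = ", ")), call. = FALSE)
  merged <- merge(costs[matched, , drop = FALSE],
                  catalog[, setdiff(names(catalog), "fmz"), drop = FALSE],
                  by = "fire_id", sort = TRUE)
  over <- merged$blm_area_ha > 1.01 * merged$total_area_ha
  merged <- merged[!over, , drop = FALSE]
  out_of_region <- if (is.null(region_mask)) {
    rep(FALSE, nrow(merged))
  } else {
    !region_mask[merged$fire_id] %in% TRUE
  }
  merged <- merged[!out_of_region, , drop = FALSE]
  rownames(merged) <- NULL
  list(frame = merged,
       log = c(rows_in = rows_in,
               unmatched = sum(!matched),
               blm_area_over = sum(over),
               out_of_region = sum(out_of_region),
               rows_out = nrow(merged)))
}

cost_transforms <- list(
  log1p = function(c) log1p(c),
  plus001 = function(c) log(c + 0.01),
  asinh = function(c) asinh(c))

#' Assemble the econometric estimation frame
#'
#' @param frame merged catalog/cost rows (e.g. from
#'   \code{\link{apply_exclusions}}).
#' @return the frame with \code{log_area} and factor columns added.
#' @export
build_econ_frame <- function(frame) {
  frame$log_area <- log(frame$total_area_ha)
  frame$fmz <- factor(frame$fmz, levels = FMZ_LEVELS)
  frame$cause <- factor(frame$cause, levels = CAUSE_LEVELS)
  frame
}

#' Default candidate control variables
#' @param frame an estimation frame.
#' @export
default_candidates <- function(frame) {
  cand <- c(WEATHER_VARS, VEG_CLASSES, "cause", "year")
  cand[cand %in% names(frame)]
}

#' LASSO selection of control variables
#'
#' Selects controls for the elasticity regressions by an L1-penalized
#' regression of log area on the standardized candidates, with the penalty
#' chosen by seeded 10-fold cross-validation (the conservative
#' one-standard-error rule by default). The zone instrument and the cost
#' variable are never eligible. A factor candidate is selected when any of
#' its indicator columns survives.
#'
#' @param frame an estimation frame with \code{log_area}.
#' @param candidates candidate variable names.
#' @param seed integer seed for the fold assignment.
#' @param rule "lambda.1se" (default) or "lambda.min".
#' @return character vector of selected candidate names (possibly empty,
#'   with a warning).
#' @export
select_controls <- function(frame, candidates = default_candidates(frame),
                            seed = 1, rule = c("lambda.1se", "lambda.min")) {
  rule <- match.arg(rule)
  if (length(candidates) == 0) stop("no candidates supplied", call. = FALSE)
  if (any(candidates %in% c("fmz", "total_cost_usd", "blm_cost_usd")))
    stop("the instrument and cost variables are not eligible controls",
         call. = FALSE)
  x <- stats::model.matrix(
    stats::reformulate(candidates, intercept = TRUE), data = frame)[, -1,
                                                                    drop = FALSE]
  y <- frame$log_area
  foldid <- with_local_seed(seed,
    sample(rep(seq_len(10), length.out = nrow(frame))))
  cv <- glmnet::cv.glmnet(x, y, foldid = foldid, standardize = TRUE)
  coefs <- as.matrix(stats::coef(cv, s = rule))[-1, 1]
  live <- names(coefs)[coefs != 0]
  assign_map <- attr(stats::model.matrix(
    stats::reformulate(candidates, intercept = TRUE), data = frame),
    "assign")[-1]
  selected <- unique(candidates[assign_map[match(live, colnames(x))]])
  if (length(selected) == 0)
    warning("LASSO shrank every candidate to zero; no controls selected",
            call. = FALSE)
  selected
}

build_design <- function(frame, controls) {
  if (length(controls) == 0) return(NULL)
  stats::model.matrix(stats::reformulate(controls, intercept = TRUE),
                      data = frame)[, -1, drop = FALSE]
}

#' Two-stage least-squares elasticity of fire size w.r.t. spending
#'
#' Stage 1 regresses the cost transform (default log(1 + C), retaining
#' monitored zero-cost fires at transform value 0) on zone indicators and
#' the controls, and reports the classical F statistic on the excluded
#' zone instruments; stage 2 regresses log area on the fitted cost
#' transform and the same controls. The reported coefficient is the
#' elasticity: the average percent change in burned area per 1 percent
#' change in expenditure. Standard errors are heteroskedasticity-robust
#' (HC1 sandwich on the second stage with structural residuals). A
#' first-stage F below 10 triggers a weak-instrument warning.
#'
#' @param frame an estimation frame from \code{\link{build_econ_frame}}.
#' @param controls control variable names (typically from
#'   \code{\link{select_controls}}).
#' @param cost_col cost column to use.
#' @param transform one of "log1p", "plus001", "asinh".
#' @param spec_label label recorded in the result.
#' @return an \code{iv_result}: beta_hat, se, ci95, first_stage_F, dfs,
#'   n, controls, spec_label.
#' @export
estimate_elasticity_iv <- function(frame, controls = character(),
                                   cost_col = "total_cost_usd",
                                   transform = c("log1p", "plus001", "asinh"),
                                   spec_label = "primary") {
  transform <- match.arg(transform)
  zones <- droplevels(factor(frame$fmz))
  if (nlevels(zones) < 2)
    stop("need at least 2 zones for the instrument", call. = FALSE)
  n <- nrow(frame)
  s <- cost_transforms[[transform]](frame[[cost_col]])
  w <- build_design(frame, controls)
  zmat <- stats::model.matrix(~zones)[, -1, drop = FALSE]
  n_inst <- ncol(zmat)

  X <- cbind(`(Intercept)` = 1, cost = s, w)
  Z <- cbind(`(Intercept)` = 1, zmat, w)
  k <- ncol(X)
  if (n <= k + 10) stop("too few observations", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  # first-stage F on the excluded instruments (classical)
  fs_full <- stats::lm.fit(Z, s)
  null_design <- if (is.null(w)) matrix(1, n, 1) else cbind(1, w)
  fs_null <- stats::lm.fit(null_design, s)
  rss1 <- sum(fs_full$residuals^2)
  rss0 <- sum(fs_null$residuals^2)
  df2 <- n - ncol(Z)
  first_F <- ((rss0 - rss1) / n_inst) / (rss1 / df2)
  if (is.finite(first_F) && first_F < 10)
    warning(sprintf("weak instrument: first-stage F = %.2f < 10 (%s)",
                    first_F, spec_label), call. = FALSE)

  # 2SLS with HC1 sandwich on the structural residuals
  Xhat <- Z %*% solve(crossprod(Z), crossprod(Z, X))
  A <- solve(crossprod(Xhat))
  b <- drop(solve(crossprod(Xhat, X), crossprod(Xhat, frame$log_area)))
  e <- drop(frame$log_area - X %*% b)
  meat <- crossprod(Xhat * e)
  V <- A %*% meat %*% A * n / (n - k)
  se <- sqrt(diag(V))
  names(b) <- names(se) <- colnames(X)

  beta <- unname(b["cost"])
  beta_se <- unname(se["cost"])
  structure(list(beta_hat = beta, se = beta_se,
                 ci95 = beta + c(-1, 1) * stats::qnorm(0.975) * beta_se,
                 first_stage_F = first_F,
                 first_stage_df = c(n_inst, df2),
                 n = n, controls = controls,
                 coefficients = b, vcov = V,
                 transform = transform, cost_col = cost_col,
                 spec_label = spec_label),
            class = "iv_result")
}

#' @export
print.iv_result <- function(x, ...) {
  cat(sprintf("2SLS elasticity (%s): %.3f (robust se %.3f), n = %d\n",
              x$spec_label, x$beta_hat, x$se, x$n))
  cat(sprintf("  95%% CI [%.3f, %.3f]; first-stage F(%d, %d) = %.2f\n",
              x$ci95[1], x$ci95[2], x$first_stage_df[1],
              x$first_stage_df[2], x$first_stage_F))
  invisible(x)
}

#' OLS counterpart of the elasticity regression
#'
#' Used to gauge the simultaneity bias that motivates the instrument;
#' robust (HC1) standard errors via the sandwich estimator.
#'
#' @inheritParams estimate_elasticity_iv
#' @export
estimate_elasticity_ols <- function(frame, controls = character(),
                                    cost_col = "total_cost_usd",
                                    transform = "log1p") {
  s <- cost_transforms[[transform]](frame[[cost_col]])
  dat <- data.frame(log_area = frame$log_area, cost = s)
  w <- build_design(frame, controls)
  if (!is.null(w)) dat <- cbind(dat, as.data.frame(w))
  fit <- stats::lm(log_area ~ ., data = dat)
  V <- sandwich::vcovHC(fit, type = "HC1")
  list(beta_hat = unname(stats::coef(fit)["cost"]),
       se = sqrt(V["cost", "cost"]), n = nrow(dat), fit = fit)
}

#' Re-estimate the elasticity under the alternate specifications
#'
#' Five rows: the primary specification (total costs, log(C + 1)); BLM
#' costs instead of reconstructed totals; lightning-caused fires only;
#' adding 0.01 instead of 1 before the log; and the inverse hyperbolic
#' sine transform. The control set from the primary specification is
#' reused throughout.
#'
#' @param frame estimation frame.
#' @param controls control set.
#' @return data.frame with one row per specification.
#' @export
run_alternate_specs <- function(frame, controls = character()) {
  specs <- list(
    primary = list(cost_col = "total_cost_usd", transform = "log1p",
                   subset = NULL),
    blm_costs = list(cost_col = "blm_cost_usd", transform = "log1p",
                     subset = NULL),
    lightning_only = list(cost_col = "total_cost_usd", transform = "log1p",
                          subset = quote(cause == "lightning")),
    plus_0.01 = list(cost_col = "total_cost_usd", transform = "plus001",
                     subset = NULL),
    asinh = list(cost_col = "total_cost_usd", transform = "asinh",
                 subset = NULL))
  rows <- lapply(names(specs), function(lab) {
    sp <- specs[[lab]]
    sub <- frame
    if (!is.null(sp$subset)) {
      sub <- frame[eval(sp$subset, frame), , drop = FALSE]
      if (nrow(sub) == 0) {
        warning(sprintf("specification '%s' has no observations; skipped",
                        lab), call. = FALSE)
        return(NULL)
      }
    }
    r <- estimate_elasticity_iv(sub, controls, cost_col = sp$cost_col,
                                transform = sp$transform, spec_label = lab)
    data.frame(spec_label = lab, beta_hat = r$beta_hat, se = r$se,
               first_stage_F = r$first_stage_F, n = r$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Elasticity by road access, with an interaction test
#'
#' Estimates the elasticity separately for fires with and without road
#' access and tests the difference with a pooled 2SLS in which the cost
#' transform and its road interaction are instrumented by the zone
#' indicators and their road interactions. When road access is strongly
#' associated with zone designation, zone variation within the roaded
#' subgroup collapses and its first-stage F degrades; such subgroups are
#' flagged.
#'
#' @param frame estimation frame with logical \code{road_access}.
#' @param controls control set.
#' @param min_n minimum subgroup size (smaller subgroups are skipped
#'   with a warning).
#' @return list(subgroups = named list of iv_result or NULL,
#'   interaction = list(estimate, se, z, p) or NULL,
#'   weak_flags = named logical).
#' @export
road_subgroup_analysis <- function(frame, controls = character(),
                                   min_n = 30) {
  stopifnot("road_access" %in% names(frame))
  groups <- list(with_roads = frame$road_access,
                 without_roads = !frame$road_access)
  subres <- lapply(names(groups), function(g) {
    sub <- frame[groups[[g]], , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning(sprintf("subgroup '%s' has n = %d < %d; skipped",
                      g, nrow(sub), min_n), call. = FALSE)
      return(NULL)
    }
    tryCatch(estimate_elasticity_iv(sub, controls,
                                    spec_label = paste0("road:", g)),
             error = function(e) {
               warning(sprintf("subgroup '%s' not estimable: %s",
                               g, conditionMessage(e)), call. = FALSE)
               NULL
             })
  })
  names(subres) <- names(groups)

  interaction <- NULL
  if (!any(vapply(subres, is.null, logical(1)))) {
    s <- cost_transforms$log1p(frame$total_cost_usd)
    road <- as.numeric(frame$road_access)
    w <- build_design(frame, controls)
    zones <- droplevels(factor(frame$fmz))
    zmat <- stats::model.matrix(~zones)[, -1, drop = FALSE]
    X <- cbind(1, s, s * road, road, w)
    Z <- cbind(1, zmat, zmat * road, road, w)
    n <- nrow(X); k <- ncol(X)
    # rank-tolerant projection: a near-deterministic road/zone association
    # can leave Z rank-deficient even when the interaction is identified
    Xhat <- stats::lm.fit(Z, X)$fitted.values
    interaction <- tryCatch({
      A <- solve(crossprod(Xhat))
      b <- drop(solve(crossprod(Xhat, X), crossprod(Xhat, frame$log_area)))
      e <- drop(frame$log_area - X %*% b)
      V <- A %*% crossprod(Xhat * e) %*% A * n / (n - k)
      est <- b[3]; se <- sqrt(V[3, 3])
      list(estimate = unname(est), se = unname(se), z = unname(est / se),
           p = 2 * stats::pnorm(-abs(est / se)))
    }, error = function(err) {
      warning("road interaction not estimable (collinear design): ",
              conditionMessage(err), call. = FALSE)
      NULL
    })
  }

  weak <- vapply(subres, function(r)
    !is.null(r) && is.finite(r$first_stage_F) && r$first_stage_F < 10,
    logical(1))
  list(subgroups = subres, interaction = interaction, weak_flags = weak)
}
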