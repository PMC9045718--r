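# Internal helpers shared across modules.

FMZ_LEVELS <- c("critical", "full", "modified", "limited")
CAUSE_LEVELS <- c("human", "lightning", "undetermined")
VEG_CLASSES <- c("black_spruce", "white_spruce", "deciduous", "grass",
                 "other_burnable")
WEATHER_VARS <- c("max_temp_c", "mean_temp_c", "max_dmc", "max_fwi",
                  "max_isi", "max_bui")

# molar masses, g/mol
MM_CO2 <- 44.009
MM_C <- 12.011

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

assert_simplex <- function(p, field, levels = NULL, tol = 1e-8) {
  if (!is.numeric(p) || any(p < 0) || abs(sum(p) - 1) > tol)
    stop_config(field, "must be a nonnegative probability vector summing to 1")
  if (!is.null(levels)) {
    if (is.null(names(p)) || !setequal(names(p), levels))
      stop_config(field, paste0("must be named with levels {",
                                paste(levels, collapse = ", "), "}"))
    p <- p[levels]
  }
  p
}

assert_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  x
}

# Evaluate `expr` under a private RNG stream: the global .Random.seed is
# saved and restored, so generator calls never perturb user random state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Dirichlet draws via independent gammas; rows sum to 1.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
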