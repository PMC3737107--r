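# Internal helpers shared across modules.
#
# Unit conventions, package-wide: transect lengths and coordinates in km
# unless a name says otherwise, perpendicular distances and detection scales
# in m, densities per km^2.  The single m <-> km bridge for the density
# estimators lives in .per_km2() so the 10^6 area factor appears once.

# n * f0 / (2L) with f0 in 1/m and L in km, rescaled to objects per km^2:
# n * f0 / (2 * L * 1000) [per m^2] * 1e6 = 500 * n * f0 / L
.per_km2 <- function(n, f0_per_m, effort_km) {
  500 * n * f0_per_m / effort_km
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded package functions do not perturb
# user-level reproducibility.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed (for sub-tasks run under an outer seed)
# kept well below .Machine$integer.max.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 100003L
}

.stop_schema <- function(msg, file = NULL) {
  if (!is.null(file)) msg <- sprintf("%s [file: %s]", msg, file)
  stop(errorCondition(msg, class = c("nestsurvey_schema_error", "error")))
}

.assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}
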