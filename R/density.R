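#' Construct a density estimate
#'
#' Container for a point density estimate with optional bootstrap
#' uncertainty, used for both nests/km^2 and builders/km^2.
#'
#' @param value Point estimate (objects per km^2), `>= 0`.
#' @param cv Coefficient of variation (fraction), or `NA`.
#' @param ci_low,ci_high 95% interval endpoints, or `NA`.
#' @param n Count of objects behind the estimate.
#' @param effort_km Transect length behind the estimate.
#' @param stratum Habitat label, or `"global"`.
#' @param estimator Short label (`"scnc"`, `"mnc"`, ...).
#' @param unit Unit label for printing.
#' @return A `density_estimate`.
#' @export
density_estimate <- function(value, cv = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, n = NA_integer_,
                             effort_km = NA_real_, stratum = "global",
                             estimator = "manual", unit = "objects/km^2") {
  if (!is.finite(value) || value < 0) stop("`value` must be >= 0", call. = FALSE)
  if (is.finite(cv) && cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  if (is.finite(ci_low) && is.finite(ci_high)) {
    if (ci_low > ci_high) stop("ci_low > ci_high", call. = FALSE)
    # percentile bootstrap intervals can exclude a skewed point estimate only
    # through resampling noise; guard against gross inversions
    if (value < ci_low - 1e-8 || value > ci_high + 1e-8)
      warning("point estimate outside its confidence interval")
  }
  structure(list(value = value, cv = cv, ci_low = ci_low, ci_high = ci_high,
                 n = n, effort_km = effort_km, stratum = stratum,
                 estimator = estimator, unit = unit),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  ci <- if (is.finite(x$ci_low)) sprintf(" [95%% CI %.2f-%.2f]", x$ci_low, x$ci_high) else ""
  cv <- if (is.finite(x$cv)) sprintf(", %%CV = %.2f", 100 * x$cv) else ""
  cat(sprintf("%s (%s): %.2f %s%s%s\n", x$estimator, x$stratum, x$value,
              x$unit, ci, cv))
  invisible(x)
}

#' Nest encounter rate
#'
#' Detections per km of transect.  If per-transect counts and lengths are
#' supplied, a transect-level bootstrap CI is attached.
#'
#' @param n Total number of detections.
#' @param effort_km Total transect length (km), `> 0`.
#' @param transect_counts,transect_lengths_km Optional per-transect counts
#'   and lengths for the bootstrap.
#' @param B Bootstrap resamples (default 999).
#' @param seed RNG seed for the bootstrap.
#' @return A `density_estimate` in nests/km.
#' @examples
#' encounter_rate(36, 12)$value  # 3
#' @export
encounter_rate <- function(n, effort_km, transect_counts = NULL,
                           transect_lengths_km = NULL, B = 999L, seed = 1L) {
  .assert_scalar_pos(effort_km, "effort_km")
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  est <- density_estimate(n / effort_km, n = n, effort_km = effort_km,
                          estimator = "encounter_rate", unit = "nests/km")
  if (!is.null(transect_counts)) {
    stopifnot(length(transect_counts) == length(transect_lengths_km))
    dat <- data.frame(transect_id = seq_along(transect_counts),
                      count = transect_counts, length_km = transect_lengths_km)
    bs <- bootstrap_ci(dat, function(d) sum(d$count) / sum(d$length_km),
                       B = B, seed = seed)
    est$cv <- bs$cv; est$ci_low <- bs$ci_low; est$ci_high <- bs$ci_high
  }
  est
}

#' SCNC nest density from a line-transect survey
#'
#' The conventional distance-sampling estimator `D = n * f(0) / (2L)`, with
#' `f(0)` per m and `L` in km, rescaled to nests per km^2.
#'
#' @param n Number of detected nests (after truncation).
#' @param f0 Estimated pdf of detection distances at 0 (1/m), from a
#'   [fit_detection()] fit, or the fit itself.
#' @param effort_km Total transect length `L` (km).
#' @param stratum Habitat label.
#' @return A `density_estimate` in nests/km^2.
#' @examples
#' scnc_nest_density(100, 1 / 42, 66)$value  # ~18.04
#' @export
scnc_nest_density <- function(n, f0, effort_km, stratum = "global") {
  if (inherits(f0, "detection_fit")) f0 <- f0$f0
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("`f0` must be a single positive number (1/m)", call. = FALSE)
  .assert_scalar_pos(effort_km, "effort_km")
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  density_estimate(.per_km2(n, f0, effort_km), n = n, effort_km = effort_km,
                   stratum = stratum, estimator = "scnc", unit = "nests/km^2")
}

#' MNC builder density from strip transects
#'
#' Marked nest count estimator `D = n / (2 s L t p)`: new nests per unit
#' strip area per day, divided by the per-builder daily nest production rate.
#'
#' @param n_new Number of new nests detected within the strip from the second
#'   visit onwards.
#' @param effort_km One-pass total strip transect length `L` (km).
#' @param s_m Strip half-width (m), from [strip_half_width()].
#' @param t_days Days elapsed between first and last survey.
#' @param p Nest production rate (nests/builder/day), numeric or a
#'   [production_rate()].
#' @param stratum Habitat label.
#' @return A `density_estimate` in builders/km^2.
#' @examples
#' mnc_builder_density(20, 33, 30, 56, 1.143)$value  # ~0.158
#' @export
mnc_builder_density <- function(n_new, effort_km, s_m, t_days, p,
                                stratum = "global") {
  if (inherits(p, "production_rate")) p <- p$p
  .assert_scalar_pos(effort_km, "effort_km")
  .assert_scalar_pos(s_m, "s_m")
  .assert_scalar_pos(t_days, "t_days")
  .assert_scalar_pos(p, "p")
  if (n_new < 0) stop("`n_new` must be >= 0", call. = FALSE)
  value <- n_new / (2 * (s_m / 1000) * effort_km * t_days * p)
  density_estimate(value, n = n_new, effort_km = effort_km, stratum = stratum,
                   estimator = "mnc", unit = "builders/km^2")
}

#' Habitat-area weighted average density
#'
#' Global density as the average of habitat-specific estimates weighted by
#' habitat area: `D = sum(A_h D_h) / sum(A_h)`.  If every component carries a
#' CV, a delta-method CV for the weighted sum of independent strata is
#' attached.
#'
#' @param estimates Named list of `density_estimate` (names = habitats), or a
#'   named numeric vector of densities.
#' @param areas_km2 Named numeric vector of habitat areas (km^2); must cover
#'   every habitat in `estimates`.
#' @return A `density_estimate` with `stratum = "global"`.
#' @examples
#' habitat_weighted_mean(c(DF = 2, OF = 4), c(DF = 1, OF = 1))$value  # 3
#' @export
habitat_weighted_mean <- function(estimates, areas_km2) {
  if (is.numeric(estimates))
    estimates <- lapply(stats::setNames(as.list(estimates), names(estimates)),
                        function(v) density_estimate(v))
  habs <- names(estimates)
  if (is.null(habs) || any(!nzchar(habs)))
    stop("`estimates` must be named by habitat", call. = FALSE)
  missing_area <- setdiff(habs, names(areas_km2))
  if (length(missing_area))
    stop(sprintf("missing area for habitat: %s",
                 paste(missing_area, collapse = ", ")), call. = FALSE)
  A <- areas_km2[habs]
  if (any(!is.finite(A)) || any(A <= 0)) stop("areas must be > 0", call. = FALSE)
  D <- vapply(estimates, `[[`, numeric(1), "value")
  value <- sum(A * D) / sum(A)
  cvs <- vapply(estimates, `[[`, numeric(1), "cv")
  cv <- if (all(is.finite(cvs)) && value > 0)
    sqrt(sum((A * D * cvs)^2)) / sum(A * D) else NA_real_
  ns <- vapply(estimates, `[[`, numeric(1), "n")
  eff <- vapply(estimates, `[[`, numeric(1), "effort_km")
  density_estimate(value, cv = cv,
                   n = if (all(is.finite(ns))) sum(ns) else NA_integer_,
                   effort_km = if (all(is.finite(eff))) sum(eff) else NA_real_,
                   stratum = "global",
                   estimator = estimates[[1L]]$estimator,
                   unit = estimates[[1L]]$unit)
}

#' Transect-level nonparametric bootstrap
#'
#' Resamples whole transects (the replicate unit of a systematic line
#' transect design) with replacement, re-applies `statistic` to each
#' resampled data set, and returns the percentile 95% interval and
#' `cv = sd / mean` of the bootstrap distribution.
#'
#' @param data A data.frame with one row per sampling unit, or with a
#'   `group` column identifying the unit; rows of resampled units are
#'   duplicated as drawn.
#' @param statistic Function of a resampled data.frame returning one number.
#' @param B Number of resamples (default 999).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param group Column naming the resampling unit (default `"transect_id"`;
#'   if absent, rows are treated as units).
#' @return List with `cv`, `ci_low`, `ci_high`, `boot` (the resample values),
#'   and `n_failed`.  Resamples where `statistic` errors are dropped; more
#'   than 20% failures is an error.
#' @export
bootstrap_ci <- function(data, statistic, B = 999L, seed = 1L,
                         group = "transect_id") {
  stopifnot(is.data.frame(data), is.function(statistic))
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  ids <- if (group %in% names(data)) unique(data[[group]]) else seq_len(nrow(data))
  if (length(ids) < 2L)
    stop("need at least 2 resampling units for a bootstrap", call. = FALSE)
  rows_of <- if (group %in% names(data))
    split(seq_len(nrow(data)), factor(data[[group]], levels = ids))
  else as.list(seq_len(nrow(data)))

  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      take <- sample.int(length(ids), replace = TRUE)
      d <- data[unlist(rows_of[take], use.names = FALSE), , drop = FALSE]
      tryCatch(as.numeric(statistic(d)), error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(!is.finite(boot))
  if (n_failed > 0.2 * B)
    stop(sprintf("estimator failed in %d/%d bootstrap resamples", n_failed, B),
         call. = FALSE)
  boot <- boot[is.finite(boot)]
  q <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  m <- mean(boot)
  list(cv = if (m > 0) stats::sd(boot) / m else 0,
       ci_low = q[1L], ci_high = q[2L], boot = boot, n_failed = n_failed)
}
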