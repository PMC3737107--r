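#' Nest production rate
#'
#' Nests built per weaned nest-building individual per day.  Site-specific
#' estimates are rarely available; the commonly borrowed value is 1.143
#' nests/builder/day (%CV = 3.51) from long-term observation of habituated
#' chimpanzees at Tai National Park.
#'
#' @param p Nests per builder per day, `> 0`.
#' @param cv Coefficient of variation (fraction), `>= 0`.
#' @return A `production_rate`.
#' @export
production_rate <- function(p = 1.143, cv = 0.0351) {
  .assert_scalar_pos(p, "p")
  if (!is.finite(cv) || cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  structure(list(p = p, cv = cv), class = "production_rate")
}

#' @export
print.production_rate <- function(x, ...) {
  cat(sprintf("Nest production rate: %.3f nests/builder/day (%%CV = %.2f)\n",
              x$p, 100 * x$cv))
  invisible(x)
}

#' Nest decay rate (mean nest lifetime)
#'
#' @param r Mean time in days until a nest becomes undetectable, `> 0`.
#' @param cv Coefficient of variation (fraction), or `NA`.
#' @return A `decay_rate`.
#' @export
decay_rate <- function(r, cv = NA_real_) {
  .assert_scalar_pos(r, "r")
  if (is.finite(cv) && cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  structure(list(r = r, cv = cv), class = "decay_rate")
}

#' @export
print.decay_rate <- function(x, ...) {
  cv <- if (is.finite(x$cv)) sprintf(" (%%CV = %.2f)", 100 * x$cv) else ""
  cat(sprintf("Nest decay rate: %.1f days%s\n", x$r, cv))
  invisible(x)
}

.value_cv <- function(x) {
  if (inherits(x, "density_estimate")) list(v = x$value, cv = x$cv)
  else if (inherits(x, "decay_rate")) list(v = x$r, cv = x$cv)
  else if (inherits(x, "production_rate")) list(v = x$p, cv = x$cv)
  else list(v = as.numeric(x), cv = NA_real_)
}

#' Back-calculate nest decay rate from paired density estimates
#'
#' The steady-state relation `D_nests = D_builders * p * r` links standing
#' nest density to builder density through the production rate `p` and mean
#' nest lifetime `r`; solving for `r` gives
#' `r = D_nests / (D_builders * p)`.  When every input carries a CV the CV of
#' `r` is propagated by the delta method ([delta_cv()]).
#'
#' @param d_nests Nest density (nests/km^2), numeric or `density_estimate`.
#' @param d_builders Builder density (builders/km^2), numeric or
#'   `density_estimate`.
#' @param p Production rate, numeric or [production_rate()].
#' @return A `decay_rate` in days.
#' @examples
#' solve_decay_rate(167.97, 0.50, 1.143)$r  # 293.9 days
#' @export
solve_decay_rate <- function(d_nests, d_builders, p = production_rate()) {
  dn <- .value_cv(d_nests); db <- .value_cv(d_builders); pp <- .value_cv(p)
  if (!is.finite(db$v) || db$v <= 0)
    stop("decay rate undefined: builder density must be > 0", call. = FALSE)
  if (!is.finite(dn$v) || dn$v <= 0)
    stop("nest density must be > 0", call. = FALSE)
  .assert_scalar_pos(pp$v, "p")
  cvs <- c(dn$cv, db$cv, pp$cv)
  cv <- if (all(is.finite(cvs))) delta_cv(cvs) else NA_real_
  decay_rate(dn$v / (db$v * pp$v), cv = cv)
}

#' Delta-method CV combination
#'
#' First-order error propagation for products and quotients of independent
#' estimates: squared coefficients of variation add, so the combined CV is
#' `sqrt(sum(cv_i^2))`.
#'
#' @param cvs Numeric vector of CVs (fractions), all `>= 0`.
#' @return Combined CV (fraction).
#' @examples
#' delta_cv(c(0.3, 0.4))  # 0.5
#' @export
delta_cv <- function(cvs) {
  if (length(cvs) == 0L) return(0)
  if (any(!is.finite(cvs)) || any(cvs < 0))
    stop("all CVs must be finite and >= 0", call. = FALSE)
  sqrt(sum(cvs^2))
}

#' Convert nest density to builder density
#'
#' Inverts the steady-state relation: `D_builders = D_nests / (r * p)`.
#' By reporting convention the builder estimate inherits the nest-density CV
#' and relative CI unchanged (`r` and `p` treated as constants); full
#' delta-method propagation over all three CVs is available with
#' `propagate = TRUE`.
#'
#' @param d_nests Nest density, numeric or `density_estimate`.
#' @param r Decay rate (days), numeric or [decay_rate()].
#' @param p Production rate, numeric or [production_rate()].
#' @param propagate If `TRUE`, combine `cv(d_nests)`, `cv(r)`, `cv(p)` via
#'   [delta_cv()]; default `FALSE` copies `cv(d_nests)`.
#' @return A `density_estimate` in builders/km^2.
#' @examples
#' builders_from_nests(75.56, 293.9, 1.143)$value  # ~0.22
#' @export
builders_from_nests <- function(d_nests, r, p = production_rate(),
                                propagate = FALSE) {
  rr <- .value_cv(r); pp <- .value_cv(p)
  .assert_scalar_pos(rr$v, "r")
  .assert_scalar_pos(pp$v, "p")
  scale <- 1 / (rr$v * pp$v)
  if (inherits(d_nests, "density_estimate")) {
    cv <- if (propagate && is.finite(d_nests$cv))
      delta_cv(c(d_nests$cv, rr$cv[is.finite(rr$cv)], pp$cv[is.finite(pp$cv)]))
    else d_nests$cv
    density_estimate(d_nests$value * scale, cv = cv,
                     ci_low = d_nests$ci_low * scale,
                     ci_high = d_nests$ci_high * scale,
                     n = d_nests$n, effort_km = d_nests$effort_km,
                     stratum = d_nests$stratum, estimator = "scnc_builders",
                     unit = "builders/km^2")
  } else {
    density_estimate(as.numeric(d_nests) * scale, estimator = "scnc_builders",
                     unit = "builders/km^2")
  }
}

#' Scale a density to a population size
#'
#' `N = D * A`, with CI endpoints scaled identically.  The unrounded value is
#' retained; printing rounds to whole animals.
#'
#' @param density A `density_estimate` (builders/km^2) or a number.
#' @param area_km2 Effective area (km^2), `> 0`.
#' @return A `population_size` list: `N`, `N_rounded`, `ci_low`, `ci_high`,
#'   `area_km2`.
#' @examples
#' population_size(density_estimate(1), 100)$N  # 100
#' @export
population_size <- function(density, area_km2) {
  .assert_scalar_pos(area_km2, "area_km2")
  d <- .value_cv(density)
  ci <- if (inherits(density, "density_estimate"))
    c(density$ci_low, density$ci_high) * area_km2 else c(NA_real_, NA_real_)
  structure(list(N = d$v * area_km2, N_rounded = round(d$v * area_km2),
                 ci_low = ci[1L], ci_high = ci[2L], cv = d$cv,
                 area_km2 = area_km2),
            class = "population_size")
}

#' @export
print.population_size <- function(x, ...) {
  ci <- if (is.finite(x$ci_low)) sprintf(" (95%% CI %.1f-%.1f)", x$ci_low, x$ci_high) else ""
  cat(sprintf("Population size: %d animals%s over %.1f km^2\n",
              x$N_rounded, ci, x$area_km2))
  invisible(x)
}
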