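# End-to-end survey pipelines: SCNC nest/builder densities, MNC builder
# density + decay-rate back-calculation, spatial randomization, simulation.
# Each accepts in-memory data frames or file paths and every stochastic step
# takes an explicit seed.

.as_obs <- function(x) if (is.character(x)) read_observations(x) else {
  if (!is.data.frame(x) || nrow(x) == 0L) .stop_schema("no observations")
  miss <- setdiff(.OBS_REQUIRED, names(x))
  if (length(miss))
    .stop_schema(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  x
}

.as_layout <- function(x) if (is.character(x)) read_transects(x) else x

# gather observation rows for (possibly duplicated) resampled transect ids
.obs_for <- function(obs, ids) {
  out <- lapply(seq_along(ids), function(i) obs[obs$transect_id == ids[i], , drop = FALSE])
  do.call(rbind, out)
}

#' Standing-crop nest count pipeline
#'
#' First-visit observations of one survey year are truncated, a detection
#' function is selected per habitat (or pooled), nest densities are computed
#' per habitat with effort from the transect layout, combined into a
#' habitat-area-weighted global density, and a transect-level bootstrap
#' supplies the CV and 95% CI of the global estimate.  If a decay and
#' production rate are given the nest densities are also converted to
#' builder densities.
#'
#' @param observations Observation data.frame or CSV path.
#' @param transects Layout data.frame or CSV path.
#' @param year Survey year to analyse (default: earliest present).
#' @param w Fixed truncation distance (m); or use `discard_fraction`.
#' @param discard_fraction Fraction of largest distances to discard.
#' @param stratify `"habitat"` (default) or `"pooled"` detection fits.
#' @param keys,max_adjustments Detection model search space
#'   (see [fit_best_detection()]).
#' @param areas_km2 Named habitat areas for weighting; default: per-habitat
#'   effort shares from the layout (self-weighting systematic design).
#' @param B Bootstrap resamples (default 999); `0` skips the bootstrap.
#' @param seed RNG seed for the bootstrap.
#' @param refit_detection Refit the selected detection model in each
#'   bootstrap resample (`TRUE`) or hold `f0` fixed (default `FALSE`,
#'   cheaper and slightly anti-conservative).
#' @param decay,production Optional [decay_rate()] / [production_rate()] for
#'   conversion to builders/km^2.
#' @param out_dir If given, writes `scnc_report.csv` (tidy estimates),
#'   `scnc_aic.csv` and `scnc_summary.json` there.
#' @return List: `fits` (per-stratum detection fits), `by_habitat`,
#'   `global`, `builders` (if converted), `encounter_rate`, `n_truncated`,
#'   `report` (tidy data.frame).
#' @export
run_scnc <- function(observations, transects, year = NULL, w = NULL,
                     discard_fraction = NULL,
                     stratify = c("habitat", "pooled"),
                     keys = c("uniform", "half-normal"), max_adjustments = 3L,
                     areas_km2 = NULL, B = 999L, seed = 1L,
                     refit_detection = FALSE,
                     decay = NULL, production = production_rate(),
                     out_dir = NULL) {
  stratify <- match.arg(stratify)
  if (!inherits(production, "production_rate"))
    production <- production_rate(production, 0)
  obs <- .as_obs(observations)
  layout <- .as_layout(transects)
  if (is.null(year)) year <- min(obs$year)
  first_visit <- min(obs$visit[obs$year == year])
  sel <- obs[obs$year == year & obs$visit == first_visit, , drop = FALSE]
  if (nrow(sel) == 0L) .stop_schema(sprintf("no observations for year %s", year))

  if (is.null(w) && is.null(discard_fraction)) discard_fraction <- 0.05
  trunc_all <- truncate_distances(sel$distance_m, w = w,
                                  discard_fraction = discard_fraction,
                                  habitat = sel$habitat,
                                  transect_id = sel$transect_id)
  w_used <- trunc_all$w

  habs <- intersect(attr(layout, "habitats") %||%
                      setdiff(names(layout), c("transect_id", "length_km")),
                    unique(trunc_all$habitat))
  effort <- .effort_by_habitat(layout)
  total_effort <- sum(layout$length_km)

  fit_for <- function(d, h, t_id) {
    s <- truncate_distances(d, w = w_used, habitat = h, transect_id = t_id)
    fit_best_detection(s, keys = keys, max_adjustments = max_adjustments)
  }
  fits <- if (stratify == "habitat") {
    stats::setNames(lapply(habs, function(hb) {
      i <- trunc_all$habitat == hb
      fit_for(trunc_all$distances[i], trunc_all$habitat[i], trunc_all$transect_id[i])
    }), habs)
  } else {
    list(pooled = fit_for(trunc_all$distances, trunc_all$habitat,
                          trunc_all$transect_id))
  }
  f0_of <- function(hb) if (stratify == "habitat") fits[[hb]]$f0 else fits$pooled$f0

  by_habitat <- stats::setNames(lapply(habs, function(hb) {
    scnc_nest_density(sum(trunc_all$habitat == hb), f0_of(hb), effort[[hb]],
                      stratum = hb)
  }), habs)
  if (is.null(areas_km2))
    areas_km2 <- effort[habs] / sum(effort[habs])  # effort-share weights
  global <- habitat_weighted_mean(by_habitat, areas_km2)

  er <- {
    cnt <- table(factor(trunc_all$transect_id, levels = layout$transect_id))
    encounter_rate(length(trunc_all$distances), total_effort,
                   transect_counts = as.numeric(cnt),
                   transect_lengths_km = layout$length_km,
                   B = max(B, 1L), seed = child_seed(seed, 99L))
  }

  if (B > 0L) {
    obs_t <- data.frame(distance_m = trunc_all$distances,
                        habitat = trunc_all$habitat,
                        transect_id = trunc_all$transect_id)
    stat <- function(lay_r) {
      o <- .obs_for(obs_t, lay_r$transect_id)
      eff_r <- vapply(habs, function(hb) sum(lay_r[[hb]]), numeric(1))
      vals <- vapply(habs, function(hb) {
        i <- o$habitat == hb
        if (eff_r[[hb]] <= 0) return(NA_real_)
        f0 <- if (refit_detection && sum(i) >= 5) {
          sp <- if (stratify == "habitat") fits[[hb]]$spec else fits$pooled$spec
          tryCatch(fit_detection(truncate_distances(o$distance_m[i], w = w_used),
                                 sp)$f0,
                   error = function(e) f0_of(hb))
        } else f0_of(hb)
        .per_km2(sum(i), f0, eff_r[[hb]])
      }, numeric(1))
      ok <- is.finite(vals)
      sum(areas_km2[habs][ok] * vals[ok]) / sum(areas_km2[habs][ok])
    }
    bs <- bootstrap_ci(layout, stat, B = B, seed = seed)
    global$cv <- bs$cv; global$ci_low <- bs$ci_low; global$ci_high <- bs$ci_high
  }

  builders <- NULL
  if (!is.null(decay)) {
    builders <- c(lapply(by_habitat, builders_from_nests, r = decay, p = production),
                  list(global = builders_from_nests(global, decay, production)))
  }

  report <- write_density_report(c(by_habitat, list(global = global),
                                   if (!is.null(builders)) builders))
  res <- list(fits = fits, by_habitat = by_habitat, global = global,
              builders = builders, encounter_rate = er,
              w = w_used, n_truncated = trunc_all$n_discarded,
              year = year, report = report, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "scnc_report.csv"), row.names = FALSE)
    aic <- do.call(rbind, lapply(names(fits), function(nm)
      cbind(stratum = nm, fits[[nm]]$aic_table)))
    utils::write.csv(aic, file.path(out_dir, "scnc_aic.csv"), row.names = FALSE)
    jsonlite::write_json(list(year = year, w = w_used, seed = seed,
                              global = global$value, cv = global$cv,
                              ci = c(global$ci_low, global$ci_high)),
                         file.path(out_dir, "scnc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Marked nest count pipeline with decay-rate back-calculation
#'
#' New nests recorded from the second visit onwards (`is_new = 1`) are
#' truncated and fitted with a detection function; the strip half-width `s`
#' is read off the detection shoulder ([strip_half_width()]); builder
#' density follows the strip estimator `n / (2 s L t p)`; and, when a
#' standing-crop nest density is supplied, the nest decay rate is solved
#' from the steady-state relation with a delta-method CV.
#'
#' @inheritParams run_scnc
#' @param tau Shoulder retention threshold for `s` (default 0.9).
#' @param t_days Days between first and last survey of the year; default
#'   `(max(visit) - 1) * visit_interval_days`.
#' @param visit_interval_days Used only when `t_days` is derived.
#' @param nest_density Optional SCNC nest density (`density_estimate` or
#'   numeric, nests/km^2) for the same year, to back-calculate decay.
#' @param printed_values Optional `list(d_nests =, d_builders =)`: skip the
#'   survey computation and solve the decay rate directly from previously
#'   published density estimates.
#' @return List: `fit`, `s_by_habitat`, `by_habitat`, `global`, `decay`
#'   (a [decay_rate()] or `NULL`), `t_days`, `report`.
#' @export
run_mnc_decay <- function(observations = NULL, transects = NULL, year = NULL,
                          w = NULL, discard_fraction = NULL, tau = 0.9,
                          stratify = c("habitat", "pooled"),
                          keys = c("uniform", "half-normal"),
                          max_adjustments = 3L,
                          areas_km2 = NULL, B = 999L, seed = 1L,
                          t_days = NULL, visit_interval_days = 14,
                          production = production_rate(),
                          nest_density = NULL, printed_values = NULL,
                          out_dir = NULL) {
  stratify <- match.arg(stratify)
  if (!inherits(production, "production_rate"))
    production <- production_rate(production, 0)
  if (!is.null(printed_values)) {
    dec <- solve_decay_rate(printed_values$d_nests, printed_values$d_builders,
                            production)
    return(list(decay = dec, global = NULL, report = NULL))
  }
  obs <- .as_obs(observations)
  layout <- .as_layout(transects)
  if (!"is_new" %in% names(obs))
    .stop_schema("MNC requires the is_new column")
  if (is.null(year)) year <- min(obs$year)
  ysel <- obs$year == year
  sel <- obs[ysel & obs$is_new == 1L, , drop = FALSE]
  if (nrow(sel) == 0L) .stop_schema(sprintf("no new-nest records for year %s", year))
  if (is.null(t_days))
    t_days <- (max(obs$visit[ysel]) - 1L) * visit_interval_days

  if (is.null(w) && is.null(discard_fraction)) discard_fraction <- 0.05
  trunc_all <- truncate_distances(sel$distance_m, w = w,
                                  discard_fraction = discard_fraction,
                                  habitat = sel$habitat,
                                  transect_id = sel$transect_id)
  w_used <- trunc_all$w

  habs <- intersect(attr(layout, "habitats") %||%
                      setdiff(names(layout), c("transect_id", "length_km")),
                    unique(trunc_all$habitat))
  effort <- .effort_by_habitat(layout)

  fits <- if (stratify == "habitat") {
    stats::setNames(lapply(habs, function(hb) {
      i <- trunc_all$habitat == hb
      fit_best_detection(truncate_distances(trunc_all$distances[i], w = w_used),
                         keys = keys, max_adjustments = max_adjustments)
    }), habs)
  } else {
    list(pooled = fit_best_detection(
      truncate_distances(trunc_all$distances, w = w_used),
      keys = keys, max_adjustments = max_adjustments))
  }
  s_of <- function(hb) strip_half_width(
    if (stratify == "habitat") fits[[hb]] else fits$pooled, tau)
  s_by_habitat <- stats::setNames(vapply(habs, s_of, numeric(1)), habs)

  by_habitat <- stats::setNames(lapply(habs, function(hb) {
    i <- trunc_all$habitat == hb & trunc_all$distances <= s_by_habitat[[hb]]
    mnc_builder_density(sum(i), effort[[hb]], s_by_habitat[[hb]], t_days,
                        production, stratum = hb)
  }), habs)
  if (is.null(areas_km2))
    areas_km2 <- effort[habs] / sum(effort[habs])
  global <- habitat_weighted_mean(by_habitat, areas_km2)

  if (B > 0L) {
    obs_t <- data.frame(distance_m = trunc_all$distances,
                        habitat = trunc_all$habitat,
                        transect_id = trunc_all$transect_id)
    stat <- function(lay_r) {
      o <- .obs_for(obs_t, lay_r$transect_id)
      vals <- vapply(habs, function(hb) {
        eff <- sum(lay_r[[hb]])
        if (eff <= 0) return(NA_real_)
        i <- o$habitat == hb & o$distance_m <= s_by_habitat[[hb]]
        sum(i) / (2 * (s_by_habitat[[hb]] / 1000) * eff * t_days * production$p)
      }, numeric(1))
      ok <- is.finite(vals)
      sum(areas_km2[habs][ok] * vals[ok]) / sum(areas_km2[habs][ok])
    }
    bs <- bootstrap_ci(layout, stat, B = B, seed = seed)
    global$cv <- bs$cv; global$ci_low <- bs$ci_low; global$ci_high <- bs$ci_high
  }

  dec <- if (!is.null(nest_density))
    solve_decay_rate(nest_density, global, production) else NULL

  report <- write_density_report(c(by_habitat, list(global = global)))
  res <- list(fits = fits, s_by_habitat = s_by_habitat, by_habitat = by_habitat,
              global = global, decay = dec, t_days = t_days, w = w_used,
              year = year, report = report, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "mnc_report.csv"), row.names = FALSE)
    jsonlite::write_json(list(year = year, w = w_used, t_days = t_days,
                              s_m = as.list(s_by_habitat), seed = seed,
                              global = global$value,
                              decay_days = if (!is.null(dec)) dec$r,
                              decay_cv = if (!is.null(dec)) dec$cv),
                         file.path(out_dir, "mnc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Nest-placement randomization pipeline
#'
#' Runs the Monte Carlo randomization test of nest locations against each
#' landscape layer inside the transect buffer.
#'
#' @param nests Nest coordinates: matrix (n x 2), a data.frame with
#'   `x_utm`/`y_utm`, or an observation CSV path.
#' @param layers Named list of [landscape_layer()] objects, or paths to
#'   GeoJSON files.
#' @param transects Transect polylines: list of matrices, or a GeoJSON path.
#' @param half_width Buffer half-width (m, default 84).
#' @param R Randomizations per layer (default 1000).
#' @param seed RNG seed.
#' @param caps Buffer end caps (see [transect_buffer()]).
#' @param out_dir If given, writes `randomization_report.csv`.
#' @return List: `results` (per-layer `randomization_result`), `region`,
#'   `report` (data.frame: layer, n_points, observed_mean_km, z, p_one_sided,
#'   p_two_sided, R, seed).
#' @export
run_randomization <- function(nests, layers, transects, half_width = 84,
                              R = 1000L, seed = 1L, caps = "flat",
                              out_dir = NULL) {
  if (is.character(nests)) {
    o <- read_observations(nests)
    if (!all(c("x_utm", "y_utm") %in% names(o)))
      .stop_schema("observations lack x_utm/y_utm coordinates", nests)
    nests <- cbind(o$x_utm, o$y_utm)
  } else if (is.data.frame(nests)) {
    nests <- cbind(nests$x_utm, nests$y_utm)
  }
  if (is.character(transects)) transects <- read_transect_lines(transects)
  layers <- lapply(layers, function(l)
    if (is.character(l)) read_landscape_layer(l) else l)
  region <- transect_buffer(transects, half_width, caps = caps)

  results <- stats::setNames(lapply(seq_along(layers), function(i) {
    randomization_test(nests, layers[[i]], region, R = R,
                       seed = child_seed(seed, i))
  }), names(layers))

  report <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(layer = nm, n_points = r$n_points,
               observed_mean_km = r$observed_mean / 1000,
               z = r$z, p_one_sided = r$p_one_sided,
               p_two_sided = r$p_two_sided, R = r$R, seed = r$seed)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "randomization_report.csv"),
                     row.names = FALSE)
  }
  list(results = results, region = region, report = report)
}

#' Simulation pipeline
#'
#' Generates a complete synthetic survey and (optionally) writes the CSV,
#' GeoJSON and ground-truth files.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return The `simulated_survey` (invisibly when writing).
#' @export
run_simulate <- function(config, out_dir = NULL) {
  survey <- simulate_survey(config)
  if (!is.null(out_dir)) {
    write_survey(survey, out_dir)
    return(invisible(survey))
  }
  survey
}

#' Recover generating parameters from a simulated survey
#'
#' The full inference chain on one synthetic survey, pooled across habitats:
#' SCNC nest density from the first-visit standing crop (half-normal
#' detection fit, the simulator's generating family), MNC builder density
#' from the new-nest stream with the strip width read off the fitted
#' shoulder, decay rate from the steady-state relation, and the SCNC builder
#' density implied by the recovered decay rate.
#'
#' @param survey A [simulate_survey()] result.
#' @param w_scnc,w_mnc Truncation distances (m) for the two streams.
#' @param tau Shoulder threshold for the strip half-width.
#' @param year Survey year to use (default: first).
#' @return List: `d_nests`, `d_builders_mnc`, `r_days`, `d_builders_scnc`,
#'   `s_m`, `f0`.
#' @export
recover_chain <- function(survey, w_scnc = 42, w_mnc = 44, tau = 0.9,
                          year = NULL) {
  stopifnot(inherits(survey, "simulated_survey"))
  obs <- survey$observations
  cfg <- survey$truth
  if (is.null(year)) year <- cfg$start_year
  L <- sum(survey$layout$length_km)

  sc <- obs[obs$year == year & obs$visit == 1L, , drop = FALSE]
  if (nrow(sc) == 0L) stop("no first-visit observations", call. = FALSE)
  s1 <- truncate_distances(sc$distance_m, w = min(w_scnc, cfg$w_band_m))
  fit1 <- fit_detection(s1, detection_spec("half-normal", 0))
  d_nests <- scnc_nest_density(length(s1$distances), fit1$f0, L)

  mn <- obs[obs$year == year & obs$is_new == 1L, , drop = FALSE]
  if (nrow(mn) == 0L) stop("no new-nest observations", call. = FALSE)
  s2 <- truncate_distances(mn$distance_m, w = min(w_mnc, cfg$w_band_m))
  fit2 <- fit_detection(s2, detection_spec("half-normal", 0))
  s_m <- strip_half_width(fit2, tau)
  yi <- year - cfg$start_year + 1L
  t_days <- (cfg$n_visits[yi] - 1L) * cfg$visit_interval_days
  n_new <- sum(s2$distances <= s_m)
  d_mnc <- mnc_builder_density(n_new, L, s_m, t_days, cfg$production)

  r <- solve_decay_rate(d_nests, d_mnc, production_rate(cfg$production, 0))
  d_scnc <- builders_from_nests(d_nests, r, production_rate(cfg$production, 0))

  list(d_nests = d_nests$value, d_builders_mnc = d_mnc$value,
       r_days = r$r, d_builders_scnc = d_scnc$value,
       s_m = s_m, f0 = fit1$f0)
}
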