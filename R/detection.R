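#' Truncate perpendicular distance data
#'
#' Builds a `distance_sample` from raw perpendicular detection distances,
#' discarding observations beyond a truncation distance `w`.  Truncation may
#' be given either as a fixed distance or as the fraction of the largest
#' distances to discard (5% is the usual omnibus choice in line-transect
#' work).
#'
#' @param distances Numeric vector of perpendicular distances (m), all >= 0.
#' @param w Fixed truncation distance in m (`Inf` keeps everything).  Exactly
#'   one of `w` and `discard_fraction` must be supplied.
#' @param discard_fraction Fraction in `[0, 0.5)` of the largest distances to
#'   discard; `w` becomes the largest retained distance.
#' @param habitat,transect_id,visit,year Optional per-record labels carried
#'   through truncation (each recycled or same length as `distances`).
#' @return A `distance_sample`: list with `distances`, the retained labels,
#'   `w`, and `n_discarded` (records removed by truncation).
#' @examples
#' s <- truncate_distances(c(1, 5, 12, 60), w = 42)
#' s$n_discarded  # 1
#' @export
truncate_distances <- function(distances, w = NULL, discard_fraction = NULL,
                               habitat = NULL, transect_id = NULL,
                               visit = NULL, year = NULL) {
  if (length(distances) == 0L) stop("no observations", call. = FALSE)
  if (anyNA(distances) || !is.numeric(distances))
    stop("`distances` must be numeric without NA", call. = FALSE)
  if (any(distances < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (is.null(w) == is.null(discard_fraction))
    stop("supply exactly one of `w` and `discard_fraction`", call. = FALSE)

  n <- length(distances)
  lab <- function(x) if (is.null(x)) NULL else rep_len(x, n)
  habitat <- lab(habitat); transect_id <- lab(transect_id)
  visit <- lab(visit); year <- lab(year)

  if (!is.null(discard_fraction)) {
    if (discard_fraction < 0 || discard_fraction >= 0.5)
      stop("`discard_fraction` must be in [0, 0.5)", call. = FALSE)
    k <- floor(discard_fraction * n)
    keep <- if (k == 0L) rep(TRUE, n) else {
      ord <- order(distances, decreasing = TRUE)
      kp <- rep(TRUE, n); kp[ord[seq_len(k)]] <- FALSE; kp
    }
    w <- max(distances[keep])
  } else {
    if (!is.numeric(w) || length(w) != 1L || is.na(w) || w <= 0)
      stop("`w` must be a single positive number", call. = FALSE)
    keep <- distances <= w
  }
  if (!any(keep)) stop("no observations", call. = FALSE)

  structure(list(
    distances = distances[keep],
    habitat = habitat[keep], transect_id = transect_id[keep],
    visit = visit[keep], year = year[keep],
    w = w, n_discarded = n - sum(keep)
  ), class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("Distance sample: %d observations, w = %g m (%d truncated)\n",
              length(x$distances), x$w, x$n_discarded))
  if (!is.null(x$habitat)) {
    tb <- table(x$habitat)
    cat("  by habitat:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Specify a conventional distance-sampling detection model
#'
#' A key function (uniform or half-normal) with an order-`adjustments`
#' cosine series: `g(y) = key(y) * (1 + sum_j a_j cos(j * pi * y / w))`.
#'
#' @param key `"uniform"` or `"half-normal"`.
#' @param adjustments Cosine series order `m >= 0`.
#' @param max_adjustments Upper bound on `m` (default 3).
#' @return A `detection_spec`.
#' @export
detection_spec <- function(key = c("uniform", "half-normal"), adjustments = 0L,
                           max_adjustments = 3L) {
  key <- match.arg(key)
  adjustments <- as.integer(adjustments)
  if (adjustments < 0L || adjustments > max_adjustments)
    stop(sprintf("`adjustments` must be in 0..%d", max_adjustments), call. = FALSE)
  structure(list(key = key, adjustments = adjustments), class = "detection_spec")
}

#' @export
print.detection_spec <- function(x, ...) {
  cat(sprintf("Detection model: %s key + %d cosine adjustment(s)\n",
              x$key, x$adjustments))
  invisible(x)
}

# --- detection-curve evaluation ---------------------------------------------

# unnormalized detection curve g(y); sigma ignored for the uniform key
.eval_g <- function(y, key, w, sigma = NULL, adj = numeric(0)) {
  g <- switch(key,
    "uniform" = rep_len(1, length(y)),
    "half-normal" = exp(-y^2 / (2 * sigma^2)),
    stop("unknown key"))
  if (length(adj)) {
    s <- 1
    for (j in seq_along(adj)) s <- s + adj[j] * cos(j * pi * y / w)
    g <- g * s
  }
  g
}

.unpack_par <- function(theta, key) {
  if (key == "half-normal")
    list(sigma = exp(theta[1L]), adj = theta[-1L])
  else
    list(sigma = NULL, adj = theta)
}

.gl_cache <- new.env(parent = emptyenv())
.gl_quad <- function(w, n = 64L) {
  key <- sprintf("%d_%.12g", n, w)
  q <- .gl_cache[[key]]
  if (is.null(q)) {
    q <- pracma::gaussLegendre(n, 0, w)
    .gl_cache[[key]] <- q
  }
  q
}

.fit_npar <- function(key, m) as.integer(key == "half-normal") + as.integer(m)

#' Control parameters for detection-function fitting
#'
#' @param grid_n Size of the constraint-evaluation grid on `[0, w]`.
#' @param n_restarts Number of deterministic jittered optimizer starts.
#' @param mono_tol Maximum allowed increase of `g` between neighbouring grid
#'   points before a parameter vector is rejected (shape constraint: the
#'   fitted curve must be nonnegative and non-increasing, preserving a
#'   "shoulder" at zero distance).
#' @param reltol Convergence tolerance on the log-likelihood.
#' @return A list of control values.
#' @export
detection_control <- function(grid_n = 512L, n_restarts = 5L,
                              mono_tol = 1e-6, reltol = 1e-8) {
  list(grid_n = as.integer(grid_n), n_restarts = as.integer(n_restarts),
       mono_tol = mono_tol, reltol = reltol)
}

# deterministic start matrix (rows = restarts); no RNG so fits are
# reproducible without touching the user's seed
.fit_starts <- function(key, m, y, w, k) {
  base <- c(
    if (key == "half-normal") log(max(stats::sd(y), w / 20, 1e-3)),
    rep(0, m)
  )
  if (length(base) == 0L) return(matrix(numeric(0), nrow = 1L, ncol = 0L))
  sig_off <- c(0, -0.7, 0.7, -1.4, 1.4)
  a1_off <- c(0, 0.3, 0.6, 0.9, 1.2)
  out <- matrix(rep(base, each = k), nrow = k)
  i <- seq_len(k)
  if (key == "half-normal") out[, 1L] <- out[, 1L] + sig_off[(i - 1L) %% 5L + 1L]
  if (m > 0L) {
    ja <- .fit_npar(key, 0L) + 1L  # first adjustment column
    out[, ja] <- a1_off[(i - 1L) %% 5L + 1L] * if (key == "half-normal") 0.5 else 1
  }
  out
}

#' Fit a detection function by maximum likelihood
#'
#' Maximizes the truncated line-transect likelihood
#' `prod_i g(y_i) / integral_0^w g` for a key + cosine-series model, under the
#' shape constraint that `g` is nonnegative and non-increasing on `[0, w]`
#' (evaluated on a fine grid).  Optimization is bounded quasi-Newton
#' (`L-BFGS-B`) from several deterministic jittered starts.
#'
#' @param sample A `distance_sample` (see [truncate_distances()]).
#' @param spec A `detection_spec`.
#' @param control See [detection_control()].
#' @return A `detection_fit` with elements `key`, `adjustments` (coefficients
#'   `a_1..a_m`), `sigma` (half-normal scale, m), `w`, `f0` (pdf of detection
#'   distances at 0, 1/m), `loglik`, `aic`, `n`, `npar`.
#' @examples
#' s <- truncate_distances(c(2, 6, 9, 14, 20, 28), w = 42)
#' fit <- fit_detection(s, detection_spec("uniform", 0))
#' fit$f0 * fit$w  # 1: flat detection
#' @export
fit_detection <- function(sample, spec, control = detection_control()) {
  stopifnot(inherits(sample, "distance_sample"), inherits(spec, "detection_spec"))
  y <- sample$distances
  w <- sample$w
  n <- length(y)
  if (n == 0L) stop("no observations", call. = FALSE)
  if (!is.finite(w)) stop("truncation distance must be finite for fitting", call. = FALSE)
  m <- spec$adjustments
  key <- spec$key
  # series terms need sample support; plain keys are fittable from few points
  if (m > 0L && n < 5L * (1L + m))
    stop(sprintf("overparameterized: %d observations cannot support %d adjustment term(s)",
                 n, m), call. = FALSE)

  grid <- seq(0, w, length.out = control$grid_n)
  quad <- .gl_quad(w)
  npar <- .fit_npar(key, m)

  feasible <- function(gg) all(gg > -1e-12) && all(diff(gg) <= control$mono_tol)

  make_fit <- function(theta) {
    pl <- .unpack_par(theta, key)
    mu <- sum(quad$w * .eval_g(quad$x, key, w, pl$sigma, pl$adj))
    gy <- .eval_g(y, key, w, pl$sigma, pl$adj)
    ll <- sum(log(gy)) - n * log(mu)
    g0 <- .eval_g(0, key, w, pl$sigma, pl$adj)
    structure(list(
      spec = spec, key = key,
      adjustments = if (m > 0L) stats::setNames(pl$adj, paste0("a", seq_len(m))) else numeric(0),
      sigma = pl$sigma, w = w,
      f0 = g0 / mu, loglik = ll, aic = -2 * ll + 2 * npar,
      n = n, npar = npar, mu = mu, n_discarded = sample$n_discarded
    ), class = "detection_fit")
  }

  if (npar == 0L) return(make_fit(numeric(0)))  # uniform, no adjustments

  nll <- function(theta) {
    pl <- .unpack_par(theta, key)
    gg <- .eval_g(grid, key, w, pl$sigma, pl$adj)
    if (any(!is.finite(gg))) return(1e10)
    mu <- sum(quad$w * .eval_g(quad$x, key, w, pl$sigma, pl$adj))
    if (!is.finite(mu) || mu <= 0) return(1e10)
    gy <- .eval_g(y, key, w, pl$sigma, pl$adj)
    ll <- sum(log(pmax(gy, 1e-300))) - n * log(mu)
    # soft shape penalty: steers the search without a numerical cliff; the
    # hard constraint is enforced afterwards by projection onto the boundary
    viol <- sum(pmin(gg, 0)^2) + sum(pmax(diff(gg) - control$mono_tol / 2, 0)^2)
    -ll + 100 * n * viol
  }

  lower <- c(if (key == "half-normal") log(w * 1e-3), rep(-5, m))
  upper <- c(if (key == "half-normal") log(w * 10), rep(5, m))
  starts <- .fit_starts(key, m, y, w, control$n_restarts)

  grid_feasible <- function(theta) {
    pl <- .unpack_par(theta, key)
    gg <- .eval_g(grid, key, w, pl$sigma, pl$adj)
    all(is.finite(gg)) && feasible(gg)
  }
  # true (unpenalized) negative loglik of a feasible parameter vector
  nll_true <- function(theta) {
    pl <- .unpack_par(theta, key)
    mu <- sum(quad$w * .eval_g(quad$x, key, w, pl$sigma, pl$adj))
    -(sum(log(.eval_g(y, key, w, pl$sigma, pl$adj))) - n * log(mu))
  }
  # the penalized optimum can sit a hair outside the shape constraints; pull
  # the adjustment vector back along its ray to the feasible boundary
  project_feasible <- function(theta) {
    if (grid_feasible(theta)) return(theta)
    if (m == 0L) return(NULL)
    ia <- (npar - m + 1L):npar
    lo <- 0; hi <- 1
    th0 <- theta; th0[ia] <- 0
    if (!grid_feasible(th0)) return(NULL)
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      th <- theta; th[ia] <- theta[ia] * mid
      if (grid_feasible(th)) lo <- mid else hi <- mid
    }
    th <- theta; th[ia] <- theta[ia] * lo
    th
  }

  # unpenalized objective (guarded against g <= 0); its optimum may be
  # infeasible, but its projection lands exactly on the constraint boundary
  nll_pure <- function(theta) {
    pl <- .unpack_par(theta, key)
    mu <- sum(quad$w * .eval_g(quad$x, key, w, pl$sigma, pl$adj))
    if (!is.finite(mu) || mu <= 0) return(1e10)
    gy <- .eval_g(y, key, w, pl$sigma, pl$adj)
    if (any(!is.finite(gy))) return(1e10)
    -(sum(log(pmax(gy, 1e-300))) - n * log(mu))
  }

  best <- NULL
  best_val <- Inf
  diagnostics <- list()
  for (i in seq_len(nrow(starts))) {
    for (objective in list(nll, nll_pure)) {
      opt <- tryCatch(
        stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(factr = control$reltol / .Machine$double.eps,
                                    maxit = 500L)),
        error = function(e) NULL)
      if (is.null(opt)) next
      par_f <- project_feasible(opt$par)
      diagnostics[[length(diagnostics) + 1L]] <-
        list(par = opt$par, value = opt$value, convergence = opt$convergence,
             feasible = !is.null(par_f))
      if (is.null(par_f)) next
      val <- nll_true(par_f)
      if (is.finite(val) && val < best_val) { best <- par_f; best_val <- val }
    }
  }
  if (is.null(best))
    stop(errorCondition(
      sprintf("detection fit did not converge to a feasible optimum (%s + %d cosine)",
              key, m),
      class = c("nestsurvey_fit_error", "error"),
      diagnostics = diagnostics))
  make_fit(best)
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("Detection function: %s key + %d cosine adjustment(s)\n",
              x$key, length(x$adjustments)))
  if (!is.null(x$sigma)) cat(sprintf("  sigma = %.3f m\n", x$sigma))
  if (length(x$adjustments))
    cat("  ", paste(sprintf("%s = %.4f", names(x$adjustments), x$adjustments),
                    collapse = ", "), "\n", sep = "")
  cat(sprintf("  w = %g m, n = %d, f(0) = %.5f /m (ESW %.2f m)\n",
              x$w, x$n, x$f0, 1 / x$f0))
  cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$loglik, x$aic))
  invisible(x)
}

#' Evaluate a fitted detection model
#'
#' @param object A `detection_fit`.
#' @param y Perpendicular distances (m) at which to evaluate.
#' @param type `"g"` (detection curve, `g(0)` scale), `"pdf"` (density of
#'   detected distances, integrates to 1 on `[0, w]`), or `"cdf"`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.detection_fit <- function(object, y, type = c("g", "pdf", "cdf"), ...) {
  type <- match.arg(type)
  g <- function(x) .eval_g(x, object$key, object$w, object$sigma, object$adjustments)
  switch(type,
    g = g(y),
    pdf = g(y) / object$mu,
    cdf = {
      vapply(pmin(pmax(y, 0), object$w), function(u) {
        if (u <= 0) return(0)
        q <- pracma::gaussLegendre(48, 0, u)
        min(1, sum(q$w * g(q$x)) / object$mu)
      }, numeric(1))
    })
}

#' @export
plot.detection_fit <- function(x, sample = NULL, nclass = 10, ...) {
  w <- x$w
  yy <- seq(0, w, length.out = 200)
  gg <- predict(x, yy, type = "g")
  gg <- gg / gg[1]
  if (!is.null(sample)) {
    h <- graphics::hist(sample$distances, breaks = seq(0, w, length.out = nclass + 1),
                        plot = FALSE)
    scl <- mean(h$density) / mean(predict(x, h$mids, type = "pdf"))
    graphics::plot(h$mids, h$density * 0 , type = "n", xlim = c(0, w),
                   ylim = c(0, max(1, h$density / (x$f0 * scl))),
                   xlab = "perpendicular distance (m)", ylab = "detection probability", ...)
    graphics::rect(h$breaks[-length(h$breaks)], 0, h$breaks[-1],
                   h$density / x$f0, col = "grey90")
    graphics::lines(yy, gg, lwd = 2)
  } else {
    graphics::plot(yy, gg, type = "l", lwd = 2, xlab = "perpendicular distance (m)",
                   ylab = "detection probability", ...)
  }
  invisible(x)
}

#' Select a detection model by AIC
#'
#' Fits every candidate specification and returns the fit with the lowest
#' AIC (ties broken in favour of fewer parameters), together with the AIC
#' gap to the runner-up.
#'
#' @param sample A `distance_sample`.
#' @param candidates List of `detection_spec` objects.
#' @param control See [detection_control()].
#' @return The winning `detection_fit`, with extra elements `delta_aic`
#'   (AIC(runner-up) - AIC(best); `NA` if a single candidate) and
#'   `aic_table` (one row per candidate that could be fitted).
#' @export
select_detection_model <- function(sample, candidates,
                                   control = detection_control()) {
  if (length(candidates) == 0L) stop("no candidate models", call. = FALSE)
  fits <- vector("list", length(candidates))
  errs <- character(0)
  for (i in seq_along(candidates)) {
    fits[[i]] <- tryCatch(fit_detection(sample, candidates[[i]], control),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      sp <- candidates[[i]]
      errs <- c(errs, sprintf("%s+%d: %s", sp$key, sp$adjustments,
                              conditionMessage(fits[[i]])))
      fits[[i]] <- NULL
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop(sprintf("all candidate models failed to fit:\n  %s",
                 paste(errs, collapse = "\n  ")), call. = FALSE)
  fits <- fits[ok]
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(fits, `[[`, numeric(1), "npar")
  ord <- order(aic, npar)
  best <- fits[[ord[1L]]]
  best$delta_aic <- if (length(ord) > 1L) aic[ord[2L]] - aic[ord[1L]] else NA_real_
  best$aic_table <- data.frame(
    key = vapply(fits, `[[`, character(1), "key"),
    adjustments = vapply(fits, function(f) length(f$adjustments), integer(1)),
    npar = npar, aic = aic, delta_aic = aic - min(aic)
  )[order(aic, npar), ]
  rownames(best$aic_table) <- NULL
  best
}

#' Forward-stepwise detection model search
#'
#' For each key function, cosine adjustment terms are added one at a time
#' while the AIC keeps decreasing (up to `max_adjustments`); the per-key
#' winners then compete on AIC.  This is the standard adjustment-order
#' search of conventional distance sampling software.
#'
#' @param sample A `distance_sample`.
#' @param keys Key functions to consider.
#' @param max_adjustments Maximum cosine order per key.
#' @param control See [detection_control()].
#' @return As [select_detection_model()].
#' @export
fit_best_detection <- function(sample, keys = c("uniform", "half-normal"),
                               max_adjustments = 3L,
                               control = detection_control()) {
  specs <- list()
  for (key in keys) {
    prev_aic <- Inf
    for (m in 0:max_adjustments) {
      f <- tryCatch(
        fit_detection(sample, detection_spec(key, m, max_adjustments), control),
        error = function(e) NULL)
      if (is.null(f)) break
      specs <- c(specs, list(detection_spec(key, m, max_adjustments)))
      if (f$aic >= prev_aic) break  # AIC stopped improving
      prev_aic <- f$aic
    }
  }
  if (length(specs) == 0L) stop("all candidate models failed to fit", call. = FALSE)
  select_detection_model(sample, specs, control)
}

# --- goodness of fit ---------------------------------------------------------

# Asymptotic CDF of the Cramer-von Mises statistic (the classical Bessel-K
# series representation of the limiting distribution); the Stephens
# small-sample modification maps W2 onto the asymptotic scale.
.cvm_cdf_asym <- function(x) {
  if (x <= 0) return(0)
  s <- 0
  for (j in 0:10) {
    a <- (4 * j + 1)^2 / (16 * x)
    coef <- gamma(j + 0.5) / (gamma(0.5) * factorial(j))
    s <- s + coef * sqrt(4 * j + 1) * exp(-2 * a) *
      besselK(a, 0.25, expon.scaled = TRUE)
  }
  min(1, max(0, s / (pi * sqrt(x))))
}

.cvm_pvalue <- function(W2, n) {
  z <- (W2 - 0.4 / n + 0.6 / n^2) * (1 + 1 / n)
  1 - .cvm_cdf_asym(max(z, 1e-10))
}

#' Goodness of fit of a detection function
#'
#' Chi-square on equal-width distance bins (expected counts from the fitted
#' density, `df = n_bins - 1 - n_free_params`), plus Kolmogorov-Smirnov and
#' Cramer-von Mises tests of the empirical CDF against the fitted CDF.
#' P-values are the usual "naive" ones that ignore parameter estimation, as
#' standard distance-sampling software reports.
#'
#' @param fit A `detection_fit`.
#' @param sample The `distance_sample` the fit was computed from (same `w`).
#' @param n_bins Number of chi-square bins; default `min(10, floor(n / 5))`.
#' @return A `gof_report` list: `chisq_stat`, `chisq_df`, `chisq_p`,
#'   `ks_stat`, `ks_p`, `cvm_stat`, `cvm_p`, `observed`, `expected`.
#' @export
goodness_of_fit <- function(fit, sample, n_bins = NULL) {
  stopifnot(inherits(fit, "detection_fit"), inherits(sample, "distance_sample"))
  if (!isTRUE(all.equal(fit$w, sample$w)))
    stop("fit and sample have different truncation distances", call. = FALSE)
  y <- sample$distances
  n <- length(y)
  if (is.null(n_bins)) n_bins <- max(2L, min(10L, floor(n / 5)))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)

  w <- fit$w
  edges <- seq(0, w, length.out = n_bins + 1L)
  Fe <- predict(fit, edges, type = "cdf")
  expected <- n * diff(Fe)
  if (any(expected < 1))
    stop("expected count below 1 in at least one bin; use fewer bins", call. = FALSE)
  observed <- as.vector(table(cut(y, edges, include.lowest = TRUE)))
  chisq_df <- n_bins - 1L - fit$npar
  if (chisq_df < 1L)
    stop("chi-square df < 1; use more bins or a simpler model", call. = FALSE)
  chisq_stat <- sum((observed - expected)^2 / expected)
  chisq_p <- stats::pchisq(chisq_stat, chisq_df, lower.tail = FALSE)

  cdf_fun <- function(q) predict(fit, q, type = "cdf")
  ks <- suppressWarnings(stats::ks.test(y, cdf_fun))

  u <- sort(cdf_fun(y))
  cvm_stat <- 1 / (12 * n) + sum((u - (2 * seq_len(n) - 1) / (2 * n))^2)
  cvm_p <- .cvm_pvalue(cvm_stat, n)

  structure(list(
    chisq_stat = chisq_stat, chisq_df = chisq_df, chisq_p = chisq_p,
    ks_stat = unname(ks$statistic), ks_p = ks$p.value,
    cvm_stat = cvm_stat, cvm_p = cvm_p,
    n_bins = n_bins, observed = observed, expected = expected
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Goodness of fit (%d bins):\n", x$n_bins))
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.4f\n",
              x$chisq_stat, x$chisq_df, x$chisq_p))
  cat(sprintf("  KS  D = %.4f, p = %.4f\n", x$ks_stat, x$ks_p))
  cat(sprintf("  CvM W2 = %.4f, p = %.4f\n", x$cvm_stat, x$cvm_p))
  invisible(x)
}

#' Strip half-width from the shoulder of a detection function
#'
#' The strip-transect half-width is the largest distance over which the
#' detection curve still retains at least a fraction `tau` of its value at
#' zero, i.e. the extent of the detection "shoulder" within which detection
#' can be treated as certain.
#'
#' @param fit A `detection_fit`.
#' @param tau Retention threshold in `(0, 1]` (default 0.9).
#' @return Strip half-width `s` in m, `0 <= s <= w`.
#' @examples
#' # half-normal: s = sigma * sqrt(2 * log(1 / tau))
#' @export
strip_half_width <- function(fit, tau = 0.9) {
  stopifnot(inherits(fit, "detection_fit"))
  if (tau <= 0 || tau > 1) stop("`tau` must be in (0, 1]", call. = FALSE)
  w <- fit$w
  xx <- seq(0, w, length.out = 4096L)
  g0 <- predict(fit, 0, type = "g")
  ratio <- predict(fit, xx, type = "g") / g0
  ok <- which(ratio >= tau - 1e-12)
  if (length(ok) == 0L) return(0)
  i <- max(ok)
  if (i == length(xx)) return(w)
  # refine the crossing between the last qualifying grid point and the next
  h <- function(x) predict(fit, x, type = "g") / g0 - tau
  if (h(xx[i]) * h(xx[i + 1L]) < 0)
    stats::uniroot(h, c(xx[i], xx[i + 1L]), tol = 1e-10)$root
  else xx[i]
}
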