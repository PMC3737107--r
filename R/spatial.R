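# Planar geometry for the nest-placement randomization test.  All
# coordinates are projected planar metres (e.g. UTM); the package does no
# datum handling or reprojection.

#' Construct a landscape feature layer
#'
#' @param kind One of `"road"`, `"river"`, `"settlement"`.
#' @param geometries List of geometries; each is a numeric matrix with two
#'   columns (x, y in m): a single row is a point, two or more rows a
#'   polyline.  A geometry may also be a list `list(polygon = ring)` where
#'   `ring` is a closed-ring matrix (points inside are at distance 0).
#' @return A `landscape_layer`.
#' @export
landscape_layer <- function(kind = c("road", "river", "settlement"), geometries) {
  kind <- match.arg(kind)
  if (length(geometries) == 0L) stop("layer has no geometries", call. = FALSE)
  geometries <- lapply(geometries, function(g) {
    if (is.list(g) && !is.null(g$polygon)) {
      g$polygon <- .as_coord_matrix(g$polygon)
      return(g)
    }
    .as_coord_matrix(g)
  })
  structure(list(kind = kind, geometries = geometries),
            class = "landscape_layer")
}

.as_coord_matrix <- function(g) {
  g <- as.matrix(g)
  if (ncol(g) != 2L || !is.numeric(g) || any(!is.finite(g)))
    stop("geometry must be a finite numeric 2-column matrix", call. = FALSE)
  unname(g)
}

#' @export
print.landscape_layer <- function(x, ...) {
  cat(sprintf("Landscape layer '%s': %d geometrie(s)\n", x$kind,
              length(x$geometries)))
  invisible(x)
}

# Coordinates in a projected CRS are metres and typically large; values that
# all fit the lon/lat range (and are not tiny toy-scale numbers) are almost
# certainly unprojected degrees.
.check_projected <- function(xy) {
  mx <- max(abs(xy))
  if (mx > 10 && all(abs(xy[, 1L]) <= 180) && all(abs(xy[, 2L]) <= 90))
    stop(paste("coordinates look geographic (lon/lat);",
               "supply projected planar coordinates in metres"), call. = FALSE)
  invisible(xy)
}

# distances from points (n x 2) to one segment (a, b); returns n-vector
.dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
}

# flatten a layer (or list of polylines) into a segment table + point table
.layer_segments <- function(geometries) {
  segs <- matrix(numeric(0), ncol = 4L)
  pts <- matrix(numeric(0), ncol = 2L)
  polys <- list()
  for (g in geometries) {
    if (is.list(g) && !is.null(g$polygon)) {
      ring <- g$polygon
      segs <- rbind(segs, cbind(ring[-nrow(ring), , drop = FALSE],
                                ring[-1L, , drop = FALSE]))
      polys <- c(polys, list(ring))
    } else if (nrow(g) == 1L) {
      pts <- rbind(pts, g)
    } else {
      segs <- rbind(segs, cbind(g[-nrow(g), , drop = FALSE],
                                g[-1L, , drop = FALSE]))
    }
  }
  list(segs = segs, pts = pts, polys = polys)
}

# ray-casting point-in-polygon (ring need not be explicitly closed)
.point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1L]; ys <- ring[, 2L]
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j[i]]; yj <- ys[j[i]]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
  }
  inside
}

#' Shortest straight-line distance from points to a feature layer
#'
#' Euclidean point-to-geometry distance, minimized over every geometry in
#' the layer.  Points inside a polygon geometry are at distance 0.
#'
#' @param points Numeric matrix (n x 2) of planar coordinates (m).
#' @param layer A [landscape_layer()] (or a bare list of geometries).
#' @return Numeric vector of distances (m), one per point.
#' @examples
#' road <- landscape_layer("road", list(rbind(c(0, 0), c(0, 1000))))
#' nearest_feature_distance(rbind(c(3e5, 4e5)), road)  # 5e5 - ish scale
#' @export
nearest_feature_distance <- function(points, layer) {
  points <- .as_coord_matrix(points)
  .check_projected(points)
  geoms <- if (inherits(layer, "landscape_layer")) layer$geometries else layer
  parts <- .layer_segments(geoms)
  px <- points[, 1L]; py <- points[, 2L]
  d <- rep(Inf, nrow(points))
  if (nrow(parts$segs)) {
    for (i in seq_len(nrow(parts$segs))) {
      s <- parts$segs[i, ]
      d <- pmin(d, .dist_point_segment(px, py, s[1L], s[2L], s[3L], s[4L]))
    }
  }
  if (nrow(parts$pts)) {
    for (i in seq_len(nrow(parts$pts))) {
      d <- pmin(d, sqrt((px - parts$pts[i, 1L])^2 + (py - parts$pts[i, 2L])^2))
    }
  }
  for (ring in parts$polys) d[.point_in_ring(px, py, ring)] <- 0
  d
}

#' Buffer region around survey transects
#'
#' The union of fixed-half-width bands around each transect polyline — the
#' surveyed area within which random nest locations are generated.  End caps
#' are flat by default (the band is the set of points whose perpendicular
#' foot falls on the line); round caps extend the band by a half-disc at
#' each vertex.
#'
#' @param transects List of transect polylines (matrices, m) or a single
#'   matrix.
#' @param half_width Buffer half-width in m (default 84, the maximum
#'   perpendicular distance at which a nest is typically recorded).
#' @param caps `"flat"` or `"round"`.
#' @return A `buffer_region` with a containment predicate, bounding box and
#'   a deterministic grid estimate of the union area (km^2).
#' @export
transect_buffer <- function(transects, half_width = 84, caps = c("flat", "round")) {
  caps <- match.arg(caps)
  .assert_scalar_pos(half_width, "half_width")
  if (is.matrix(transects)) transects <- list(transects)
  if (length(transects) == 0L) stop("no transects", call. = FALSE)
  transects <- lapply(transects, .as_coord_matrix)
  segs <- .layer_segments(transects)$segs
  if (nrow(segs) == 0L) stop("transects contain no segments", call. = FALSE)

  contains <- function(px, py) {
    inside <- rep(FALSE, length(px))
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      if (caps == "round") {
        inside <- inside |
          (.dist_point_segment(px, py, s[1L], s[2L], s[3L], s[4L]) <= half_width)
      } else {
        dx <- s[3L] - s[1L]; dy <- s[4L] - s[2L]
        len2 <- dx * dx + dy * dy
        t <- ((px - s[1L]) * dx + (py - s[2L]) * dy) / len2
        perp <- abs((px - s[1L]) * (-dy) + (py - s[2L]) * dx) / sqrt(len2)
        inside <- inside | (t >= 0 & t <= 1 & perp <= half_width)
      }
      if (all(inside)) break
    }
    inside
  }

  allxy <- do.call(rbind, transects)
  bbox <- c(xmin = min(allxy[, 1L]) - half_width,
            xmax = max(allxy[, 1L]) + half_width,
            ymin = min(allxy[, 2L]) - half_width,
            ymax = max(allxy[, 2L]) + half_width)

  # deterministic grid estimate of the union area
  nx <- 512L
  ny <- 512L
  gx <- seq(bbox["xmin"], bbox["xmax"], length.out = nx)
  gy <- seq(bbox["ymin"], bbox["ymax"], length.out = ny)
  gg <- expand.grid(x = gx, y = gy)
  frac <- mean(contains(gg$x, gg$y))
  area_km2 <- frac * (bbox["xmax"] - bbox["xmin"]) *
    (bbox["ymax"] - bbox["ymin"]) / 1e6
  if (area_km2 <= 0) stop("buffer region has zero area", call. = FALSE)

  structure(list(transects = transects, half_width = half_width, caps = caps,
                 contains = contains, bbox = bbox,
                 area_km2 = unname(area_km2)),
            class = "buffer_region")
}

#' @export
print.buffer_region <- function(x, ...) {
  cat(sprintf("Transect buffer: %d transect(s), half-width %g m, %s caps, area ~ %.3f km^2\n",
              length(x$transects), x$half_width, x$caps, x$area_km2))
  invisible(x)
}

#' Uniform random points inside a buffer region
#'
#' Rejection sampling from the bounding box; reproducible given the seed.
#'
#' @param region A [transect_buffer()].
#' @param n Number of points (default 214, the reference count of
#'   independent nest locations).
#' @param seed RNG seed.
#' @return Numeric matrix (n x 2) of planar coordinates (m).
#' @export
random_points_in_buffer <- function(region, n = 214L, seed = 1L) {
  stopifnot(inherits(region, "buffer_region"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  bb <- region$bbox
  with_seed(seed, {
    out <- matrix(NA_real_, n, 2L)
    got <- 0L
    tries <- 0L
    while (got < n) {
      m <- max(2L * (n - got), 256L)
      px <- stats::runif(m, bb["xmin"], bb["xmax"])
      py <- stats::runif(m, bb["ymin"], bb["ymax"])
      keep <- region$contains(px, py)
      k <- min(sum(keep), n - got)
      if (k > 0L) {
        idx <- which(keep)[seq_len(k)]
        out[got + seq_len(k), ] <- cbind(px[idx], py[idx])
        got <- got + k
      }
      tries <- tries + 1L
      if (tries > 10000L) stop("rejection sampling failed: region too thin",
                               call. = FALSE)
    }
    out
  })
}

#' Monte Carlo randomization test of nest placement
#'
#' Compares the observed mean nearest straight-line distance from nest
#' locations to a feature layer against the distribution of the same
#' statistic for uniformly random locations within the surveyed transect
#' buffer.  The one-sided p is the fraction of null means falling below the
#' observed mean (large p: nests farther from the feature than chance); a
#' two-sided companion and a normal-score `z` are also reported.
#'
#' @param nests Matrix (n x 2) of nest coordinates (m).
#' @param layer A [landscape_layer()].
#' @param region A [transect_buffer()].
#' @param R Number of randomizations (default 1000).
#' @param seed RNG seed.
#' @param collapse_duplicates Collapse identical coordinates to one
#'   independent location before testing (several nests in one tree share a
#'   GPS reading); default `TRUE`.
#' @return A `randomization_result`: `observed_mean` (m), `null_means`,
#'   `z`, `p_one_sided`, `p_two_sided`, `n_points`, `R`, `seed`.
#' @export
randomization_test <- function(nests, layer, region, R = 1000L, seed = 1L,
                               collapse_duplicates = TRUE) {
  stopifnot(inherits(region, "buffer_region"))
  nests <- .as_coord_matrix(nests)
  if (nrow(nests) == 0L) stop("no nest locations", call. = FALSE)
  if (collapse_duplicates) nests <- unique(nests)
  R <- as.integer(R)
  if (R < 1L) stop("`R` must be >= 1", call. = FALSE)

  observed <- mean(nearest_feature_distance(nests, layer))
  n <- nrow(nests)
  null_means <- vapply(seq_len(R), function(r) {
    pts <- random_points_in_buffer(region, n, seed = child_seed(seed, r))
    mean(nearest_feature_distance(pts, layer))
  }, numeric(1))

  s <- stats::sd(null_means)
  z <- if (R > 1L && s > 0) (observed - mean(null_means)) / s else NA_real_
  p_one <- mean(null_means < observed)
  p_two <- min(1, 2 * min(mean(null_means <= observed),
                          mean(null_means >= observed)))
  structure(list(observed_mean = observed, null_means = null_means, z = z,
                 p_one_sided = p_one, p_two_sided = p_two,
                 n_points = n, R = R, seed = seed, kind = layer$kind),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("Randomization test vs %s (R = %d):\n",
              x$kind %||% "feature", x$R))
  cat(sprintf("  observed mean distance = %.2f km (n = %d)\n",
              x$observed_mean / 1000, x$n_points))
  cat(sprintf("  null mean = %.2f km, Z = %.2f\n",
              mean(x$null_means) / 1000, x$z))
  cat(sprintf("  p (null below observed) = %.4f, two-sided p = %.4f\n",
              x$p_one_sided, x$p_two_sided))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean nearest-feature distance with normal 95% CI
#'
#' @param distances_m Numeric vector of distances in m.
#' @return List `mean_km`, `ci_low_km`, `ci_high_km`, `n`.
#' @examples
#' mean_distance_summary(c(1000, 2000, 3000))$mean_km  # 2
#' @export
mean_distance_summary <- function(distances_m) {
  if (length(distances_m) == 0L) stop("no distances", call. = FALSE)
  m <- mean(distances_m)
  se <- if (length(distances_m) > 1L)
    stats::sd(distances_m) / sqrt(length(distances_m)) else 0
  list(mean_km = m / 1000,
       ci_low_km = (m - 1.96 * se) / 1000,
       ci_high_km = (m + 1.96 * se) / 1000,
       n = length(distances_m))
}

#' Habitat-wise comparison of nearest-feature distances
#'
#' Thin pass-through to the Kruskal-Wallis rank sum test for comparing the
#' distances of nests (or habitats) to a landscape feature across groups.
#'
#' @param distances_m Numeric vector of distances.
#' @param habitat Grouping factor of the same length.
#' @return An `htest` from [stats::kruskal.test()].
#' @export
habitat_feature_test <- function(distances_m, habitat) {
  stats::kruskal.test(distances_m, factor(habitat))
}
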