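test_that("nearest-feature distance handles points, polylines and polygons", {
  pt_layer <- landscape_layer("settlement", list(matrix(c(0, 0), 1)))
  expect_equal(nearest_feature_distance(rbind(c(3, 4)), pt_layer), 5)
  expect_equal(nearest_feature_distance(rbind(c(0, 0)), pt_layer), 0)

  line <- rbind(c(0, 0), c(10, 0), c(10, 10))
  road <- landscape_layer("road", list(line))
  expect_equal(nearest_feature_distance(rbind(c(5, 3)), road), 3)
  expect_equal(nearest_feature_distance(rbind(c(10, 5)), road), 0)

  poly <- landscape_layer("settlement", list(list(polygon = rbind(
    c(0, 0), c(4, 0), c(4, 4), c(0, 4)))))
  expect_equal(nearest_feature_distance(rbind(c(2, 2)), poly), 0)  # inside
  expect_equal(nearest_feature_distance(rbind(c(7, 2)), poly), 3)  # outside
})

test_that("polyline distance agrees with a dense-sampling oracle", {
  set.seed(4)
  line <- cbind(cumsum(runif(6, 100, 500)), cumsum(rnorm(6, 0, 300))) + 5e5
  layer <- landscape_layer("river", list(line))
  pts <- cbind(runif(10, 5e5, 5.02e5), runif(10, -1e3, 1e3))
  got <- nearest_feature_distance(pts, layer)
  # oracle: minimum distance to 1e4 points sampled densely along the line
  tt <- seq(0, 1, length.out = 2500)
  dense <- do.call(rbind, lapply(seq_len(nrow(line) - 1), function(i)
    cbind(line[i, 1] + tt * (line[i + 1, 1] - line[i, 1]),
          line[i, 2] + tt * (line[i + 1, 2] - line[i, 2]))))
  oracle <- apply(pts, 1, function(p)
    min(sqrt((dense[, 1] - p[1])^2 + (dense[, 2] - p[2])^2)))
  expect_equal(got, oracle, tolerance = 0.1)
  expect_true(all(got <= oracle + 1e-9))
})

test_that("geographic-looking coordinates are rejected", {
  layer <- landscape_layer("road", list(rbind(c(-15.2, 11.6), c(-15.1, 11.7))))
  expect_error(nearest_feature_distance(rbind(c(-15.15, 11.65)), layer),
               "projected")
})

test_that("transect buffer area matches flat-cap geometry", {
  tr <- rbind(c(5e5, 0), c(5e5, 3000))  # one straight 3 km transect
  reg <- transect_buffer(tr, half_width = 84)
  expect_equal(reg$area_km2, 2 * 0.084 * 3, tolerance = 0.01)

  # two parallel transects 100 m apart: union smaller than the sum,
  # and equal to the exact overlapping-rectangles union
  tr2 <- list(rbind(c(5e5, 0), c(5e5, 3000)),
              rbind(c(5e5 + 100, 0), c(5e5 + 100, 3000)))
  reg2 <- transect_buffer(tr2, half_width = 84)
  sum_areas <- 2 * (2 * 0.084 * 3)
  exact_union <- (2 * 84 + 100) * 3000 / 1e6
  expect_lt(reg2$area_km2, sum_areas)
  expect_equal(reg2$area_km2, exact_union, tolerance = 0.01)

  expect_error(transect_buffer(list(), 84), "no transects")
  expect_error(transect_buffer(tr, -5), "positive")
})

test_that("random points fall inside the buffer and are uniform over it", {
  tr <- rbind(c(5e5, 0), c(5e5, 4000))
  reg <- transect_buffer(tr, half_width = 84)
  pts <- random_points_in_buffer(reg, 214, seed = 3)
  expect_equal(nrow(pts), 214)
  expect_true(all(in_vertical_band(pts[, 1], pts[, 2], 5e5, 0, 4000, 84)))
  expect_identical(pts, random_points_in_buffer(reg, 214, seed = 3))

  # quadrant uniformity over 100 seeded draws of 4000 points
  ok <- 0L
  for (s in 1:100) {
    p <- random_points_in_buffer(reg, 4000, seed = s)
    qx <- p[, 1] > 5e5
    qy <- p[, 2] > 2000
    counts <- table(factor(qx, c(FALSE, TRUE)), factor(qy, c(FALSE, TRUE)))
    pval <- suppressWarnings(stats::chisq.test(as.vector(counts))$p.value)
    if (pval > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 98L)
})

test_that("randomization test is seeded, translation-invariant and monotone in displacement", {
  tr <- list(rbind(c(5e5, 0), c(5e5, 3000)),
             rbind(c(501000, 0), c(501000, 3000)))
  reg <- transect_buffer(tr, half_width = 84)
  layer <- landscape_layer("road", list(rbind(c(498000, -500), c(498000, 3500))))
  nests <- random_points_in_buffer(reg, 40, seed = 77)

  r1 <- randomization_test(nests, layer, reg, R = 99, seed = 5)
  r2 <- randomization_test(nests, layer, reg, R = 99, seed = 5)
  expect_identical(r1, r2)
  expect_equal(length(r1$null_means), 99L)
  expect_true(r1$p_one_sided >= 0 && r1$p_one_sided <= 1)

  # translating everything leaves the result numerically unchanged
  sh <- c(25000, -7000)
  shift <- function(m) sweep(m, 2, -sh)
  reg_s <- transect_buffer(lapply(tr, shift), half_width = 84)
  layer_s <- landscape_layer("road", lapply(layer$geometries, shift))
  r_s <- randomization_test(shift(nests), layer_s, reg_s, R = 99, seed = 5)
  expect_equal(r_s$observed_mean, r1$observed_mean, tolerance = 1e-9)
  expect_equal(r_s$null_means, r1$null_means, tolerance = 1e-9)
  expect_equal(r_s$z, r1$z, tolerance = 1e-7)
  expect_equal(r_s$p_one_sided, r1$p_one_sided)

  # moving every nest strictly farther from the feature cannot decrease Z
  nests_far <- sweep(nests, 2, c(-2000, 0))  # feature sits west; move east
  r_far <- randomization_test(nests_far, layer, reg, R = 99, seed = 5)
  expect_gte(r_far$z, r1$z)
})

test_that("degenerate and single-rep randomizations are handled as defined", {
  tr <- rbind(c(5e5, 0), c(5e5, 3000))
  reg <- transect_buffer(tr, half_width = 84)
  layer <- landscape_layer("road", list(rbind(c(498000, 0), c(498000, 3000))))
  nests <- random_points_in_buffer(reg, 10, seed = 2)
  r <- randomization_test(nests, layer, reg, R = 1, seed = 9)
  expect_true(r$p_one_sided %in% c(0, 1))
  expect_true(is.na(r$z))
})

test_that("duplicate nest coordinates collapse to independent locations", {
  tr <- rbind(c(5e5, 0), c(5e5, 3000))
  reg <- transect_buffer(tr, half_width = 84)
  layer <- landscape_layer("road", list(rbind(c(498000, 0), c(498000, 3000))))
  nests <- random_points_in_buffer(reg, 20, seed = 4)
  dup <- rbind(nests, nests[1:6, ])
  r_dup <- randomization_test(dup, layer, reg, R = 49, seed = 1)
  r_uni <- randomization_test(nests, layer, reg, R = 49, seed = 1)
  expect_equal(r_dup$n_points, 20L)
  expect_equal(r_dup$observed_mean, r_uni$observed_mean)
})

test_that("mean distance summary reports km with a normal CI", {
  s <- mean_distance_summary(c(2000, 2000))
  expect_equal(s$mean_km, 2)
  expect_equal(s$ci_high_km - s$ci_low_km, 0)

  s3 <- mean_distance_summary(c(1000, 2000, 3000))
  expect_equal(s3$mean_km, 2)
  half <- 1.96 * sd(c(1000, 2000, 3000)) / sqrt(3) / 1000
  expect_equal(s3$ci_low_km, 2 - half, tolerance = 1e-12)
  expect_equal(s3$ci_high_km, 2 + half, tolerance = 1e-12)
  expect_error(mean_distance_summary(numeric(0)), "no distances")
})

test_that("habitat-feature comparison defers to the rank test", {
  set.seed(12)
  d <- c(rnorm(20, 1000, 100), rnorm(20, 3000, 100))
  h <- rep(c("OF", "DF"), each = 20)
  kt <- habitat_feature_test(d, h)
  expect_s3_class(kt, "htest")
  expect_lt(kt$p.value, 0.001)
})
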