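test_that("landscape defaults give 11 transects of 3 km (33 km per-visit effort)", {
  cfg <- simulation_config(seed = 1)
  ls <- build_landscape(cfg)
  expect_equal(nrow(ls$layout), 11L)
  expect_equal(sum(ls$layout$length_km), 33)
  # layout composition columns sum to the transect length
  habs <- names(cfg$habitat_proportions)
  expect_equal(rowSums(ls$layout[, habs]), rep(3, 11), tolerance = 1e-9,
               ignore_attr = TRUE)
  # transect polylines measure 3 km
  for (g in ls$transects)
    expect_equal(sqrt(sum((g[2, ] - g[1, ])^2)), 3000)
})

test_that("single-habitat and zero-density configurations degenerate correctly", {
  cfg <- simulation_config(habitat_proportions = c(DF = 1),
                           builder_density = c(DF = 0.5),
                           sigma_by_habitat = c(DF = 15), seed = 2)
  ls <- build_landscape(cfg)
  expect_true(all(ls$segments$habitat == "DF"))

  cfg0 <- simulation_config(builder_density = 0, seed = 3)
  sv <- simulate_survey(cfg0)
  expect_equal(nrow(sv$observations), 0L)
  expect_true(all(sv$standing$n_standing == 0))
})

test_that("habitat mosaic reproduces the configured proportions in expectation", {
  cfg <- simulation_config(n_transects = 34L, segment_length_km = 0.01,
                           seed = 5)  # > 1e4 segments
  ls <- build_landscape(cfg)
  expect_gte(nrow(ls$segments), 1e4)
  got <- prop.table(table(ls$segments$habitat))[names(cfg$habitat_proportions)]
  expect_equal(as.numeric(got), as.numeric(cfg$habitat_proportions),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("nest births are Poisson with the configured intensity", {
  cfg <- simulation_config(n_transects = 1L, transect_length_km = 1,
                           habitat_proportions = c(DF = 1),
                           builder_density = c(DF = 2), mean_lifetime_days = 50,
                           sigma_by_habitat = c(DF = 15), w_band_m = 50,
                           n_visits = 1L, seed = 1)
  ls <- build_landscape(cfg)
  # expected births in the band over burn-in + survey span
  area <- 2 * 0.05 * 1
  t_tot <- 5 * 50   # five-lifetime burn-in + zero survey span
  mean_expect <- 2 * 1.143 * area * t_tot
  set.seed(2024)
  seed_pool <- matrix(sample.int(2^31 - 2, 100 * 50), nrow = 100)
  ok <- 0L
  for (run in 1:100) {
    counts <- vapply(1:50, function(k) {
      cfg_k <- simulation_config(n_transects = 1L, transect_length_km = 1,
                                 habitat_proportions = c(DF = 1),
                                 builder_density = c(DF = 2),
                                 mean_lifetime_days = 50,
                                 sigma_by_habitat = c(DF = 15), w_band_m = 50,
                                 n_visits = 1L, seed = seed_pool[run, k])
      nrow(simulate_nest_dynamics(ls, cfg_k))
    }, numeric(1))
    disp <- sum((counts - mean(counts))^2 / mean(counts))  # ~ chisq_49
    in_band <- disp > qchisq(0.005, 49) && disp < qchisq(0.995, 49)
    if (in_band) ok <- ok + 1L
  }
  expect_gte(ok, 98L)
  # and the intensity itself is right (pooling the last run)
  expect_equal(mean(counts), mean_expect, tolerance = 0.2)
})

test_that("infinite detection scale makes the first visit a census of the standing crop", {
  cfg <- simulation_config(sigma_by_habitat = c(DF = 1e9, OF = 1e9,
                                                SAV = 1e9, OTH = 1e9),
                           n_visits = 1L, seed = 6)
  sv <- simulate_survey(cfg)
  expect_equal(nrow(sv$observations), sv$standing$n_standing[1])
})

test_that("first-visit detected fraction matches the half-normal quadrature", {
  sigma <- 18
  cfg <- simulation_config(habitat_proportions = c(DF = 1),
                           builder_density = c(DF = 3),
                           sigma_by_habitat = c(DF = sigma), w_band_m = 60,
                           n_visits = 1L, seed = 7)
  sv <- simulate_survey(cfg)
  frac_mc <- nrow(sv$observations) / sv$standing$n_standing[1]
  frac_q <- integrate(function(x) exp(-x^2 / (2 * sigma^2)), 0, 60)$value / 60
  n0 <- sv$standing$n_standing[1]
  expect_equal(frac_mc, frac_q,
               tolerance = 3 * sqrt(frac_q * (1 - frac_q) / n0) / frac_q)
})

test_that("marked nest stream only emits nests born since the previous visit", {
  sv <- simulate_survey(simulation_config(seed = 8))
  vd <- sv$visit_days
  obs <- sv$observations
  births <- sv$nests$birth_day[match(obs$nest_id, sv$nests$nest_id)]
  for (yi in seq_along(vd)) {
    for (k in seq_along(vd[[yi]])[-1]) {
      i <- obs$year == sv$truth$start_year + yi - 1 & obs$visit == k
      if (!any(i)) next
      expect_true(all(obs$is_new[i] == 1L))
      expect_true(all(births[i] > vd[[yi]][k - 1]))   # marking correctness
      expect_true(all(births[i] <= vd[[yi]][k]))
    }
  }
  first <- obs$visit == 1
  expect_true(all(obs$is_new[first] == 0L))
  # default schedule: 4 visits year one, 5 visits year two, biweekly
  expect_equal(vd[[1]], c(0, 14, 28, 42))
  expect_equal(vd[[2]], 365 + c(0, 14, 28, 42, 56))
})

test_that("identical config and seed give an identical survey; observations stay in band", {
  a <- simulate_survey(simulation_config(seed = 99))
  b <- simulate_survey(simulation_config(seed = 99))
  expect_identical(a$observations, b$observations)
  expect_identical(a$standing, b$standing)
  c2 <- simulate_survey(simulation_config(seed = 100))
  expect_false(identical(a$observations, c2$observations))
  expect_true(all(a$observations$distance_m <= a$truth$w_band_m))
})

test_that("configuration validation catches inconsistent inputs", {
  expect_error(simulation_config(), "mandatory")
  expect_error(simulation_config(habitat_proportions = c(DF = 0.6, OF = 0.2),
                                 seed = 1), "sum to 1")
  expect_error(simulation_config(w_band_m = 30, truncation_m = 42, seed = 1),
               "narrower")
  expect_error(simulation_config(production = -1, seed = 1), "positive")
})

test_that("written survey files round-trip through the readers", {
  sv <- simulate_survey(simulation_config(seed = 21))
  dir <- tempfile("survey")
  paths <- write_survey(sv, dir)
  obs <- read_observations(paths[["observations"]])
  expect_equal(nrow(obs), nrow(sv$observations))
  lay <- read_transects(paths[["transects"]])
  expect_equal(sum(lay$length_km), 33)
  road <- read_landscape_layer(file.path(dir, "road.geojson"))
  expect_s3_class(road, "landscape_layer")
  expect_equal(road$kind, "road")
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_equal(truth$mean_lifetime_days, 294)
  lines <- nestsurvey:::read_transect_lines(file.path(dir, "transect_lines.geojson"))
  expect_equal(length(lines), 11L)
  unlink(dir, recursive = TRUE)
})
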