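test_that("truncation retains, tallies and records w correctly", {
  d <- c(1, 5, 12, 30, 41, 60, 84)
  s <- truncate_distances(d, w = 42)
  expect_true(all(s$distances <= 42))
  expect_equal(s$w, 42)
  expect_equal(s$n_discarded, 2L)

  expect_identical(truncate_distances(d, w = Inf)$distances, d)
  expect_equal(truncate_distances(d, w = Inf)$n_discarded, 0L)

  d20 <- c(seq(1, 19), 50)
  s5 <- truncate_distances(d20, discard_fraction = 0.05)
  expect_equal(s5$n_discarded, 1L)          # exactly the single largest
  expect_equal(s5$w, 19)                    # w = largest retained
  expect_false(50 %in% s5$distances)

  expect_error(truncate_distances(numeric(0), w = 10), "no observations")
  expect_error(truncate_distances(c(1, 2), w = 0), "positive")
  expect_error(truncate_distances(c(1, 2), discard_fraction = 0.6), "0.5")
  expect_error(truncate_distances(c(-1, 2), w = 10), "nonnegative")
})

test_that("labels travel with retained records through truncation", {
  s <- truncate_distances(c(5, 50, 10), w = 42, habitat = c("DF", "OF", "SAV"),
                          transect_id = c("a", "b", "c"))
  expect_equal(s$habitat, c("DF", "SAV"))
  expect_equal(s$transect_id, c("a", "c"))
})

test_that("uniform key without adjustments is the closed-form flat fit", {
  s <- truncate_distances(c(3, 10, 22, 31, 40), w = 42)
  f <- fit_detection(s, detection_spec("uniform", 0))
  expect_equal(f$f0, 1 / 42, tolerance = 1e-12)
  expect_equal(f$loglik, -5 * log(42), tolerance = 1e-12)
  expect_equal(f$aic, -2 * f$loglik)
  expect_equal(f$npar, 0L)
})

test_that("half-normal MLE matches a dense grid-search oracle", {
  s <- truncate_distances(c(5, 10, 15, 20), w = 42)
  f <- fit_detection(s, detection_spec("half-normal", 0))
  sig_grid <- exp(seq(log(0.1), log(200), length.out = 4000))
  ll <- vapply(sig_grid, oracle_hn_loglik, numeric(1), y = s$distances, w = 42)
  sig_star <- sig_grid[which.max(ll)]
  expect_equal(f$sigma, sig_star, tolerance = 1e-3)
  expect_gte(f$loglik, max(ll) - 1e-6)
})

test_that("returned MLEs beat every point of a parameter grid (oracle)", {
  for (seed in 1:3) {
    set.seed(seed)
    y <- r_trunc_halfnormal(40, 15, 42)
    s <- truncate_distances(y, w = 42)

    fhn <- fit_detection(s, detection_spec("half-normal", 0))
    grid <- exp(seq(log(1), log(150), length.out = 200))
    ll <- vapply(grid, oracle_hn_loglik, numeric(1), y = y, w = 42)
    expect_gte(fhn$loglik, max(ll) - 1e-6)

    fuc <- fit_detection(s, detection_spec("uniform", 1))
    a_grid <- seq(0, 1, length.out = 200)  # monotone non-increasing range
    ll2 <- vapply(a_grid, oracle_unifcos_loglik, numeric(1), y = y, w = 42)
    expect_gte(fuc$loglik, max(ll2) - 1e-6)
  }
})

test_that("fitted densities integrate to one and f0*w matches 1 + sum(a) for uniform-cosine", {
  set.seed(11)
  y <- r_trunc_halfnormal(80, 16, 42)
  s <- truncate_distances(y, w = 42)
  for (spec in list(detection_spec("uniform", 0), detection_spec("uniform", 1),
                    detection_spec("uniform", 2), detection_spec("half-normal", 0),
                    detection_spec("half-normal", 1))) {
    f <- fit_detection(s, spec)
    int <- stats::integrate(function(u) predict(f, u, type = "pdf"), 0, 42,
                            rel.tol = 1e-9)$value
    expect_equal(int, 1, tolerance = 1e-6)
    gg <- predict(f, seq(0, 42, length.out = 300), type = "g")
    expect_true(all(gg >= -1e-9))
    # shoulder: monotone non-increasing g implies f0 * w >= 1
    expect_gte(f$f0 * f$w, 1 - 1e-8)
    if (f$key == "uniform")
      expect_equal(f$f0 * f$w, 1 + sum(f$adjustments), tolerance = 1e-8)
  }
})

test_that("overparameterized and degenerate fits error informatively", {
  s <- truncate_distances(c(2, 5, 9, 14), w = 42)
  expect_error(fit_detection(s, detection_spec("uniform", 1)), "overparameterized")
  expect_error(detection_spec("uniform", 4), "0\\.\\.3")
})

test_that("AIC selection is order-invariant, reports the runner-up gap, breaks ties by parsimony", {
  set.seed(3)
  y <- r_trunc_halfnormal(60, 14, 42)
  s <- truncate_distances(y, w = 42)
  cands <- list(detection_spec("uniform", 0), detection_spec("half-normal", 0),
                detection_spec("uniform", 1))
  b1 <- select_detection_model(s, cands)
  b2 <- select_detection_model(s, rev(cands))
  expect_equal(b1$key, b2$key)
  expect_equal(b1$aic, b2$aic)
  expect_equal(b1$delta_aic, b2$delta_aic)
  expect_gte(b1$delta_aic, 0)

  single <- select_detection_model(s, list(detection_spec("uniform", 0)))
  expect_true(is.na(single$delta_aic))

  tiny <- truncate_distances(c(2, 5, 9, 14), w = 42)
  expect_error(select_detection_model(tiny, list(detection_spec("uniform", 1),
                                                 detection_spec("half-normal", 1))),
               "all candidate models failed")
})

test_that("chi-square GOF reproduces the hand-computed binned statistic", {
  # 6, 3, 1 observations in three equal bins on [0, 30]; flat fit, E = 10/3
  y <- c(rep(5, 6), rep(15, 3), 25)
  s <- truncate_distances(y, w = 30)
  f <- fit_detection(s, detection_spec("uniform", 0))
  g <- goodness_of_fit(f, s, n_bins = 3)
  expect_equal(g$chisq_stat, 3.80, tolerance = 1e-10)
  expect_equal(g$chisq_df, 2L)
  expect_equal(g$expected, rep(10 / 3, 3), tolerance = 1e-8)

  # equal observed and expected counts give exactly zero
  y0 <- c(5, 5, 15, 15, 25, 25)
  s0 <- truncate_distances(y0, w = 30)
  f0 <- fit_detection(s0, detection_spec("uniform", 0))
  expect_equal(goodness_of_fit(f0, s0, n_bins = 3)$chisq_stat, 0)

  expect_error(goodness_of_fit(f0, s0, n_bins = 12), "fewer bins")
  expect_error(goodness_of_fit(f0, s0, n_bins = 1), "at least 2")
})

test_that("GOF p-values are well-behaved when the model is correct", {
  set.seed(5)
  y <- r_trunc_halfnormal(150, 15, 42)
  fit <- fit_detection(truncate_distances(y, w = 42), detection_spec("half-normal", 0))
  ok <- 0L
  for (i in 1:100) {
    ynew <- r_trunc_halfnormal(150, fit$sigma, 42)
    g <- goodness_of_fit(fit, truncate_distances(ynew, w = 42))
    expect_true(all(c(g$chisq_p, g$ks_p, g$cvm_p) >= 0 &
                    c(g$chisq_p, g$ks_p, g$cvm_p) <= 1))
    if (min(g$chisq_p, g$ks_p, g$cvm_p) > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 90L)
})

test_that("strip half-width follows the detection shoulder", {
  set.seed(9)
  y <- r_trunc_halfnormal(200, 20, 60)
  f <- fit_detection(truncate_distances(y, w = 60), detection_spec("half-normal", 0))
  expect_equal(strip_half_width(f, 0.9), f$sigma * sqrt(2 * log(1 / 0.9)),
               tolerance = 1e-6)
  expect_lte(strip_half_width(f, 0.5), f$w)

  fu <- fit_detection(truncate_distances(y, w = 60), detection_spec("uniform", 0))
  expect_equal(strip_half_width(fu, 0.9), 60)   # flat detection: s = w

  # habitat-specific fits give habitat-specific widths
  set.seed(10)
  yA <- r_trunc_halfnormal(120, 12, 60)
  yB <- r_trunc_halfnormal(120, 22, 60)
  fA <- fit_detection(truncate_distances(yA, w = 60), detection_spec("half-normal", 0))
  fB <- fit_detection(truncate_distances(yB, w = 60), detection_spec("half-normal", 0))
  expect_lt(strip_half_width(fA, 0.9), strip_half_width(fB, 0.9))
})
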