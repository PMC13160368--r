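test_that("conformal quantile follows the order-statistic rule", {
  expect_equal(conformal_quantile(10:1, alpha = 0.1), 9)  # ceil(0.9*10) = 9
  expect_equal(conformal_quantile(c(3, 1, 2), alpha = 1e-6), 3)
  expect_equal(conformal_quantile(rep(7, 5), alpha = 0.4), 7)
  set.seed(1)
  s <- stats::rnorm(23)
  expect_equal(conformal_quantile(s, 0.15), sort(s)[ceiling(0.85 * 23)])
  expect_error(conformal_quantile(numeric(0), 0.1), "empty")
})

test_that("monotone trial vectors enumerate the constrained grid", {
  tr <- enumerate_monotone_trials(3, 3)
  expect_equal(dim(tr), c(3, 3))
  expect_equal(tr[, 2], c(0.25, 0.5, 0.75))

  tr5 <- enumerate_monotone_trials(5, 10)
  expect_equal(nrow(tr5), choose(10, 3))  # ordering is forced
  expect_true(all(tr5[, 1] == 0) && all(tr5[, 5] == 1))
  # every vector is a valid warping on the coarse grid
  cg <- seq(0, 1, length.out = 5)
  for (r in c(1, 57, 120)) {
    expect_s3_class(warping(cg, tr5[r, ]), "warping")
  }
  expect_error(enumerate_monotone_trials(2, 5), "at least 3")
})

test_that("FFCP accepts the truth exactly for degenerate identical samples", {
  g <- time_grid(21)
  f <- fsample(g, sin(2 * pi * g) + 2)
  train <- rep(list(f), 8)
  np <- restrict(f, interval_regime(0.5))
  band <- suppressWarnings(
    ffcp(train, np, config = fcp_config(bandwidth = 1, trial_points = 41)))
  ev <- evaluate_band(band, f)
  expect_true(all(ev$inside))
  expect_equal(ev$all_inside, 1L)
})

test_that("FFCP engine matches a naive per-(t, y) loop", {
  set.seed(42)
  n <- 5
  fns <- two_peak_fixture(n = n, n_grid = 16, seed = 42)
  target <- two_peak_fixture(n = 1, n_grid = 16, seed = 43)[[1]]
  np <- restrict(target, interval_regime(0.5))
  h <- 0.8
  cfg <- fcp_config(bandwidth = h, trial_points = 31, alpha = 0.2,
                    band_resolution = "grid")

  band <- ffcp(fns, np, config = cfg)

  xs <- c(lapply(fns, restrict, regime = np$regime), list(np))
  D <- distance_matrix(xs, "l2")
  Y <- t(sapply(fns, `[[`, "values"))
  yv <- conformalfd:::trial_values(Y, cfg)
  naive <- naive_ffcp_accept(D, Y, yv, h, alpha = 0.2)
  expect_identical(unname(band$accepted), unname(naive))
})

test_that("bands are permutation symmetric in the training sample", {
  fns <- two_peak_fixture(n = 12, n_grid = 31, seed = 51)
  target <- two_peak_fixture(n = 1, n_grid = 31, seed = 52)[[1]]
  np <- restrict(target, interval_regime(0.5))
  # several candidates with the uncorrected argmin: selection is then a
  # symmetric function of the augmented data
  cfg <- fcp_config(bandwidth = c(0.3, 0.8), trial_points = 51,
                    tuning_split = FALSE)

  band <- ffcp(fns, np, config = cfg)
  set.seed(3)
  perm <- sample(12)
  band_p <- ffcp(fns[perm], np, config = cfg)
  expect_equal(band_p$lower, band$lower)
  expect_equal(band_p$upper, band$upper)
  expect_equal(band_p$h_star, band$h_star)
})

test_that("bands are nested in alpha and stable under trial refinement", {
  fns <- two_peak_fixture(n = 15, n_grid = 26, seed = 61)
  target <- two_peak_fixture(n = 1, n_grid = 26, seed = 62)[[1]]
  np <- restrict(target, interval_regime(0.5))

  b10 <- ffcp(fns, np, config = fcp_config(alpha = 0.1, bandwidth = 0.5,
                                           trial_points = 60,
                                           band_resolution = "grid"))
  b20 <- ffcp(fns, np, config = fcp_config(alpha = 0.2, bandwidth = 0.5,
                                           trial_points = 60,
                                           band_resolution = "grid"))
  ok <- !b10$empty & !b20$empty
  expect_true(all(b20$lower[ok] >= b10$lower[ok] - 1e-12))
  expect_true(all(b20$upper[ok] <= b10$upper[ok] + 1e-12))

  b_fine <- ffcp(fns, np, config = fcp_config(alpha = 0.1, bandwidth = 0.5,
                                              trial_points = 120,
                                              band_resolution = "grid"))
  step <- apply(conformalfd:::trial_values(
    t(sapply(fns, `[[`, "values")), fcp_config(trial_points = 60)), 1,
    function(r) r[2] - r[1])
  ok <- !b10$empty & !b_fine$empty
  expect_true(all(abs(b_fine$lower - b10$lower)[ok] <= step[ok] + 1e-12))
  expect_true(all(abs(b_fine$upper - b10$upper)[ok] <= step[ok] + 1e-12))
})

test_that("SFCP reduces to FFCP behaviour when phases are degenerate", {
  fns <- two_peak_fixture(n = 24, n_grid = 41, seed = 71)
  target <- two_peak_fixture(n = 1, n_grid = 41, seed = 72)[[1]]
  np <- restrict(target, interval_regime(0.5))
  sp <- split_plan(24, seed = 5)
  cfg <- fcp_config(bandwidth = c(0.2, 0.5, 1))

  b_sfcp <- suppressWarnings(sfcp(fns, np, split = sp, config = cfg))
  b_ffcp <- ffcp(fns[sp$calib], np, config = cfg)

  # with no phase variation, registration to the Karcher mean is close to a
  # no-op, so the two bands nearly coincide
  scale <- mean(b_ffcp$upper - b_ffcp$lower, na.rm = TRUE)
  expect_lt(mean(abs(b_sfcp$lower - b_ffcp$lower), na.rm = TRUE), 0.5 * scale)
  expect_lt(mean(abs(b_sfcp$upper - b_ffcp$upper), na.rm = TRUE), 0.5 * scale)
})

test_that("SFCPP accepted set matches exhaustive naive recomputation", {
  fns <- two_peak_fixture(n = 8, n_grid = 21, phase = TRUE, seed = 81)
  target <- two_peak_fixture(n = 1, n_grid = 21, phase = TRUE, seed = 82)[[1]]
  np <- restrict(target, interval_regime(0.5))
  sp <- split_plan(8, n1 = 4, seed = 9)
  cg <- c(0, 0.5, 1)
  cfg <- fcp_config(bandwidth = 0.6, alpha = 0.25)

  pred <- suppressWarnings(
    sfcpp(fns, np, split = sp, coarse_grid = cg, config = cfg,
          trials_per_point = 5))

  calib <- fns[sp$calib]
  xs <- c(lapply(calib, restrict, regime = np$regime), list(np))
  D <- distance_matrix(xs, "l2")
  Y <- do.call(rbind, lapply(pred$calibration_phases, function(g)
    stats::approx(g$grid, g$values, xout = cg, rule = 2)$y))
  Y[, 1] <- 0
  Y[, 3] <- 1
  naive <- naive_sfcpp_accept(D, Y, pred$trials, h = 0.6, alpha = 0.25)
  expect_identical(unname(pred$accepted), unname(naive))
})

test_that("SFCPP centers on the identity for unwarped data", {
  fns <- two_peak_fixture(n = 20, n_grid = 41, seed = 91)
  target <- two_peak_fixture(n = 1, n_grid = 41, seed = 92)[[1]]
  np <- restrict(target, interval_regime(0.5))
  pred <- suppressWarnings(
    sfcpp(fns, np, split = split_plan(20, seed = 2),
          trials_per_point = 20,
          config = fcp_config(tuning = "global")))
  cg <- pred$coarse_grid
  expect_lt(max(abs(pred$point_prediction - cg)), 0.1)
  expect_false(pred$empty)
  ev <- evaluate_phase_set(pred, identity_warping(time_grid(41)))
  expect_equal(ev$covered, 1L)
})

test_that("SFCP runs end-to-end under fragmented and sparse regimes", {
  set.seed(4)
  cfg <- sim_config(n = 24, n_grid = 41, phase_variation = TRUE)
  fns <- apply_phase(generate_two_peak(cfg, n = 25),
                     generate_beta_warpings(25, time_grid(41)))
  for (rg in list(make_observation_regime("fragmented"),
                  make_observation_regime("sparse"))) {
    np <- restrict(fns[[25]], rg)
    b <- suppressWarnings(sfcp(fns[1:24], np, split = split_plan(24, seed = 1)))
    orc <- pairwise_align(b$karcher$mean_function, fns[[25]])
    ev <- evaluate_band(b, orc$aligned)
    expect_gt(mean(ev$inside), 0.7)
    expect_true(all(ev$lengths >= 0))
    expect_false(any(b$empty))
  }
})
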