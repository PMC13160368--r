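test_that("SRSF transform matches closed forms and flags bad input", {
  g <- time_grid(101)

  q_lin <- srsf_transform(fsample(g, g))
  expect_equal(q_lin$values, rep(1, 101), tolerance = 1e-12)
  expect_equal(q_lin$origin, 0)

  q_const <- srsf_transform(fsample(g, rep(3, 101)))
  expect_equal(q_const$values, rep(0, 101))
  expect_equal(q_const$origin, 3)

  # f(t) = t^2 has SRSF sqrt(2t); centered differences are exact for
  # quadratics at interior points.
  q_sq <- srsf_transform(fsample(g, g^2))
  interior <- 2:100
  expect_equal(q_sq$values[interior], sqrt(2 * g[interior]), tolerance = 1e-10)

  expect_error(fsample(g, c(rep(0, 100), NA)), "finite")
})

test_that("SRSF inversion reconstructs functions", {
  g <- time_grid(101)
  expect_equal(srsf_inverse(srsf(g, rep(1, 101), origin = 0))$values, g,
               tolerance = 1e-12)
  expect_equal(srsf_inverse(srsf(g, rep(0, 101), origin = 5))$values,
               rep(5, 101))

  # Round trip on a sharp two-peak function.
  f <- two_peak_fixture(n = 1)[[1]]
  back <- srsf_inverse(srsf_transform(f))
  expect_lt(max(abs(back$values - f$values)), 0.05)
})

test_that("domain warping composes and inverts correctly", {
  g <- time_grid(101)
  f <- two_peak_fixture(n = 1)[[1]]

  expect_equal(warp_function(f, identity_warping(g))$values, f$values)

  gam <- smooth_random_warping(g)
  expect_equal(warp_function(fsample(g, g), gam)$values, gam$values)

  # f o gamma o gamma^{-1} recovers f up to interpolation error.
  fw <- warp_function(f, gam)
  back <- warp_function(fw, invert_warping_for_test(gam))
  expect_lt(max(abs(back$values - f$values)), 0.05)

  expect_error(warp_function(f, list(values = g)), "invalid warping")
  expect_error(warping(g, rev(g)), "endpoints|positive")
})

test_that("SRSF group action is an isometry and commutes with the transform", {
  g <- time_grid(201)
  f <- two_peak_fixture(n = 1, n_grid = 201)[[1]]
  q <- srsf_transform(f)

  expect_equal(group_action_srsf(q, identity_warping(g))$values, q$values)

  set.seed(5)
  for (shapes in list(c(2, 1), c(1.2, 2.6), c(2.8, 2.8))) {
    gam <- warping(g, stats::pbeta(g, shapes[1], shapes[2]))
    qg <- group_action_srsf(q, gam)
    # isometry
    expect_lt(abs(l2_norm(g, qg$values) - l2_norm(g, q$values)), 0.02)
    # commutativity with Q
    q_of_warp <- srsf_transform(warp_function(f, gam))
    expect_lt(l2_norm(g, qg$values - q_of_warp$values), 0.15)
  }
})

test_that("Fisher-Rao distance is invariant to simultaneous warping", {
  g <- time_grid(201)
  fns <- two_peak_fixture(n = 2, n_grid = 201, seed = 7)
  d0 <- srsf_distance(srsf_transform(fns[[1]]), srsf_transform(fns[[2]]))
  gam <- smooth_random_warping(g, 2.2, 1.4)
  d1 <- srsf_distance(srsf_transform(warp_function(fns[[1]], gam)),
                      srsf_transform(warp_function(fns[[2]], gam)))
  expect_lt(abs(d0 - d1), 0.05 * max(d0, 1))
})

test_that("pairwise alignment is exact on the DP path set", {
  # Self-alignment returns the identity with zero amplitude distance.
  f <- two_peak_fixture(n = 1)[[1]]
  reg <- pairwise_align(f, f)
  expect_equal(reg$warping$values, f$grid, tolerance = 1e-12)
  expect_lt(reg$amplitude_distance, 1e-10)

  # DP objective no worse than the identity warping.
  fns <- two_peak_fixture(n = 2, seed = 9)
  reg2 <- pairwise_align(fns[[1]], fns[[2]])
  d_id <- srsf_distance(srsf_transform(fns[[1]]), srsf_transform(fns[[2]]))
  expect_lte(reg2$amplitude_distance, d_id + 1e-10)

  # Warped copies realign to near-zero amplitude distance.
  g <- time_grid(101)
  gam <- smooth_random_warping(g, 2, 1.2)
  fw <- warp_function(f, gam)
  expect_gt(srsf_distance(srsf_transform(f), srsf_transform(fw)), 1)
  expect_lt(amplitude_distance(f, fw), 0.25)

  # Constant inputs trigger the degenerate contract.
  fc <- fsample(g, rep(1, 101))
  expect_warning(regc <- pairwise_align(fc, fc), "degenerate")
  expect_equal(regc$warping$values, g)
})

test_that("DP objective equals the brute-force minimum over its path set", {
  g <- time_grid(8)
  set.seed(31)
  for (rep in 1:3) {
    v1 <- cumsum(c(0, stats::rnorm(7, sd = 0.5)))
    v2 <- cumsum(c(0, stats::rnorm(7, sd = 0.5)))
    q1 <- srsf_transform(fsample(g, v1))
    q2 <- srsf_transform(fsample(g, v2))
    dp <- conformalfd:::dp_align_srsf(q1$values, q2$values, nbhd = 3L)
    brute <- brute_force_dp_value(q1$values, q2$values, nbhd = 3)
    expect_equal(dp$value, brute, tolerance = 1e-10)
  }
})

test_that("Karcher mean fixes degenerate samples and reduces phase variance", {
  f <- two_peak_fixture(n = 1)[[1]]

  km1 <- karcher_mean(list(f))
  expect_equal(km1$mean_function$values, f$values)

  km3 <- karcher_mean(list(f, f, f))
  expect_lt(max(abs(km3$mean_function$values - f$values)), 0.05)
  for (g in km3$relative_phases) {
    expect_lt(max(abs(g$values - g$grid)), 1e-6)
  }
  expect_true(km3$converged)
  expect_error(karcher_mean(list()), "at least one")

  # A warped population realigns: cross-sectional variance of the aligned
  # functions drops by a large factor and the objective is non-increasing.
  set.seed(77)
  cfg <- sim_config(n = 30, n_grid = 101)
  fns <- apply_phase(generate_two_peak(cfg, n = 30),
                     generate_beta_warpings(30, grid = time_grid(101)))
  km <- karcher_mean(fns)
  V0 <- sapply(fns, `[[`, "values")
  V1 <- sapply(km$aligned_functions, `[[`, "values")
  ratio <- mean(apply(V0, 1, var)) / mean(apply(V1, 1, var))
  expect_gt(ratio, 5)
  expect_true(all(diff(km$objective) <= 1e-8))
  # mean of f_i(0) preserved; mean relative phase centered at the identity
  expect_equal(km$mean_function$values[1], mean(sapply(fns, function(x) x$values[1])))
  gbar <- rowMeans(sapply(km$relative_phases, `[[`, "values"))
  expect_lt(max(abs(gbar - time_grid(101))), 0.02)
})

test_that("amplitude distance behaves like an elastic metric", {
  fns <- two_peak_fixture(n = 2, seed = 15)
  expect_lt(amplitude_distance(fns[[1]], fns[[1]]), 1e-10)
  d <- amplitude_distance(fns[[1]], fns[[2]])
  expect_gte(d, 0)
  d_id <- srsf_distance(srsf_transform(fns[[1]]), srsf_transform(fns[[2]]))
  expect_lte(d, d_id + 1e-10)
})

test_that("warping distance has the closed-form value and metric properties", {
  g <- time_grid(101)
  id <- identity_warping(g)
  sq <- warping(g, g^2)

  expect_equal(warping_distance(id, id), 0)
  expect_equal(warping_distance(sq, sq), 0)
  # d_w(id, t^2) = arccos(int_0^1 sqrt(2t) dt) = arccos(2 sqrt(2) / 3)
  expect_equal(warping_distance(id, sq), acos(2 * sqrt(2) / 3),
               tolerance = 2e-3)

  set.seed(8)
  for (i in 1:4) {
    ab <- stats::runif(4, 1, 3)
    g1 <- warping(g, stats::pbeta(g, ab[1], ab[2]))
    g2 <- warping(g, stats::pbeta(g, ab[3], ab[4]))
    expect_identical(warping_distance(g1, g2), warping_distance(g2, g1))
    expect_gte(warping_distance(g1, g2), 0)
    expect_false(is.na(warping_distance(g1, g2)))
  }
})
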