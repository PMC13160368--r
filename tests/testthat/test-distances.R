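test_that("restriction retains the right observations per regime", {
  g <- time_grid(101)
  f <- two_peak_fixture(n = 1)[[1]]

  full <- restrict(f, interval_regime(1))
  expect_equal(full$values, f$values)

  half <- restrict(f, interval_regime(0.5))
  expect_length(half$times, 51)  # grid points with t <= 0.5
  expect_equal(half$values, f$values[1:51])

  sp <- restrict(f, sparse_regime(seq(0, 1, by = 0.1)))
  expect_length(sp$values, 11)
  expect_equal(sp$values[1], f$values[1])

  fr <- restrict(f, fragment_regime(rbind(c(0, 0.2), c(0.4, 0.6), c(0.8, 1))))
  expect_length(fr$parts, 3)
  expect_equal(fr$parts[[2]]$times, g[g >= 0.4 - 1e-10 & g <= 0.6 + 1e-10])

  expect_error(interval_regime(0), "in \\(0, 1\\]")
  expect_error(fragment_regime(rbind(c(0, 0.5), c(0.4, 1))), "disjoint")
})

test_that("partial distances match quadrature oracles and metric axioms", {
  g <- time_grid(101)
  reg <- interval_regime(0.5)
  x0 <- restrict(fsample(g, rep(0, 101)), reg)
  x1 <- restrict(fsample(g, rep(1, 101)), reg)

  # int_0^0.5 1 dt = 0.5
  expect_equal(partial_distance(x0, x1, "l2"), sqrt(0.5), tolerance = 1e-10)
  for (m in c("l2", "fr", "amplitude")) {
    expect_equal(suppressWarnings(partial_distance(x1, x1, m)), 0,
                 tolerance = 1e-10)
  }

  # triangle inequality for l2 and fr on sampled triples
  fns <- two_peak_fixture(n = 3, seed = 21)
  xs <- lapply(fns, restrict, regime = reg)
  for (m in c("l2", "fr")) {
    d12 <- partial_distance(xs[[1]], xs[[2]], m)
    d13 <- partial_distance(xs[[1]], xs[[3]], m)
    d23 <- partial_distance(xs[[2]], xs[[3]], m)
    expect_lte(d12, d13 + d23 + 1e-10)
  }

  expect_error(partial_distance(x0, restrict(fsample(g, g),
                                             sparse_regime(c(0, 0.5, 1)))),
               "same regime")
})

test_that("fragmented distance is the weighted sum of per-fragment distances", {
  reg3 <- fragment_regime(rbind(c(0, 0.2), c(0.4, 0.6), c(0.8, 1)))
  fns <- two_peak_fixture(n = 2, seed = 33)
  x1 <- restrict(fns[[1]], reg3)
  x2 <- restrict(fns[[2]], reg3)
  per_frag <- vapply(1:3, function(j) {
    p1 <- x1$parts[[j]]; p2 <- x2$parts[[j]]
    sqrt(pracma::trapz(p1$times, (p1$values - p2$values)^2))
  }, numeric(1))
  expect_equal(partial_distance(x1, x2, "l2"), mean(per_frag),
               tolerance = 1e-12)

  # single fragment with weight 1 reduces to the plain metric
  reg1 <- fragment_regime(rbind(c(0, 0.5)), weights = 1)
  xi <- restrict(fns[[1]], reg1)
  xj <- restrict(fns[[2]], reg1)
  plain <- partial_distance(restrict(fns[[1]], interval_regime(0.5)),
                            restrict(fns[[2]], interval_regime(0.5)), "l2")
  expect_equal(partial_distance(xi, xj, "l2"), plain, tolerance = 1e-12)
})

test_that("sparse distance is Euclidean on the value vectors", {
  g <- time_grid(101)
  reg <- sparse_regime(seq(0, 1, by = 0.1))
  x1 <- restrict(fsample(g, g), reg)
  x2 <- restrict(fsample(g, 2 * g), reg)
  expect_equal(partial_distance(x1, x2, "l2"),
               sqrt(sum(seq(0, 1, by = 0.1)^2)), tolerance = 1e-10)
})

test_that("distance matrices are symmetric with zero diagonal", {
  reg <- interval_regime(0.5)
  fns <- two_peak_fixture(n = 6, seed = 41)
  xs <- lapply(fns, restrict, regime = reg)

  for (m in c("l2", "fr")) {
    D <- distance_matrix(xs, m)
    expect_equal(diag(D), rep(0, 6), tolerance = 1e-8)
    expect_equal(D, t(D), tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(D >= 0))
    # fast path agrees with the scalar routine
    expect_equal(D[1, 2], partial_distance(xs[[1]], xs[[2]], m),
                 tolerance = 1e-8)
  }

  Da <- suppressWarnings(distance_matrix(xs[1:4], "amplitude", k_max = 4))
  expect_equal(Da, t(Da), ignore_attr = TRUE)
  expect_equal(diag(Da), rep(0, 4), tolerance = 1e-8)

  x2 <- xs[c(1, 1)]
  expect_equal(unname(distance_matrix(x2, "l2")), matrix(0, 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})
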