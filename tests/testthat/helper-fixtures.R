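# Shared fixtures: all data are generated in code under fixed seeds.

two_peak_fixture <- function(n = 10, n_grid = 101, phase = FALSE, seed = 101) {
  set.seed(seed)
  cfg <- sim_config(n = max(n, 2), n_grid = n_grid, phase_variation = phase)
  fns <- generate_two_peak(cfg, n = n)
  if (phase) {
    fns <- apply_phase(fns, generate_beta_warpings(n, grid = time_grid(n_grid)))
  }
  fns
}

smooth_random_warping <- function(grid, a = 2, b = 1.5) {
  warping(grid, stats::pbeta(grid, a, b))
}

# Independent reimplementation of the FFCP accept/reject decision: a naive
# double loop over time points and trial values that re-runs the smoother on
# each augmented data set from scratch. Used as an oracle for the vectorized
# engine.
naive_ffcp_accept <- function(D, Y, yv, h, alpha, kernel = "gaussian") {
  n <- nrow(Y)
  Tn <- ncol(Y)
  K <- smoothing_kernel(kernel)
  k <- ceiling((1 - alpha) * (n + 1))
  acc <- matrix(FALSE, Tn, ncol(yv))
  for (tt in seq_len(Tn)) {
    for (jj in seq_len(ncol(yv))) {
      y <- yv[tt, jj]
      resp <- c(Y[, tt], y)
      yhat <- vapply(seq_len(n + 1), function(i) {
        w <- K(D[i, -i] / h)
        sum(w * resp[-i]) / sum(w)
      }, numeric(1))
      S <- abs(resp - yhat)
      acc[tt, jj] <- S[n + 1] <= sort(S)[k]
    }
  }
  acc
}

# Naive SFCPP accept decision: loops over trial vectors, re-smooths every
# coordinate of the augmented phase responses, and scores with the
# sqrt-increment arc-length distance.
naive_sfcpp_accept <- function(D, Y, trials, h, alpha, kernel = "gaussian") {
  n2 <- nrow(Y)
  K <- smoothing_kernel(kernel)
  k <- ceiling((1 - alpha) * (n2 + 1))
  dw <- function(v1, v2) {
    ip <- sum(sqrt(pmax(diff(v1), 0) * pmax(diff(v2), 0)))
    acos(min(max(ip, -1), 1))
  }
  vapply(seq_len(nrow(trials)), function(r) {
    resp <- rbind(Y, trials[r, ])
    S <- vapply(seq_len(n2 + 1), function(i) {
      w <- K(D[i, -i] / h)
      yhat <- drop(w %*% resp[-i, , drop = FALSE]) / sum(w)
      dw(resp[i, ], yhat)
    }, numeric(1))
    S[n2 + 1] <= sort(S)[k]
  }, logical(1))
}

# Brute-force minimum of the DP objective: exhaustive enumeration of every
# monotone lattice path with coprime steps bounded by `nbhd`, costing each
# edge with the same trapezoidal quadrature as the aligner.
brute_force_dp_value <- function(q1, q2, nbhd = 3) {
  T <- length(q1)
  steps <- expand.grid(di = 1:nbhd, dj = 1:nbhd)
  keep <- mapply(function(p, q) {
    while (q) { r <- p %% q; p <- q; q <- r }
    p == 1
  }, steps$di, steps$dj)
  steps <- steps[keep, ]
  h <- 1 / (T - 1)
  edge <- function(a, b, di, dj) {
    rs <- sqrt(dj / di)
    o <- 0:di
    pos <- b + dj * o / di
    fl <- pmin(floor(pos), T - 2)
    w <- pos - fl
    q2v <- q2[fl + 1] * (1 - w) + q2[fl + 2] * w
    q2v[pos >= T - 1] <- q2[T]
    wt <- rep(1, di + 1)
    wt[c(1, di + 1)] <- 0.5
    sum(wt * (q1[a + o + 1] - q2v * rs)^2) * h
  }
  best <- Inf
  recurse <- function(i, j, cost) {
    if (cost >= best) return(invisible())
    if (i == T - 1 && j == T - 1) {
      best <<- min(best, cost)
      return(invisible())
    }
    for (s in seq_len(nrow(steps))) {
      di <- steps$di[s]; dj <- steps$dj[s]
      if (i + di <= T - 1 && j + dj <= T - 1) {
        recurse(i + di, j + dj, cost + edge(i, j, di, dj))
      }
    }
  }
  recurse(0, 0, 0)
  best
}

l2_norm <- function(grid, v) sqrt(pracma::trapz(grid, v^2))

# Numerical inverse by swapping axes and re-interpolating onto the grid.
invert_warping_for_test <- function(gam) {
  v <- stats::approx(gam$values, gam$grid, xout = gam$grid, rule = 2)$y
  v[1] <- 0
  v[length(v)] <- 1
  warping(gam$grid, v, slope_eps = 0)
}
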