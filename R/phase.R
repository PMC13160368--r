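#' Enumerate monotone trial vectors for phase prediction
#'
#' All strictly increasing vectors on a coarse grid of `coarse_T` points with
#' fixed endpoints y_1 = 0 and y_T = 1 and interior entries drawn from the
#' uniform grid j/(g+1), j = 1..g, on (0, 1). Because ordering is forced,
#' there are choose(g, coarse_T - 2) such vectors.
#'
#' @param coarse_T Number of coarse time points (>= 3).
#' @param values_per_point Number g of interior grid values.
#' @return Matrix with one trial vector per row (`coarse_T` columns).
#' @export
enumerate_monotone_trials <- function(coarse_T, values_per_point) {
  if (coarse_T < 3) stop("need at least 3 coarse time points", call. = FALSE)
  g <- values_per_point
  u <- seq_len(g) / (g + 1)
  combos <- utils::combn(g, coarse_T - 2)
  inner <- matrix(u[combos], nrow = coarse_T - 2)
  cbind(0, t(inner), 1, deparse.level = 0)
}

# d_w scores of every trial row against a matrix of smoothed responses that
# is affine in the trial: Yhat = a + w * y (rowwise). Returns the inner
# products sum_j sqrt(dY_j * dYhat_j) for one calibration response Yrow.
phase_scores_affine <- function(Yrow, a, w, trial_diffs) {
  da <- diff(a)
  dYhat <- matrix(da, nrow = nrow(trial_diffs), ncol = length(da),
                  byrow = TRUE) + w * trial_diffs
  dYhat[dYhat < 0] <- 0
  ip <- sqrt(dYhat) %*% sqrt(pmax(diff(Yrow), 0))
  acos(pmin(pmax(drop(ip), -1), 1))
}

# Phase prediction set for a single bandwidth: augmented scoring of every
# monotone trial vector, lower-quantile inclusion, pointwise envelope.
# D: (m+1) x (m+1); Y: m x Tc warping vectors; k: quantile index.
phase_set_for_h <- function(D, Y, trials, trial_diffs, h, k, config) {
  m <- nrow(Y)
  Tc <- ncol(Y)
  Wn <- kernel_weights(D, h, config$kernel)
  w_new <- Wn[seq_len(m), m + 1]
  A <- Wn[seq_len(m), seq_len(m), drop = FALSE] %*% Y
  yhat_new <- drop(Wn[m + 1, seq_len(m), drop = FALSE] %*% Y)
  yhat_new[1] <- 0
  yhat_new[Tc] <- 1

  d_new_hat <- pmax(diff(yhat_new), 0)
  ip_new <- sqrt(pmax(trial_diffs, 0)) %*% sqrt(d_new_hat)
  S_new <- acos(pmin(pmax(drop(ip_new), -1), 1))

  cnt <- integer(nrow(trials))
  for (i in seq_len(m)) {
    S_i <- phase_scores_affine(Y[i, ], A[i, ], w_new[i], trial_diffs)
    cnt <- cnt + (S_i < S_new)
  }
  acc <- cnt <= k - 1
  if (any(acc)) {
    env_lo <- apply(trials[acc, , drop = FALSE], 2, min)
    env_hi <- apply(trials[acc, , drop = FALSE], 2, max)
    lengths <- env_hi - env_lo
  } else {
    env_lo <- env_hi <- rep(NA_real_, Tc)
    lengths <- rep(0, Tc)
  }
  list(h = h, accepted = acc, lower = env_lo, upper = env_hi,
       lengths = lengths, empty = rep(!any(acc), Tc), point = yhat_new)
}

# Mean time-averaged envelope length of pilot phase problems per bandwidth,
# with each pseudo-target in turn playing the new observation. All-empty
# candidates become Inf.
pilot_phase_lengths <- function(D_pilot, Y_pilot, pseudo, H, config,
                                trials_per_point) {
  a <- nrow(Y_pilot)
  Tc <- ncol(Y_pilot)
  k <- ceiling((1 - config$alpha) * a)
  trials <- enumerate_monotone_trials(Tc, trials_per_point)
  trial_diffs <- t(diff(t(trials)))
  L <- N <- numeric(length(H))
  for (j in pseudo) {
    idx <- c(setdiff(seq_len(a), j), j)
    Dj <- D_pilot[idx, idx]
    Yj <- Y_pilot[idx[seq_len(a - 1)], , drop = FALSE]
    for (s in seq_along(H)) {
      b <- phase_set_for_h(Dj, Yj, trials, trial_diffs, H[s], k, config)
      if (!b$empty[1]) {
        L[s] <- L[s] + mean(b$lengths)
        N[s] <- N[s] + 1
      }
    }
  }
  out <- L / N
  out[N == 0] <- Inf
  out
}

#' Split conformal prediction of relative phase (SFCPP)
#'
#' Joint conformal prediction of the relative phase of a partially observed
#' function with respect to the Karcher mean of a training set. Responses are
#' the calibration relative phases sampled on a coarse grid; trial values are
#' whole monotone vectors with fixed endpoints (pointwise intervals cannot
#' respect monotonicity, so the prediction is joint over the coarse grid).
#' Each coordinate is smoothed with the neighborhood estimator, the
#' nonconformity score is the Fisher-Rao distance between warping vectors
#' (arc length on the Hilbert sphere of sqrt-increment vectors), and a trial
#' vector is accepted when its augmented score is within the lower (1 -
#' alpha) conformal quantile. Bandwidth tuning is global (one bandwidth for
#' all coordinates), minimizing the time-averaged pointwise envelope length
#' of the accepted set.
#'
#' @param functions List of n complete [fsample]s.
#' @param new_partial [partial_obs] for the new function.
#' @param split A [split_plan]; default balanced.
#' @param coarse_grid Coarse time grid for the phase (default
#'   `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param config An [fcp_config] (`tuning` is forced to global).
#' @param trials_per_point Number of interior trial values per coarse point.
#' @param karcher_args Extra arguments passed to [karcher_mean].
#' @return A list of class `phase_prediction_set` with the accepted trial
#'   vectors, the pointwise \[min, max\] envelope, the unaugmented smoothed
#'   point prediction, the selected bandwidth and the split/Karcher objects.
#' @export
sfcpp <- function(functions, new_partial, split = NULL,
                  coarse_grid = c(0, 0.25, 0.5, 0.75, 1),
                  config = fcp_config(tuning = "global"),
                  trials_per_point = 100, karcher_args = list()) {
  stopifnot(inherits(new_partial, "partial_obs"))
  n <- length(functions)
  if (is.null(split)) split <- split_plan(n)
  fm <- fsample_matrix(functions)
  validate_grid(fm$grid, uniform = TRUE)
  Tc <- length(coarse_grid)
  if (Tc < 3) stop("coarse grid needs at least 3 points", call. = FALSE)

  km <- do.call(karcher_mean,
                c(list(fs = functions[split$train],
                       k_max = config$k_max), karcher_args))
  calib <- functions[split$calib]
  regs <- lapply(calib, function(f)
    pairwise_align(km$mean_function, f, k_max = config$k_max))
  # Relative phases sampled on the coarse grid (linear interpolation).
  Y <- do.call(rbind, lapply(regs, function(r) {
    v <- stats::approx(r$warping$grid, r$warping$values,
                       xout = coarse_grid, rule = 2)$y
    v[1] <- 0
    v[Tc] <- 1
    v
  }))
  n2 <- nrow(Y)

  xs <- c(lapply(calib, restrict, regime = new_partial$regime),
          list(new_partial))
  D <- distance_matrix(xs, config$metric, k_max = config$k_max)

  trials <- enumerate_monotone_trials(Tc, trials_per_point)
  trial_diffs <- t(diff(t(trials)))
  k <- ceiling((1 - config$alpha) * (n2 + 1))

  H <- if (!is.null(config$bandwidth)) {
    sort(unique(config$bandwidth))
  } else {
    candidate_bandwidths(D, beta = config$beta_grid)
  }

  if (config$tuning_split && length(H) > 1 && split$n1 >= 4) {
    # Global bandwidth selected on pilot problems among the training
    # relative phases, independent of the calibration scores.
    xs_train <- lapply(functions[split$train], restrict,
                       regime = new_partial$regime)
    D_train <- distance_matrix(xs_train, config$metric, k_max = config$k_max)
    Y_train <- do.call(rbind, lapply(km$relative_phases, function(g) {
      v <- stats::approx(g$grid, g$values, xout = coarse_grid, rule = 2)$y
      v[1] <- 0
      v[Tc] <- 1
      v
    }))
    norms <- vapply(xs_train, partial_obs_norm, numeric(1))
    pseudo <- representative_targets(norms, config$pilot_targets)
    sel <- pilot_phase_lengths(D_train, Y_train, pseudo, H, config,
                               trials_per_point = min(15, trials_per_point))
    best <- phase_set_for_h(D, Y, trials, trial_diffs, H[which.min(sel)],
                            k, config)
  } else {
    per_h <- lapply(H, function(h)
      phase_set_for_h(D, Y, trials, trial_diffs, h, k, config))
    tuned <- tune_bandwidth(function(h) per_h[[match(h, H)]], H,
                            mode = "global")
    best <- per_h[[tuned$pick[1]]]
  }

  structure(list(
    coarse_grid = coarse_grid,
    trials = trials,
    accepted = best$accepted,
    accepted_vectors = trials[best$accepted, , drop = FALSE],
    envelope_lower = best$lower, envelope_upper = best$upper,
    envelope_lengths = best$lengths,
    empty = !any(best$accepted),
    point_prediction = best$point,
    alpha = config$alpha, method = "sfcpp",
    h_star = best$h, candidates = H,
    trials_per_point = trials_per_point,
    karcher = km, karcher_converged = km$converged, split = split,
    calibration_phases = lapply(regs, `[[`, "warping")),
    class = "phase_prediction_set")
}

#' @export
print.phase_prediction_set <- function(x, ...) {
  cat(sprintf(
    "<phase_prediction_set> alpha = %.3g, %d/%d trial vectors accepted, mean envelope length %.4g\n",
    x$alpha, sum(x$accepted), nrow(x$trials), mean(x$envelope_lengths)))
  invisible(x)
}
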