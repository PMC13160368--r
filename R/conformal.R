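#' Configuration for the conformal prediction engines
#'
#' @param alpha Miscoverage level in (0, 1).
#' @param metric Predictor distance: `"l2"`, `"fr"` or `"amplitude"`.
#' @param kernel Smoothing kernel name.
#' @param tuning Bandwidth selection mode, `"local"` (one bandwidth per time
#'   point) or `"global"`.
#' @param bandwidth Optional fixed bandwidth (or vector of candidates); when
#'   `NULL`, candidates come from distance quantiles via
#'   [candidate_bandwidths].
#' @param beta_grid Quantile levels used to build the candidate set.
#' @param trial_points Number of points in the response trial grid.
#' @param trial_margin Fraction of the observed response range added on each
#'   side of the trial grid.
#' @param k_max DP slope bound used wherever registration is involved.
#' @param band_resolution `"exact"` computes interval endpoints in closed
#'   form from the piecewise-linear accept rule (no trial-grid noise; the
#'   default); `"grid"` reports the hull of accepted trial-grid values, the
#'   plain grid-search formulation.
#' @param tuning_split Select the bandwidth on pilot conformal problems that
#'   are independent of the conformalized nonconformity scores (default).
#'   Selecting on the same scores that form the conformal quantile biases
#'   intervals short and breaks pointwise validity wherever the response
#'   distribution is skewed; the pilot construction keeps the selection
#'   length-driven while preserving the finite-sample guarantee. Set to
#'   `FALSE` for the uncorrected argmin.
#' @param tuning_frac Fraction of the training functions set aside as the
#'   FFCP tuning subset (SFCP/SFCPP tune on the training half instead, which
#'   costs no data).
#' @param pilot_targets Number of representative pseudo-targets used in the
#'   pilot problems (chosen symmetrically by predictor-norm quantiles).
#' @param pilot_trial_points Trial-grid resolution of the pilot problems.
#' @return A list of class `fcp_config`.
#' @export
fcp_config <- function(alpha = 0.1, metric = c("l2", "fr", "amplitude"),
                       kernel = c("gaussian", "triangular"),
                       tuning = c("local", "global"), bandwidth = NULL,
                       beta_grid = seq(0.1, 0.9, by = 0.1),
                       trial_points = 200, trial_margin = 0.25, k_max = 7,
                       band_resolution = c("exact", "grid"),
                       tuning_split = TRUE, tuning_frac = 0.3,
                       pilot_targets = 5, pilot_trial_points = 60) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(alpha = alpha, metric = match.arg(metric),
                 kernel = match.arg(kernel), tuning = match.arg(tuning),
                 bandwidth = bandwidth, beta_grid = beta_grid,
                 trial_points = trial_points, trial_margin = trial_margin,
                 k_max = k_max, band_resolution = match.arg(band_resolution),
                 tuning_split = tuning_split,
                 tuning_frac = tuning_frac, pilot_targets = pilot_targets,
                 pilot_trial_points = pilot_trial_points),
            class = "fcp_config")
}

#' Train/calibration split plan
#'
#' @param n Total number of complete functions.
#' @param n1 Training-set size (default a balanced split, `floor(n/2)`).
#' @param seed Optional seed for the random split (recorded in the plan).
#' @return A list of class `split_plan` with sorted `train` and `calib`
#'   index vectors.
#' @export
split_plan <- function(n, n1 = floor(n / 2), seed = NULL) {
  if (n1 <= 0 || n1 >= n) stop("need 0 < n1 < n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  train <- sort(sample.int(n, n1))
  structure(list(n = n, n1 = n1, n2 = n - n1, train = train,
                 calib = setdiff(seq_len(n), train), seed = seed),
            class = "split_plan")
}

#' Lower conformal quantile of a score vector
#'
#' The ceiling((1 - alpha) m)-th smallest of the m augmented scores — the
#' lower-quantile convention under which the conformal inclusion rule attains
#' finite-sample marginal validity for exchangeable scores.
#'
#' @param scores Numeric vector (nonempty).
#' @param alpha Miscoverage level in (0, 1).
#' @return The threshold score.
#' @export
conformal_quantile <- function(scores, alpha) {
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  sort(scores)[ceiling((1 - alpha) * length(scores))]
}

# Uniform trial grids along the y-axis, one row per time point, covering the
# responses observed at that time point with a proportional margin on each
# side. Per-time-point ranges are essential: the response scale varies by
# orders of magnitude along the domain, and a single global grid cannot
# resolve prediction intervals where the responses are nearly constant.
trial_values_for <- function(Y, config) {
  if (identical(config$band_resolution, "grid")) trial_values(Y, config) else NULL
}

trial_values <- function(Y, config) {
  t(apply(Y, 2, function(col) {
    r <- range(col)
    m <- config$trial_margin * diff(r)
    if (m <= 0) m <- max(abs(r[1]), 1) * config$trial_margin
    seq(r[1] - m, r[2] + m, length.out = config$trial_points)
  }))
}

# Conformal band for a single bandwidth.
#
# D:  (m+1) x (m+1) predictor distance matrix (last row/column is the new
#     observation); Y: m x T matrix of known responses; yv: T x nY trial
#     values (one grid per time point). For each time point t and each trial
#     value y, the augmented smoother is affine in y: Yhat_i = A_i(t) +
#     w_i * y, so all trial values are scored with array operations; y is
#     accepted when the number of augmented scores strictly below S_{m+1}(y)
#     is at most ceiling((1-alpha)(m+1)) - 1, which is exactly the
#     lower-quantile inclusion rule.
band_for_h <- function(D, Y, yv, h, k, config) {
  m <- nrow(Y)
  Tn <- ncol(Y)
  Wn <- kernel_weights(D, h, config$kernel)
  w_new <- Wn[seq_len(m), m + 1]
  A <- Wn[seq_len(m), seq_len(m), drop = FALSE] %*% Y
  yhat_new <- drop(Wn[m + 1, seq_len(m), drop = FALSE] %*% Y)
  exact <- is.null(yv)
  acc <- if (exact) NULL else matrix(FALSE, Tn, ncol(yv))
  lo <- hi <- rep(NA_real_, Tn)
  for (tt in seq_len(Tn)) {
    r <- Y[, tt] - A[, tt]
    cnew <- yhat_new[tt]
    if (exact) {
      ends <- exact_hull_cpp(r, w_new, cnew, k)
      lo[tt] <- ends[1]
      hi[tt] <- ends[2]
    } else {
      yv_t <- yv[tt, ]
      S_known <- abs(r - tcrossprod(w_new, yv_t))
      S_new <- abs(yv_t - cnew)
      cnt <- colSums(S_known < rep(S_new, each = m))
      a <- cnt <= k - 1
      acc[tt, ] <- a
      if (any(a)) {
        # The continuous accept region extends beyond the outermost accepted
        # grid value by up to one grid step; half-step padding is the
        # unbiased estimate of its endpoints.
        half <- (yv_t[2] - yv_t[1]) / 2
        lo[tt] <- yv_t[which(a)[1]] - half
        hi[tt] <- yv_t[rev(which(a))[1]] + half
      }
    }
  }
  empty <- is.na(lo)
  list(h = h, lower = lo, upper = hi,
       lengths = ifelse(empty, 0, hi - lo), empty = empty,
       accepted = acc, point = yhat_new,
       resid = Y - A, w_new = w_new)
}

# Representative pseudo-targets for pilot tuning problems: indices at the
# quantiles of the predictor-norm order, a symmetric function of the sample.
representative_targets <- function(norms, m) {
  ord <- order(norms)
  unique(ord[round(seq(1, length(norms), length.out = min(m, length(norms))))])
}

# Average per-time-point PI lengths over pilot conformal problems built
# inside an index set that is independent of the conformalized scores:
# each pseudo-target in turn plays the new observation among the pilot
# functions. Returns an |H| x T matrix (empty pilot intervals contribute
# nothing; an all-empty cell becomes Inf so it is never selected).
pilot_band_lengths <- function(D_pilot, Y_pilot, pseudo, H, config) {
  a <- nrow(Y_pilot)
  Tn <- ncol(Y_pilot)
  k <- ceiling((1 - config$alpha) * a)
  cfg_pilot <- config
  cfg_pilot$trial_points <- config$pilot_trial_points
  L <- matrix(0, length(H), Tn)
  N <- matrix(0, length(H), Tn)
  for (j in pseudo) {
    idx <- c(setdiff(seq_len(a), j), j)
    Dj <- D_pilot[idx, idx]
    Yj <- Y_pilot[idx[seq_len(a - 1)], , drop = FALSE]
    yvj <- trial_values_for(Yj, cfg_pilot)
    for (s in seq_along(H)) {
      b <- band_for_h(Dj, Yj, yvj, H[s], k, cfg_pilot)
      keep <- !b$empty
      L[s, keep] <- L[s, keep] + b$lengths[keep]
      N[s, keep] <- N[s, keep] + 1
    }
  }
  out <- L / N
  out[N == 0] <- Inf
  out
}

# Assemble a prediction band from per-bandwidth bands. Selection lengths
# default to the bands' own lengths (uncorrected argmin); pilot-based tuning
# passes independently computed lengths instead.
conformal_band_engine <- function(D, Y, yv, grid, config, method, H,
                                  sel_lengths = NULL) {
  m <- nrow(Y)
  Tn <- ncol(Y)
  k <- ceiling((1 - config$alpha) * (m + 1))
  alpha <- config$alpha

  per_h <- lapply(H, function(h) band_for_h(D, Y, yv, h, k, config))

  if (is.null(sel_lengths)) {
    tuned <- tune_bandwidth(function(h) per_h[[match(h, H)]], H,
                            mode = config$tuning)
    pick <- tuned$pick
    h_star <- tuned$h_star
  } else {
    if (config$tuning == "global") {
      pick <- rep(which.min(rowMeans(sel_lengths)), Tn)
    } else {
      pick <- unname(apply(sel_lengths, 2, which.min))
    }
    h_star <- H[pick]
  }
  lower <- vapply(seq_len(Tn), function(tt) per_h[[pick[tt]]]$lower[tt],
                  numeric(1))
  upper <- vapply(seq_len(Tn), function(tt) per_h[[pick[tt]]]$upper[tt],
                  numeric(1))
  empty <- vapply(seq_len(Tn), function(tt) per_h[[pick[tt]]]$empty[tt],
                  logical(1))
  accepted <- if (is.null(yv)) NULL else do.call(rbind,
    lapply(seq_len(Tn), function(tt) per_h[[pick[tt]]]$accepted[tt, ]))
  point <- (lower + upper) / 2

  structure(list(
    grid = grid, lower = lower, upper = upper,
    lengths = ifelse(empty, 0, upper - lower), empty = empty,
    point = point, alpha = alpha, method = method,
    h_star = h_star, candidates = H,
    trial_values = yv, accepted = accepted, pick = pick, k = k,
    candidate_bands = lapply(per_h, function(b)
      b[c("h", "lower", "upper", "lengths", "empty", "resid", "w_new",
          "point")])),
    class = "prediction_band")
}

#' @export
print.prediction_band <- function(x, ...) {
  cat(sprintf(
    "<prediction_band> %s, alpha = %.3g, %d time points, mean length %.4g%s\n",
    toupper(x$method), x$alpha, length(x$grid), mean(x$lengths),
    if (any(x$empty)) sprintf(" (%d empty)", sum(x$empty)) else ""))
  invisible(x)
}

#' Full functional conformal prediction (FFCP)
#'
#' Pointwise conformal prediction bands for a new function observed only on a
#' sub-domain. Predictors are the restrictions of all functions to the
#' observed sub-domain; responses are the function values at each time point.
#' For every time point and trial response value the augmented data are
#' smoothed with the neighborhood estimator, absolute-residual nonconformity
#' scores are formed, and the trial value is kept when its score falls within
#' the lower (1 - alpha) conformal quantile. The predictor distance matrix is
#' computed once and reused across all time points and trial values.
#'
#' @param train List of complete [fsample]s on a common uniform grid.
#' @param new_partial [partial_obs] for the new function (carries the regime
#'   descriptor that is also applied to the training functions).
#' @param config An [fcp_config].
#' @return A `prediction_band` with per-time-point intervals, lengths, empty
#'   flags, the midpoint point prediction, selected bandwidth(s) and the raw
#'   accepted trial sets.
#' @export
ffcp <- function(train, new_partial, config = fcp_config()) {
  stopifnot(inherits(new_partial, "partial_obs"))
  fm <- fsample_matrix(train)
  validate_grid(fm$grid, uniform = TRUE)
  n <- length(train)
  Y <- t(fm$values)  # n x T
  xs <- c(lapply(train, restrict, regime = new_partial$regime),
          list(new_partial))
  D <- distance_matrix(xs, config$metric, k_max = config$k_max)

  H <- if (!is.null(config$bandwidth)) {
    sort(unique(config$bandwidth))
  } else {
    candidate_bandwidths(D, beta = config$beta_grid)
  }

  a <- ceiling(config$tuning_frac * n)
  use_pilot <- config$tuning_split && length(H) > 1 && a >= 4
  if (use_pilot) {
    # Index-random tuning subset: bandwidths are selected on conformal
    # problems among these functions only, so the selection is independent
    # of the scores that are conformalized on the remainder.
    idx_a <- sort(sample.int(n, a))
    idx_b <- setdiff(seq_len(n), idx_a)
    norms <- vapply(xs[idx_a], partial_obs_norm, numeric(1))
    pseudo <- representative_targets(norms, config$pilot_targets)
    sel <- pilot_band_lengths(D[idx_a, idx_a],
                              Y[idx_a, , drop = FALSE], pseudo, H, config)
    sys <- c(idx_b, n + 1)
    Yb <- Y[idx_b, , drop = FALSE]
    band <- conformal_band_engine(D[sys, sys], Yb,
                                  trial_values_for(Yb, config),
                                  fm$grid, config, method = "ffcp",
                                  H = H, sel_lengths = sel)
    band$tuning_subset <- idx_a
  } else {
    band <- conformal_band_engine(D, Y, trial_values_for(Y, config), fm$grid,
                                  config, method = "ffcp", H = H)
  }
  band
}

#' Split functional conformal prediction with registration (SFCP)
#'
#' Conformal prediction of the amplitude of a partially observed function.
#' The complete functions are split into a training and a calibration set;
#' the training set yields a Karcher mean template, every calibration
#' function is registered to it, and the registered amplitudes become the
#' responses while the predictors stay the unregistered restrictions to the
#' observed sub-domain. The FFCP engine is then run on the calibration system
#' over the entire domain (the observed sub-interval of the target does not
#' determine which warped time interval is missing, so the band covers all
#' time points). The band targets the amplitude of the new function, i.e. the
#' new function composed with its latent relative phase with respect to the
#' training template.
#'
#' @param functions List of n complete [fsample]s.
#' @param new_partial [partial_obs] for the new function.
#' @param split A [split_plan]; default a balanced split drawn from the
#'   current RNG state.
#' @param config An [fcp_config].
#' @param karcher_args Extra arguments passed to [karcher_mean].
#' @return A `prediction_band` (method `"sfcp"`) with the Karcher mean fit in
#'   `$karcher`, the split in `$split`, and a `karcher_converged` flag (on
#'   non-convergence the last iterate is used and the flag is `FALSE`).
#' @export
sfcp <- function(functions, new_partial, split = NULL,
                 config = fcp_config(), karcher_args = list()) {
  stopifnot(inherits(new_partial, "partial_obs"))
  n <- length(functions)
  if (is.null(split)) split <- split_plan(n)
  if (split$n != n) stop("split plan does not match the sample", call. = FALSE)
  fm <- fsample_matrix(functions)
  validate_grid(fm$grid, uniform = TRUE)

  km <- do.call(karcher_mean,
                c(list(fs = functions[split$train],
                       k_max = config$k_max), karcher_args))
  calib <- functions[split$calib]
  regs <- lapply(calib, function(f)
    pairwise_align(km$mean_function, f, k_max = config$k_max))
  Y <- do.call(rbind, lapply(regs, function(r) r$aligned$values))  # n2 x T

  xs <- c(lapply(calib, restrict, regime = new_partial$regime),
          list(new_partial))
  D <- distance_matrix(xs, config$metric, k_max = config$k_max)

  H <- if (!is.null(config$bandwidth)) {
    sort(unique(config$bandwidth))
  } else {
    candidate_bandwidths(D, beta = config$beta_grid)
  }

  sel <- NULL
  if (config$tuning_split && length(H) > 1 && split$n1 >= 4) {
    # Tune on the training half: pilot problems among the training
    # amplitudes are independent of the calibration set and the target, so
    # selection costs no calibration data and preserves exact validity.
    xs_train <- lapply(functions[split$train], restrict,
                       regime = new_partial$regime)
    D_train <- distance_matrix(xs_train, config$metric, k_max = config$k_max)
    Y_train <- do.call(rbind, lapply(km$aligned_functions, `[[`, "values"))
    norms <- vapply(xs_train, partial_obs_norm, numeric(1))
    pseudo <- representative_targets(norms, config$pilot_targets)
    sel <- pilot_band_lengths(D_train, Y_train, pseudo, H, config)
  }
  band <- conformal_band_engine(D, Y, trial_values_for(Y, config), fm$grid,
                                config, method = "sfcp", H = H,
                                sel_lengths = sel)
  band$karcher <- km
  band$karcher_converged <- km$converged
  band$split <- split
  band$calibration_phases <- lapply(regs, `[[`, "warping")
  band
}

# Membership of the true response in the conformal accept region itself (not
# its interval hull): the rank test evaluated at the observed truth. Used to
# compare hull-based and set-based coverage accounting.
region_membership <- function(band, truth) {
  Tn <- length(band$grid)
  vapply(seq_len(Tn), function(tt) {
    cb <- band$candidate_bands[[band$pick[tt]]]
    y <- truth$values[tt]
    S_known <- abs(cb$resid[, tt] - cb$w_new * y)
    S_new <- abs(y - cb$point[tt])
    sum(S_known < S_new) <= band$k - 1
  }, logical(1))
}
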