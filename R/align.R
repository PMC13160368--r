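#' Pairwise elastic registration by dynamic programming
#'
#' Finds the warping gamma* minimizing the L2 distance between the SRSF of
#' `f1` and the group-action-transformed SRSF of `f2`, so that `f2 o gamma*`
#' is registered to `f1`. The optimization is an exact dynamic program over
#' piecewise-linear monotone lattice paths on the sample grid with local
#' slopes restricted to \[1/k_max, k_max\]; ties between equal-cost paths
#' break toward the identity diagonal, so registering a function to itself
#' returns the identity warping exactly.
#'
#' @param f1 Template [fsample].
#' @param f2 [fsample] to be registered to `f1` (same uniform grid).
#' @param k_max Slope bound of the DP path set (default 7).
#' @return A list of class `registration` with elements `warping` (gamma*),
#'   `aligned` (`f2 o gamma*`), `amplitude_distance`
#'   (d2(q1, (q2 o gamma*) sqrt(gamma*'))) and `dp_value` (the DP objective).
#' @export
pairwise_align <- function(f1, f2, k_max = 7) {
  stopifnot(inherits(f1, "fsample"), inherits(f2, "fsample"))
  validate_grid(f1$grid, uniform = TRUE)
  if (length(f1$grid) != length(f2$grid) ||
      max(abs(f1$grid - f2$grid)) > 1e-10) {
    stop("functions must share a common grid", call. = FALSE)
  }
  q1 <- srsf_transform(f1)
  q2 <- srsf_transform(f2)
  if (max(abs(q1$values)) < 1e-10 || max(abs(q2$values)) < 1e-10) {
    warning("degenerate (constant) input; returning identity warping",
            call. = FALSE)
    gam <- identity_warping(f1$grid)
    return(structure(list(warping = gam, aligned = f2,
                          amplitude_distance = srsf_distance(q1, q2),
                          dp_value = srsf_distance(q1, q2)^2),
                     class = "registration"))
  }
  dp <- dp_align_srsf(q1$values, q2$values, nbhd = as.integer(k_max))
  gam <- as_strict_warping(f1$grid, dp$gamma)
  aligned <- warp_function(f2, gam)
  qa <- group_action_srsf(q2, gam)
  structure(list(warping = gam, aligned = aligned,
                 amplitude_distance = srsf_distance(q1, qa),
                 dp_value = dp$value),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("<registration> amplitude distance %.4g, max |gamma(t) - t| = %.4g\n",
              x$amplitude_distance, max(abs(x$warping$values - x$warping$grid))))
  invisible(x)
}

#' Amplitude distance between two functions
#'
#' d_a(f1, f2) = d2(q1, (q2 o gamma*) sqrt(gamma*')), the SRSF L2 distance
#' after optimal registration of `f2` to `f1`. Because the discretized
#' optimization is directional, the value is only approximately symmetric;
#' [distance_matrix] symmetrizes it when a symmetric matrix is required.
#'
#' @inheritParams pairwise_align
#' @return Nonnegative scalar.
#' @export
amplitude_distance <- function(f1, f2, k_max = 7) {
  pairwise_align(f1, f2, k_max = k_max)$amplitude_distance
}

#' Karcher mean of a sample of functions under the elastic metric
#'
#' Alternating minimization of the elastic sum-of-squares objective: register
#' every SRSF to the current template, update the template as the
#' cross-sectional mean of the aligned SRSFs, and stop when the relative
#' change of the objective falls below `tol`. The template is initialized at
#' the input SRSF closest in L2 to the cross-sectional SRSF mean
#' (deterministic, robust to outliers). After convergence the relative phases
#' are centered: the mean warping is composed out so the average relative
#' phase is approximately the identity, which makes the amplitude/phase
#' decomposition identifiable.
#'
#' @param fs List of [fsample]s on a common uniform grid (n >= 1).
#' @param max_iter Maximum number of alternating iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @param k_max DP slope bound passed to the aligner.
#' @return A list of class `karcher_mean` with `mean_srsf`, `mean_function`
#'   (origin = mean of the f_i(0)), `relative_phases`, `aligned_functions`,
#'   `n_iterations`, `converged` and the `objective` trace.
#' @export
karcher_mean <- function(fs, max_iter = 20, tol = 1e-3, k_max = 7) {
  if (!is.list(fs) || length(fs) == 0) {
    stop("need at least one function", call. = FALSE)
  }
  n <- length(fs)
  fm <- fsample_matrix(fs)
  grid <- fm$grid
  validate_grid(grid, uniform = TRUE)
  qs <- lapply(fs, srsf_transform)
  qmat <- vapply(qs, function(q) q$values, numeric(length(grid)))
  origin <- mean(vapply(fs, function(f) f$values[1], numeric(1)))

  if (n == 1) {
    return(structure(list(
      mean_srsf = qs[[1]], mean_function = fs[[1]],
      relative_phases = list(identity_warping(grid)),
      aligned_functions = fs, n_iterations = 0L, converged = TRUE,
      objective = 0), class = "karcher_mean"))
  }

  # Deterministic initialization: input SRSF closest to the pointwise mean.
  qbar0 <- rowMeans(qmat)
  d0 <- apply(qmat, 2, function(v) pracma::trapz(grid, (v - qbar0)^2))
  mu <- qmat[, which.min(d0)]

  gammas <- vector("list", n)
  aligned_q <- qmat
  obj_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  mu_srsf <- srsf(grid, mu, origin = origin)
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      dp <- dp_align_srsf(mu, qmat[, i], nbhd = as.integer(k_max))
      gammas[[i]] <- as_strict_warping(grid, dp$gamma)
      aligned_q[, i] <- group_action_srsf(qs[[i]], gammas[[i]])$values
    }
    obj <- sum(apply(aligned_q, 2,
                     function(v) pracma::trapz(grid, (v - mu)^2)))
    obj_trace <- c(obj_trace, obj)
    mu_new <- rowMeans(aligned_q)
    if (iter > 1) {
      prev <- obj_trace[iter - 1]
      if (abs(prev - obj) <= tol * max(prev, 1e-12)) {
        converged <- TRUE
        mu <- mu_new
        break
      }
    }
    mu <- mu_new
  }

  # Phase centering: compose out the cross-sectional mean warping.
  gmat <- vapply(gammas, function(g) g$values, numeric(length(grid)))
  gbar <- as_strict_warping(grid, rowMeans(gmat))
  gbar_inv <- invert_warping(gbar)
  gammas <- lapply(gammas, compose_warpings, g2 = gbar_inv)
  aligned_fns <- mapply(function(f, g) warp_function(f, g), fs, gammas,
                        SIMPLIFY = FALSE)
  aligned_q <- vapply(lapply(aligned_fns, srsf_transform),
                      function(q) q$values, numeric(length(grid)))
  mu_srsf <- srsf(grid, rowMeans(aligned_q), origin = origin)

  structure(list(
    mean_srsf = mu_srsf,
    mean_function = srsf_inverse(mu_srsf),
    relative_phases = gammas,
    aligned_functions = aligned_fns,
    n_iterations = iter,
    converged = converged,
    objective = obj_trace), class = "karcher_mean")
}

#' @export
print.karcher_mean <- function(x, ...) {
  cat(sprintf("<karcher_mean> n = %d, %d iterations, %s\n",
              length(x$relative_phases), x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
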