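#' Kernel functions for neighborhood smoothing
#'
#' Gaussian K(u) = exp(-u^2/2) (default throughout) and the triangular
#' kernel K(u) = max(1 - |u|, 0).
#'
#' @param name `"gaussian"` or `"triangular"`.
#' @return A vectorized kernel function.
#' @export
smoothing_kernel <- function(name = c("gaussian", "triangular")) {
  name <- match.arg(name)
  switch(name,
    gaussian = function(u) exp(-u^2 / 2),
    triangular = function(u) pmax(1 - abs(u), 0))
}

# Row-normalized leave-self-out kernel weight matrix from a distance matrix.
# Rows whose kernel weights all underflow fall back to uniform weights over
# the other rows (with a warning), keeping the smoother total and symmetric.
kernel_weights <- function(D, h, kernel = "gaussian") {
  K <- smoothing_kernel(kernel)
  W <- K(D / h)
  diag(W) <- 0
  denom <- rowSums(W)
  bad <- denom <= 0 | !is.finite(denom)
  if (any(bad)) {
    warning("kernel weights underflowed for some rows; using uniform weights",
            call. = FALSE)
    W[bad, ] <- 1
    diag(W) <- 0
    denom <- rowSums(W)
  }
  W / denom
}

#' Neighborhood-smoothing estimator
#'
#' Leave-self-out kernel-weighted average of the responses,
#' Yhat_i(t) = sum_\{i' != i\} K(d(X_i, X_i')/h) Y_i'(t) / sum K(...),
#' applied column-wise across all time points. The weights are row-stochastic;
#' rows with fully underflowed weights fall back to the unweighted mean of the
#' other rows with a warning.
#'
#' @param D Square symmetric distance matrix between the predictors.
#' @param Y Response matrix, one row per observation (columns are time
#'   points); row count must match `nrow(D)`.
#' @param h Positive bandwidth.
#' @param kernel Kernel name, see [smoothing_kernel].
#' @return Matrix of smoothed responses, same shape as `Y`.
#' @export
smooth_estimate <- function(D, Y, h, kernel = "gaussian") {
  Y <- as.matrix(Y)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square", call. = FALSE)
  if (nrow(Y) != nrow(D)) {
    stop("Y must have one row per distance-matrix row", call. = FALSE)
  }
  if (!is.numeric(h) || length(h) != 1 || h <= 0) {
    stop("h must be a positive scalar", call. = FALSE)
  }
  if (!all(is.finite(D))) stop("D must be finite", call. = FALSE)
  kernel_weights(D, h, kernel) %*% Y
}

#' Candidate bandwidths from the empirical distance distribution
#'
#' The `quantile` rule takes lower-beta quantiles of the strictly-upper-
#' triangle distances for a grid of beta values; the `fixed` rule passes a
#' user grid through unchanged. Nonpositive and duplicated candidates are
#' dropped.
#'
#' @param D Distance matrix.
#' @param rule `"quantile"` or `"fixed"`.
#' @param beta Quantile levels in (0, 1) for the `quantile` rule.
#' @param grid Bandwidth values for the `fixed` rule.
#' @return Sorted vector of positive candidate bandwidths.
#' @export
candidate_bandwidths <- function(D, rule = c("quantile", "fixed"),
                                 beta = seq(0.1, 0.9, by = 0.1), grid = NULL) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    H <- sort(unique(grid[grid > 0]))
    if (length(H) == 0) stop("no positive candidate bandwidths", call. = FALSE)
    return(H)
  }
  d <- D[upper.tri(D)]
  if (all(d <= 1e-14)) stop("all distances are zero", call. = FALSE)
  if (any(beta <= 0 | beta >= 1)) stop("beta must lie in (0, 1)", call. = FALSE)
  H <- unname(stats::quantile(d, probs = beta))
  H <- sort(unique(H[H > 0]))
  if (length(H) == 0) stop("no positive candidate bandwidths", call. = FALSE)
  H
}

#' Bandwidth selection by minimum prediction-interval length
#'
#' Runs a conformal routine once per candidate bandwidth and returns the
#' minimizer of interval length: globally (one h minimizing the time-averaged
#' length) or locally (one h per time point). Ties break toward the smallest
#' bandwidth. Time points whose interval is empty are excluded from the
#' argmin unless every candidate is empty there.
#'
#' @param runner Function taking a bandwidth and returning a list with a
#'   numeric `lengths` vector (and optionally `empty` flags).
#' @param H Candidate bandwidths (nonempty).
#' @param mode `"global"` or `"local"`.
#' @return List with `h_star` (scalar for global, vector per time point for
#'   local), the `bands` returned by the runner (for audit) and the index
#'   selection used.
#' @export
tune_bandwidth <- function(runner, H, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (length(H) == 0) stop("empty candidate set", call. = FALSE)
  H <- sort(H)
  bands <- lapply(H, runner)
  L <- do.call(rbind, lapply(bands, function(b) as.numeric(b$lengths)))
  E <- do.call(rbind, lapply(bands, function(b) {
    if (!is.null(b$empty)) as.logical(b$empty) else rep(FALSE, ncol(L))
  }))
  L_obj <- L
  L_obj[E] <- Inf
  all_empty <- apply(E, 2, all)
  L_obj[, all_empty] <- L[, all_empty]
  if (mode == "global") {
    avg <- rowMeans(L_obj)
    pick <- which.min(avg)  # which.min takes the first (smallest h) on ties
    list(h_star = H[pick], bands = bands, pick = rep(pick, ncol(L)))
  } else {
    pick <- unname(apply(L_obj, 2, which.min))
    list(h_star = H[pick], bands = bands, pick = pick)
  }
}
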