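#' Observation-regime descriptors for partial functional data
#'
#' A descriptor says which part of \[0, 1\] a new function is observed on:
#' an initial interval \[0, U\], a union of disjoint fragments with
#' neighborhood-smoothing weights, or a set of sparse time points.
#'
#' @param U Truncation time in (0, 1\].
#' @return An object of class `obs_regime`.
#' @export
interval_regime <- function(U) {
  if (!is.numeric(U) || length(U) != 1 || U <= 0 || U > 1) {
    stop("U must be a single value in (0, 1]", call. = FALSE)
  }
  structure(list(regime = "interval", U = U), class = "obs_regime")
}

#' @rdname interval_regime
#' @param fragments Matrix or list of disjoint, ordered intervals
#'   \[U_j1, U_j2\] within \[0, 1\] (rows of a 2-column matrix).
#' @param weights Fragment weights lambda_j summing to 1; default uniform.
#' @export
fragment_regime <- function(fragments, weights = NULL) {
  if (is.list(fragments)) fragments <- do.call(rbind, fragments)
  fragments <- as.matrix(fragments)
  if (ncol(fragments) != 2 || any(fragments[, 1] >= fragments[, 2]) ||
      any(fragments < 0) || any(fragments > 1)) {
    stop("fragments must be nonempty intervals within [0, 1]", call. = FALSE)
  }
  J <- nrow(fragments)
  if (J > 1 && any(fragments[-1, 1] <= fragments[-J, 2])) {
    stop("fragments must be disjoint and ordered", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1 / J, J)
  if (length(weights) != J || abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(regime = "fragmented", fragments = fragments,
                 weights = weights), class = "obs_regime")
}

#' @rdname interval_regime
#' @param points Ordered time points in \[0, 1\] at which the function is
#'   observed (sparse regime).
#' @export
sparse_regime <- function(points) {
  points <- sort(unique(as.numeric(points)))
  if (length(points) < 1 || any(points < 0) || any(points > 1)) {
    stop("sparse points must lie in [0, 1]", call. = FALSE)
  }
  structure(list(regime = "sparse", points = points), class = "obs_regime")
}

#' @export
print.obs_regime <- function(x, ...) {
  desc <- switch(x$regime,
    interval = sprintf("[0, %.3g]", x$U),
    fragmented = paste(apply(x$fragments, 1, function(r)
      sprintf("[%.3g, %.3g]", r[1], r[2])), collapse = " u "),
    sparse = sprintf("%d time points", length(x$points)))
  cat(sprintf("<obs_regime> %s: %s\n", x$regime, desc))
  invisible(x)
}

#' Restrict a function to an observed sub-domain
#'
#' Interval and fragmented regimes keep the grid points falling inside the
#' closed sub-intervals; the sparse regime interpolates the function linearly
#' at the listed time points.
#'
#' @param f An [fsample].
#' @param regime An [interval_regime], [fragment_regime] or [sparse_regime].
#' @return An object of class `partial_obs` carrying the regime, the retained
#'   time points and the restricted values (per fragment in the fragmented
#'   regime).
#' @export
restrict <- function(f, regime) {
  stopifnot(inherits(f, "fsample"), inherits(regime, "obs_regime"))
  eps <- 1e-10
  out <- switch(regime$regime,
    interval = {
      keep <- f$grid <= regime$U + eps
      if (!any(keep)) stop("empty observed set", call. = FALSE)
      list(times = f$grid[keep], values = f$values[keep])
    },
    fragmented = {
      parts <- apply(regime$fragments, 1, function(r) {
        keep <- f$grid >= r[1] - eps & f$grid <= r[2] + eps
        list(times = f$grid[keep], values = f$values[keep])
      })
      if (all(vapply(parts, function(p) length(p$times) == 0, logical(1)))) {
        stop("empty observed set", call. = FALSE)
      }
      list(parts = parts)
    },
    sparse = {
      list(times = regime$points,
           values = stats::approx(f$grid, f$values, xout = regime$points,
                                  rule = 2)$y)
    })
  structure(c(list(regime = regime), out), class = "partial_obs")
}

#' @export
print.partial_obs <- function(x, ...) {
  n_obs <- if (x$regime$regime == "fragmented") {
    sum(vapply(x$parts, function(p) length(p$times), integer(1)))
  } else length(x$times)
  cat(sprintf("<partial_obs> %s regime, %d observed values\n",
              x$regime$regime, n_obs))
  invisible(x)
}

# Euclidean norm of the observed values of a partial observation (any regime).
partial_obs_norm <- function(x) {
  if (x$regime$regime == "fragmented") {
    sqrt(sum(vapply(x$parts, function(p) sum(p$values^2), numeric(1))))
  } else {
    sqrt(sum(x$values^2))
  }
}

# Distance between two vectors sampled on a shared sub-grid, for one metric.
# fr/amplitude affinely rescale the sub-domain to [0, 1] first, since
# warpings are defined on the unit interval.
segment_distance <- function(times, v1, v2, metric, k_max = 7) {
  if (metric == "l2") {
    if (length(times) == 1) return(abs(v1 - v2))
    return(sqrt(pracma::trapz(times, (v1 - v2)^2)))
  }
  if (length(times) < 2) return(abs(v1 - v2))
  ts <- (times - times[1]) / (times[length(times)] - times[1])
  ts[1] <- 0
  ts[length(ts)] <- 1
  f1 <- fsample(ts, v1)
  f2 <- fsample(ts, v2)
  if (metric == "fr") {
    return(srsf_distance(srsf_transform(f1), srsf_transform(f2)))
  }
  if (metric == "amplitude") {
    d12 <- suppressWarnings(amplitude_distance(f1, f2, k_max = k_max))
    d21 <- suppressWarnings(amplitude_distance(f2, f1, k_max = k_max))
    return((d12 + d21) / 2)
  }
  stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
}

#' Distance between two partial observations
#'
#' Metrics on a shared observed sub-domain: `l2` (trapezoidal L2), `fr`
#' (SRSF L2, i.e. the Fisher-Rao distance) and `amplitude` (elastic distance
#' after registration, symmetrized). Fragmented observations combine
#' per-fragment distances with the regime weights lambda_j; sparse
#' observations always use the Euclidean distance on the value vectors.
#'
#' @param x1,x2 [partial_obs] objects sharing the same regime descriptor.
#' @param metric One of `"l2"`, `"fr"`, `"amplitude"`.
#' @param k_max DP slope bound for the amplitude metric.
#' @return Nonnegative scalar.
#' @export
partial_distance <- function(x1, x2, metric = c("l2", "fr", "amplitude"),
                             k_max = 7) {
  metric <- match.arg(metric)
  stopifnot(inherits(x1, "partial_obs"), inherits(x2, "partial_obs"))
  if (x1$regime$regime != x2$regime$regime) {
    stop("observations must share the same regime", call. = FALSE)
  }
  switch(x1$regime$regime,
    interval = {
      if (length(x1$times) != length(x2$times) ||
          max(abs(x1$times - x2$times)) > 1e-10) {
        stop("observations must share the same sub-domain", call. = FALSE)
      }
      segment_distance(x1$times, x1$values, x2$values, metric, k_max)
    },
    fragmented = {
      w <- x1$regime$weights
      d <- vapply(seq_along(w), function(j) {
        p1 <- x1$parts[[j]]
        p2 <- x2$parts[[j]]
        if (length(p1$times) == 0) return(0)
        segment_distance(p1$times, p1$values, p2$values, metric, k_max)
      }, numeric(1))
      sum(w * d)
    },
    sparse = {
      if (length(x1$times) != length(x2$times)) {
        stop("observations must share the same sample points", call. = FALSE)
      }
      sqrt(sum((x1$values - x2$values)^2))
    })
}

#' Pairwise distance matrix between partial observations
#'
#' Symmetric with zero diagonal. For the `l2`, `fr` and sparse cases the
#' matrix is assembled from inner products in one pass; the `amplitude`
#' metric performs a registration per (unordered) pair and is symmetrized by
#' construction in [partial_distance].
#'
#' @param xs List of [partial_obs] (length >= 2) sharing a descriptor.
#' @inheritParams partial_distance
#' @return A matrix with attribute `metric`.
#' @export
distance_matrix <- function(xs, metric = c("l2", "fr", "amplitude"),
                            k_max = 7) {
  metric <- match.arg(metric)
  n <- length(xs)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  regime <- xs[[1]]$regime$regime

  D <- NULL
  if (metric == "l2" && regime == "interval") {
    V <- vapply(xs, function(x) x$values, numeric(length(xs[[1]]$times)))
    D <- gram_l2_distances(xs[[1]]$times, V)
  } else if (metric == "fr" && regime == "interval") {
    times <- xs[[1]]$times
    ts <- (times - times[1]) / (times[length(times)] - times[1])
    ts[1] <- 0; ts[length(ts)] <- 1
    Q <- vapply(xs, function(x) srsf_transform(fsample(ts, x$values))$values,
                numeric(length(ts)))
    D <- gram_l2_distances(ts, Q)
  } else if (regime == "sparse") {
    V <- vapply(xs, function(x) x$values, numeric(length(xs[[1]]$times)))
    D <- as.matrix(stats::dist(t(V)))
    dimnames(D) <- NULL
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        D[i, j] <- D[j, i] <- partial_distance(xs[[i]], xs[[j]], metric,
                                               k_max = k_max)
      }
    }
  }
  attr(D, "metric") <- metric
  D
}

# Trapezoid-weighted pairwise L2 distances between the columns of V.
gram_l2_distances <- function(times, V) {
  m <- length(times)
  w <- numeric(m)
  if (m > 1) {
    dt <- diff(times)
    w[1] <- dt[1] / 2
    w[m] <- dt[m - 1] / 2
    if (m > 2) w[2:(m - 1)] <- (dt[-1] + dt[-(m - 1)]) / 2
  } else {
    w <- 1
  }
  G <- crossprod(V * sqrt(w))
  s <- diag(G)
  D2 <- outer(s, s, "+") - 2 * G
  D2[D2 < 0] <- 0
  sqrt(D2)
}
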