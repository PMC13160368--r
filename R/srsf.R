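#' SRSF transform
#'
#' Maps a function f to its square-root slope function
#' q(t) = sign(f'(t)) sqrt(|f'(t)|). The derivative is estimated by centered
#' finite differences with one-sided stencils at the boundary (the same scheme
#' used for warping derivatives, so the group action commutes with the
#' transform up to discretization error).
#'
#' @param f An [fsample].
#' @return An [srsf] with `origin = f(0)`.
#' @export
srsf_transform <- function(f) {
  stopifnot(inherits(f, "fsample"))
  fdot <- pracma::gradient(f$values, f$grid)
  srsf(f$grid, sign(fdot) * sqrt(abs(fdot)), origin = f$values[1])
}

#' Inverse SRSF transform
#'
#' Reconstructs f(t) = f(0) + int_0^t q(s)|q(s)| ds by cumulative trapezoidal
#' quadrature on the grid.
#'
#' @param q An [srsf].
#' @return An [fsample].
#' @export
srsf_inverse <- function(q) {
  stopifnot(inherits(q, "srsf"))
  qq <- q$values * abs(q$values)
  fsample(q$grid, q$origin + pracma::cumtrapz(q$grid, qq)[, 1])
}

#' Warp a function's domain
#'
#' Composition f(gamma(t)), evaluated by linear interpolation of f at the
#' warped abscissae; abscissae outside \[0, 1\] are clipped to the endpoints.
#'
#' @param f An [fsample].
#' @param gamma A [warping] on the same grid.
#' @return An [fsample] holding f(gamma(t_k)).
#' @export
warp_function <- function(f, gamma) {
  stopifnot(inherits(f, "fsample"))
  if (!inherits(gamma, "warping")) stop("invalid warping", call. = FALSE)
  at <- pmin(pmax(gamma$values, 0), 1)
  vals <- stats::approx(f$grid, f$values, xout = at, rule = 2)$y
  fsample(f$grid, vals)
}

#' Group action of a warping on an SRSF
#'
#' Returns (q o gamma) sqrt(gamma'), the SRSF-space counterpart of domain
#' warping. The action is an isometry of L2 up to discretization error.
#' gamma' uses the same finite-difference scheme as [srsf_transform].
#'
#' @param q An [srsf].
#' @param gamma A [warping].
#' @return An [srsf]; the origin is unchanged (gamma(0) = 0).
#' @export
group_action_srsf <- function(q, gamma) {
  stopifnot(inherits(q, "srsf"))
  if (!inherits(gamma, "warping")) stop("invalid warping", call. = FALSE)
  gdot <- pracma::gradient(gamma$values, gamma$grid)
  gdot <- pmax(gdot, 0)
  at <- pmin(pmax(gamma$values, 0), 1)
  qg <- stats::approx(q$grid, q$values, xout = at, rule = 2)$y
  srsf(q$grid, qg * sqrt(gdot), origin = q$origin)
}

#' Fisher-Rao distance between warping functions
#'
#' d_w(g1, g2) = arccos(<q1, q2>) where q = sqrt(gamma') is the SRSF of a
#' warping, a point on the unit Hilbert sphere. The derivative is treated as
#' piecewise constant on grid intervals (forward differences), under which the
#' inner product reduces to sum_j sqrt(dg1_j * dg2_j) and the formula is exact
#' for the discretized objects: d_w(g, g) = 0 identically and the output is
#' clipped to \[-1, 1\] before arccos so it is never NaN.
#'
#' @param g1,g2 [warping]s on a common grid.
#' @return Distance in \[0, pi/2\].
#' @export
warping_distance <- function(g1, g2) {
  if (!inherits(g1, "warping") || !inherits(g2, "warping")) {
    stop("invalid warping", call. = FALSE)
  }
  if (length(g1$grid) != length(g2$grid) ||
      max(abs(g1$grid - g2$grid)) > 1e-10) {
    stop("warpings must share a common grid", call. = FALSE)
  }
  warping_distance_num(g1$values, g2$values)
}

# Inner-product form on raw increasing vectors with endpoints 0 and 1; used
# directly by the phase-prediction engine where trial vectors are plain rows.
warping_distance_num <- function(v1, v2) {
  ip <- sum(sqrt(pmax(diff(v1), 0) * pmax(diff(v2), 0)))
  acos(min(max(ip, -1), 1))
}

#' L2 distance between two SRSFs (the Fisher-Rao distance between functions)
#'
#' @param q1,q2 [srsf]s on a common grid.
#' @return Nonnegative distance computed by trapezoidal quadrature.
#' @export
srsf_distance <- function(q1, q2) {
  stopifnot(inherits(q1, "srsf"), inherits(q2, "srsf"))
  sqrt(pracma::trapz(q1$grid, (q1$values - q2$values)^2))
}

# Repair interpolation-level ties so a numerically computed warping passes
# strict-monotonicity validation without visibly moving any value.
as_strict_warping <- function(grid, v) {
  v[1] <- 0
  v[length(v)] <- 1
  v <- cummax(v)
  if (any(diff(v) <= 0)) {
    v <- v + seq(0, 1e-9, length.out = length(v))
    v <- (v - v[1]) / (v[length(v)] - v[1])
  }
  warping(grid, v, slope_eps = 0)
}

# Numerical inverse of a warping: swap axes and re-interpolate onto the grid.
invert_warping <- function(gamma) {
  v <- stats::approx(gamma$values, gamma$grid, xout = gamma$grid, rule = 2)$y
  as_strict_warping(gamma$grid, v)
}

# Composition g1 o g2 evaluated on the grid: g1(g2(t)).
compose_warpings <- function(g1, g2) {
  v <- stats::approx(g1$grid, g1$values, xout = pmin(pmax(g2$values, 0), 1),
                     rule = 2)$y
  as_strict_warping(g1$grid, v)
}
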