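#' Uniform time grid on the unit interval
#'
#' @param n_points Number of grid points (>= 2).
#' @return Numeric vector of `n_points` equally spaced points from 0 to 1.
#' @export
time_grid <- function(n_points) {
  if (n_points < 2) stop("a time grid needs at least 2 points", call. = FALSE)
  seq(0, 1, length.out = n_points)
}

# Internal grid validator shared by all constructors. `uniform` enforces the
# equal-spacing requirement t_{k+1} - t_k = 1/(T-1) used by the conformal
# engines; the elastic core only needs monotonicity.
validate_grid <- function(grid, uniform = FALSE) {
  if (!is.numeric(grid) || length(grid) < 2 || anyNA(grid)) {
    stop("grid must be a numeric vector with at least 2 finite points",
         call. = FALSE)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (abs(grid[1]) > 1e-10 || abs(grid[length(grid)] - 1) > 1e-10) {
    stop("grid must start at 0 and end at 1", call. = FALSE)
  }
  if (uniform) {
    h <- 1 / (length(grid) - 1)
    if (max(abs(diff(grid) - h)) > 1e-8) {
      stop("grid must be uniformly spaced", call. = FALSE)
    }
  }
  invisible(grid)
}

#' Functional sample on a common grid
#'
#' A single real-valued function observed on a grid over \[0, 1\].
#'
#' @param grid Strictly increasing grid from 0 to 1.
#' @param values Function values at the grid points (finite).
#' @return An object of class `fsample` with elements `grid` and `values`.
#' @export
fsample <- function(grid, values) {
  validate_grid(grid)
  if (length(values) != length(grid)) {
    stop("values must have one entry per grid point", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  structure(list(grid = as.numeric(grid), values = as.numeric(values)),
            class = "fsample")
}

#' @export
print.fsample <- function(x, ...) {
  cat(sprintf("<fsample> %d grid points, range [%.4g, %.4g]\n",
              length(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' Warping function (boundary-preserving diffeomorphism of \[0, 1\])
#'
#' Discretized element of the warping group: gamma(0) = 0, gamma(1) = 1 and
#' strictly increasing. Monotonicity is checked on finite-difference slopes
#' with tolerance `slope_eps`.
#'
#' @param grid Time grid.
#' @param values Warping values at the grid points.
#' @param slope_eps Minimum admissible finite-difference slope.
#' @return An object of class `warping`.
#' @export
warping <- function(grid, values, slope_eps = 1e-8) {
  validate_grid(grid)
  if (length(values) != length(grid)) {
    stop("values must have one entry per grid point", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("warping values must be finite", call. = FALSE)
  if (abs(values[1]) > 1e-8 || abs(values[length(values)] - 1) > 1e-8) {
    stop("invalid warping: endpoints must be gamma(0) = 0, gamma(1) = 1",
         call. = FALSE)
  }
  slopes <- diff(values) / diff(grid)
  if (any(slopes <= slope_eps)) {
    stop("invalid warping: slopes must be strictly positive", call. = FALSE)
  }
  values[1] <- 0
  values[length(values)] <- 1
  structure(list(grid = as.numeric(grid), values = as.numeric(values)),
            class = "warping")
}

#' Identity warping on a grid
#' @param grid Time grid.
#' @return A `warping` with gamma(t) = t.
#' @export
identity_warping <- function(grid) warping(grid, grid)

#' @export
print.warping <- function(x, ...) {
  dev <- max(abs(x$values - x$grid))
  cat(sprintf("<warping> %d grid points, max |gamma(t) - t| = %.4g\n",
              length(x$grid), dev))
  invisible(x)
}

#' Square-root slope function (SRSF)
#'
#' Container for q = sign(f')sqrt(|f'|) together with the origin f(0) needed
#' to invert the representation.
#'
#' @param grid Time grid.
#' @param values SRSF values.
#' @param origin The source function's value at t = 0.
#' @return An object of class `srsf`.
#' @export
srsf <- function(grid, values, origin = 0) {
  validate_grid(grid)
  if (length(values) != length(grid)) {
    stop("values must have one entry per grid point", call. = FALSE)
  }
  if (!all(is.finite(values)) || !is.finite(origin)) {
    stop("SRSF values and origin must be finite", call. = FALSE)
  }
  structure(list(grid = as.numeric(grid), values = as.numeric(values),
                 origin = as.numeric(origin)),
            class = "srsf")
}

#' @export
print.srsf <- function(x, ...) {
  cat(sprintf("<srsf> %d grid points, L2 norm %.4g, origin %.4g\n",
              length(x$grid), sqrt(pracma::trapz(x$grid, x$values^2)), x$origin))
  invisible(x)
}

# Coerce a list of fsamples sharing one grid into a T x n value matrix.
fsample_matrix <- function(fs) {
  grid <- fs[[1]]$grid
  for (f in fs) {
    if (length(f$grid) != length(grid) || max(abs(f$grid - grid)) > 1e-10) {
      stop("all functions must share a common grid", call. = FALSE)
    }
  }
  list(grid = grid, values = vapply(fs, function(f) f$values, numeric(length(grid))))
}
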