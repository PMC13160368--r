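#' Simulation configuration for the two-peak study population
#'
#' Defaults reproduce the simulation population used throughout the package's
#' validation study: sums of two Gaussian bumps centered at 0.25 and 0.75
#' with width 0.07 and i.i.d. N(2, 0.1 I2) coefficients, optionally composed
#' with random Beta-CDF warpings whose shape parameters are i.i.d.
#' Uniform(1, 3).
#'
#' @param n Number of complete functions per replicate.
#' @param n_grid Number of grid points T.
#' @param phase_variation Compose the functions with random warpings?
#' @param peak_centers,peak_width Bump locations and common width.
#' @param coef_mean,coef_sd Mean and standard deviation of the bump
#'   coefficients (sd = sqrt(0.1) for covariance 0.1 I2).
#' @param shape_range Range of the Uniform law for the Beta shape parameters.
#' @param regime An `obs_regime` for the new function (default interval
#'   \[0, 0.5\]).
#' @param alpha Miscoverage level carried into evaluation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 100, n_grid = 100, phase_variation = FALSE,
                       peak_centers = c(0.25, 0.75), peak_width = 0.07,
                       coef_mean = 2, coef_sd = sqrt(0.1),
                       shape_range = c(1, 3),
                       regime = interval_regime(0.5), alpha = 0.1) {
  if (n < 2 || n_grid < 2) stop("need n >= 2 and n_grid >= 2", call. = FALSE)
  if (peak_width <= 0) stop("peak width must be positive", call. = FALSE)
  structure(list(n = n, n_grid = n_grid, phase_variation = phase_variation,
                 peak_centers = peak_centers, peak_width = peak_width,
                 coef_mean = coef_mean, coef_sd = coef_sd,
                 shape_range = shape_range, regime = regime, alpha = alpha),
            class = "sim_config")
}

#' Generate two-peak functions
#'
#' f_i(t) = Z_i1 exp(-(t - 0.25)^2 / 0.07^2) + Z_i2 exp(-(t - 0.75)^2 /
#' 0.07^2) with Z_i ~ N(2, 0.1 I2), sampled on a uniform grid. Coefficients
#' are drawn from the current RNG state, so a prior `set.seed()` makes the
#' output reproducible.
#'
#' @param config A [sim_config].
#' @param n Number of functions (default `config$n`).
#' @param Z Optional n x 2 matrix of fixed coefficients (bypasses sampling).
#' @return List of [fsample]s.
#' @export
generate_two_peak <- function(config = sim_config(), n = config$n, Z = NULL) {
  grid <- time_grid(config$n_grid)
  bumps <- vapply(config$peak_centers,
                  function(ctr) exp(-(grid - ctr)^2 / config$peak_width^2),
                  numeric(length(grid)))
  if (is.null(Z)) {
    Z <- matrix(stats::rnorm(n * length(config$peak_centers),
                             mean = config$coef_mean, sd = config$coef_sd),
                nrow = n)
  }
  lapply(seq_len(nrow(Z)), function(i)
    fsample(grid, drop(bumps %*% Z[i, ])))
}

#' Generate random Beta-CDF warpings
#'
#' gamma_i = F_\{a,b\}, the Beta(a, b) CDF evaluated on the grid, with a, b
#' i.i.d. Uniform(1, 3). Every output is a valid warping (Beta CDFs on (1,3)
#' shapes are strictly increasing with fixed endpoints); a = b = 1 gives the
#' identity.
#'
#' @param n Number of warpings.
#' @param grid Time grid.
#' @param shape_range Range of the uniform law for a and b.
#' @param shapes Optional n x 2 matrix of fixed (a, b) pairs.
#' @return List of [warping]s.
#' @export
generate_beta_warpings <- function(n, grid = time_grid(100),
                                   shape_range = c(1, 3), shapes = NULL) {
  if (is.null(shapes)) {
    shapes <- matrix(stats::runif(2 * n, shape_range[1], shape_range[2]),
                     ncol = 2)
  }
  lapply(seq_len(nrow(shapes)), function(i)
    warping(grid, stats::pbeta(grid, shapes[i, 1], shapes[i, 2])))
}

#' Apply phase variation to a sample of functions
#'
#' Composes each function with its warping, f_i o gamma_i.
#'
#' @param functions List of [fsample]s.
#' @param warpings List of [warping]s of equal length.
#' @return List of [fsample]s.
#' @export
apply_phase <- function(functions, warpings) {
  if (length(functions) != length(warpings)) {
    stop("need one warping per function", call. = FALSE)
  }
  mapply(warp_function, functions, warpings, SIMPLIFY = FALSE)
}

#' Observation-regime descriptors used in the simulation study
#'
#' Convenience constructor: a fixed or randomly drawn truncation interval
#' \[0, U\], the three-fragment layout \[0,0.2\] u \[0.4,0.6\] u \[0.8,1\]
#' with uniform weights, or the 11-point sparse design 0, 0.1, ..., 1. When
#' `U_law` is supplied, U is drawn from it using the current RNG state —
#' independent of any function generation, so the truncation time is
#' independent of the observation process by construction.
#'
#' @param type `"interval"`, `"fragmented"` or `"sparse"`.
#' @param U Fixed truncation point for the interval regime.
#' @param U_law Optional function(1) -> U drawing a random truncation point.
#' @return An `obs_regime`.
#' @export
make_observation_regime <- function(type = c("interval", "fragmented", "sparse"),
                                    U = 0.5, U_law = NULL) {
  type <- match.arg(type)
  switch(type,
    interval = {
      if (!is.null(U_law)) U <- U_law(1)
      interval_regime(U)
    },
    fragmented = fragment_regime(rbind(c(0, 0.2), c(0.4, 0.6), c(0.8, 1))),
    sparse = sparse_regime(seq(0, 1, by = 0.1)))
}

# Draw a full replicate: n + 1 i.i.d. functions (the last is the prediction
# target) plus the observation regime, using two independent seeded RNG
# streams so the truncation draw never depends on the function draw.
simulate_replicate <- function(config, fn_seed, regime_seed = NULL,
                               U_law = NULL) {
  set.seed(fn_seed)
  fns <- generate_two_peak(config, n = config$n + 1)
  if (config$phase_variation) {
    gams <- generate_beta_warpings(config$n + 1, grid = time_grid(config$n_grid),
                                  shape_range = config$shape_range)
    fns <- apply_phase(fns, gams)
  }
  regime <- config$regime
  if (!is.null(U_law)) {
    if (!is.null(regime_seed)) set.seed(regime_seed)
    regime <- interval_regime(U_law(1))
  }
  list(functions = fns[seq_len(config$n)], target = fns[[config$n + 1]],
       regime = regime)
}
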