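#' Evaluate a prediction band against a known target function
#'
#' @param band A `prediction_band`.
#' @param truth An [fsample] on the band's grid (for SFCP, the oracle
#'   amplitude of the target: the complete target registered to the training
#'   Karcher mean).
#' @return List with the pointwise containment indicators `inside`, the
#'   per-time-point `lengths`, and `all_inside` (1 when the whole function
#'   lies inside the band). Empty intervals never contain the truth.
#' @export
evaluate_band <- function(band, truth) {
  stopifnot(inherits(band, "prediction_band"), inherits(truth, "fsample"))
  if (length(truth$grid) != length(band$grid) ||
      max(abs(truth$grid - band$grid)) > 1e-10) {
    stop("band and truth must share a grid", call. = FALSE)
  }
  inside <- !band$empty & truth$values >= band$lower &
    truth$values <= band$upper
  inside[is.na(inside)] <- FALSE
  list(inside = inside, lengths = band$lengths,
       all_inside = as.integer(all(inside)))
}

#' Evaluate a phase prediction set against a known relative phase
#'
#' Joint containment is checked after snapping the truth's interior
#' coordinates to the nearest interior trial value (the accepted set is
#' finite while the truth is continuous); a snapped vector that collides on a
#' grid value, or an empty accepted set, counts as non-covered.
#'
#' @param pred A `phase_prediction_set`.
#' @param truth A [warping], or a numeric vector of the true relative phase
#'   already sampled on the coarse grid.
#' @return List with `covered` (0/1), the snapped vector, and the
#'   time-averaged envelope length.
#' @export
evaluate_phase_set <- function(pred, truth) {
  stopifnot(inherits(pred, "phase_prediction_set"))
  tv <- if (inherits(truth, "warping")) {
    stats::approx(truth$grid, truth$values, xout = pred$coarse_grid,
                  rule = 2)$y
  } else {
    as.numeric(truth)
  }
  Tc <- length(pred$coarse_grid)
  if (length(tv) != Tc) stop("truth must match the coarse grid", call. = FALSE)
  g <- pred$trials_per_point
  u <- seq_len(g) / (g + 1)
  snapped <- vapply(tv[-c(1, Tc)], function(v) u[which.min(abs(u - v))],
                    numeric(1))
  snapped_full <- c(0, snapped, 1)
  covered <- 0L
  if (!pred$empty && all(diff(snapped_full) > 0)) {
    dev <- apply(abs(sweep(pred$accepted_vectors, 2, snapped_full)), 1, max)
    covered <- as.integer(any(dev < 1e-9))
  }
  list(covered = covered, snapped = snapped_full,
       mean_length = mean(pred$envelope_lengths))
}

#' Monte Carlo coverage study
#'
#' Runs B independent replicates of a conformal method on freshly generated
#' two-peak data (new functions, new split and new target every replicate)
#' and aggregates pointwise and overall coverage and interval lengths. For
#' `"sfcp"` the truth is the oracle amplitude obtained by registering the
#' complete target to the training Karcher mean; for `"sfcpp"` it is the
#' corresponding oracle relative phase.
#'
#' @param method `"ffcp"`, `"sfcp"` or `"sfcpp"`.
#' @param config A [sim_config].
#' @param B Number of Monte Carlo replicates.
#' @param seed Master seed; all per-replicate seeds derive from it.
#' @param fcp An [fcp_config]; default matches the study (L2 distance,
#'   Gaussian kernel, local tuning for bands, global for phase).
#' @param coarse_grid,trials_per_point SFCPP settings.
#' @param karcher_args Extra arguments for [karcher_mean].
#' @return A list of class `mc_summary` with pointwise coverage `p_k`,
#'   pointwise lengths `ell_k`, time-averaged `p_bar` and `ell_bar`, overall
#'   coverage `p` with a normal-approximation 95% CI, and per-replicate
#'   records. Replicate-level failures are recorded and skipped.
#' @export
run_monte_carlo <- function(method = c("ffcp", "sfcp", "sfcpp"),
                            config = sim_config(), B = 100, seed = 1,
                            fcp = NULL, coarse_grid = c(0, 0.25, 0.5, 0.75, 1),
                            trials_per_point = 100, karcher_args = list()) {
  method <- match.arg(method)
  if (is.null(fcp)) {
    fcp <- fcp_config(alpha = config$alpha,
                      tuning = if (method == "sfcpp") "global" else "local")
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, 3 * B)
  fn_seeds <- rep_seeds[seq_len(B)]
  split_seeds <- rep_seeds[B + seq_len(B)]

  records <- vector("list", B)
  failures <- 0L
  for (b in seq_len(B)) {
    rec <- tryCatch({
      repdata <- simulate_replicate(config, fn_seed = fn_seeds[b])
      new_partial <- restrict(repdata$target, repdata$regime)
      if (method == "ffcp") {
        band <- ffcp(repdata$functions, new_partial, config = fcp)
        ev <- evaluate_band(band, repdata$target)
        c(ev, list(mean_length = mean(ev$lengths)))
      } else {
        split <- split_plan(config$n, seed = split_seeds[b])
        if (method == "sfcp") {
          band <- suppressWarnings(
            sfcp(repdata$functions, new_partial, split = split, config = fcp,
                 karcher_args = karcher_args))
          oracle <- pairwise_align(band$karcher$mean_function, repdata$target,
                                   k_max = fcp$k_max)
          ev <- evaluate_band(band, oracle$aligned)
          c(ev, list(mean_length = mean(ev$lengths)))
        } else {
          pred <- suppressWarnings(
            sfcpp(repdata$functions, new_partial, split = split,
                  coarse_grid = coarse_grid, config = fcp,
                  trials_per_point = trials_per_point,
                  karcher_args = karcher_args))
          oracle <- pairwise_align(pred$karcher$mean_function, repdata$target,
                                   k_max = fcp$k_max)
          ev <- evaluate_phase_set(pred, oracle$warping)
          list(inside = ev$covered, lengths = pred$envelope_lengths,
               all_inside = ev$covered, mean_length = ev$mean_length)
        }
      }
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- failures + 1L
      records[[b]] <- list(error = conditionMessage(rec))
    } else {
      records[[b]] <- rec
    }
  }

  ok <- !vapply(records, function(r) !is.null(r$error), logical(1))
  if (!any(ok)) stop("all replicates failed", call. = FALSE)
  inside <- do.call(rbind, lapply(records[ok], function(r) as.numeric(r$inside)))
  lens <- do.call(rbind, lapply(records[ok], function(r) as.numeric(r$lengths)))
  overall <- vapply(records[ok], function(r) r$all_inside, numeric(1))
  Bok <- sum(ok)

  p_k <- colMeans(inside)
  ell_k <- colMeans(lens)
  p <- mean(overall)
  se <- sqrt(p * (1 - p) / Bok)
  structure(list(
    method = method, B = Bok, failures = failures, alpha = config$alpha,
    p_k = p_k, ell_k = ell_k,
    p_bar = mean(p_k), ell_bar = mean(ell_k),
    p = p, p_se = se, p_ci = c(max(0, p - 1.96 * se), min(1, p + 1.96 * se)),
    p_k_ci = rbind(pmax(0, p_k - 1.96 * sqrt(p_k * (1 - p_k) / Bok)),
                   pmin(1, p_k + 1.96 * sqrt(p_k * (1 - p_k) / Bok))),
    mean_length = mean(vapply(records[ok], `[[`, numeric(1), "mean_length")),
    records = records, seed = seed,
    config = config), class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("<mc_summary> %s, B = %d (alpha = %.3g)\n", toupper(x$method),
              x$B, x$alpha))
  cat(sprintf("  overall coverage p = %.4f (95%% CI %.4f, %.4f)\n",
              x$p, x$p_ci[1], x$p_ci[2]))
  cat(sprintf("  time-averaged coverage p_bar = %.4f, PI length = %.4f\n",
              x$p_bar, x$ell_bar))
  if (x$failures > 0) cat(sprintf("  %d replicate(s) failed\n", x$failures))
  invisible(x)
}
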