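#' Smoothing weight from the device noise variance
#'
#' Published scaling relation between the observation-noise level and the
#' smoothing weight that brings the reconstruction closest to the (unknown)
#' true trajectory:
#' \deqn{\eta_b \approx 0.046\,\beta^3 + 0.054,}
#' where `beta` is the noise variance in m^2.  The relation was obtained
#' for high sampling rates; at coarse resolutions a simulation sweep
#' ([optimize_eta()]) is the safer route.
#'
#' Note a quirk of the published relation: it is described as scaling with
#' the noise's standard deviation cubed while its argument is defined as
#' the variance.  This function evaluates the formula exactly as printed,
#' with `beta` the variance, and does not attempt to resolve the
#' ambiguity; for the sub-m^2 variances typical of filtered GPS data the
#' two readings differ by less than the cubic term's contribution.
#'
#' @param beta Noise variance in m^2, `>= 0` (vectorized).
#' @return The smoothing weight(s) `0.046 * beta^3 + 0.054`.
#' @examples
#' eta_from_noise(0)    # 0.054, the intercept
#' eta_from_noise(0.4)  # 0.056944, for 0.4 m^2 GPS error variance
#' @export
eta_from_noise <- function(beta) {
  beta <- as.numeric(beta)
  if (anyNA(beta) || any(beta < 0)) {
    stop("`beta` must be >= 0", call. = FALSE)
  }
  0.046 * beta^3 + 0.054
}

#' Configuration of an eta sweep
#'
#' @param eta_grid Positive smoothing weights to evaluate.  The default is
#'   the broad 17-point sweep from 10 down to 1e-7 used for the tracking
#'   experiments.
#' @param n_replicates Number of noisy observation replicates generated by
#'   [optimize_eta()] per noise level (default 100).
#' @param refinement_rounds Number of grid-refinement rounds around the
#'   running argmin in [optimize_eta()].
#' @param refinement_span Initial half-width of the refined grid in
#'   decades (multiplicative; default 1 = one decade either side), halved
#'   each round.
#' @param refinement_points Number of log-spaced points per refined grid.
#' @param seed Integer seed driving replicate noise in [optimize_eta()].
#' @return An object of class `"eta_sweep_config"`.
#' @export
eta_sweep_config <- function(eta_grid = default_eta_grid(),
                             n_replicates = 100L,
                             refinement_rounds = 3L,
                             refinement_span = 1,
                             refinement_points = 9L,
                             seed = 1L) {
  eta_grid <- as.numeric(eta_grid)
  if (length(eta_grid) < 1L || any(!is.finite(eta_grid)) || any(eta_grid <= 0)) {
    stop("`eta_grid` entries must be positive and finite", call. = FALSE)
  }
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  structure(list(eta_grid = eta_grid,
                 n_replicates = as.integer(n_replicates),
                 refinement_rounds = as.integer(refinement_rounds),
                 refinement_span = as.numeric(refinement_span),
                 refinement_points = as.integer(refinement_points),
                 seed = as.integer(seed)),
            class = "eta_sweep_config")
}

#' The default broad eta grid
#'
#' Seventeen weights spanning 10 down to 1e-7, the grid used to tabulate
#' position and acceleration errors against time resolution.
#' @return Numeric vector of length 17, decreasing.
#' @export
default_eta_grid <- function() {
  c(10, 5, 1, 0.5, 0.1, 0.05, 0.01, 5e-3, 1e-3, 5e-4,
    1e-4, 5e-5, 1e-5, 5e-6, 1e-6, 5e-7, 1e-7)
}

#' Sweep the smoothing weight over a grid
#'
#' Runs [filter_track()] at each weight and records the RMS position (and,
#' when available, acceleration) error against a reference.  With
#' `reference = NULL` the observations themselves are the reference — the
#' mode used on real data, where truth is unknown; position error is then
#' the filter's misfit to the data and grows with `eta`.  With a
#' [phase_trajectory()] reference (simulated truth) the position error
#' typically has an interior minimum.
#'
#' @param obs An [observation_series()].
#' @param reference `NULL` (compare against `obs`), a [phase_trajectory()],
#'   or a list with elements `positions` and optionally `accelerations`
#'   (per-interval, `n x d`).
#' @param config An [eta_sweep_config()]; only `eta_grid` is used here.
#' @param filter_args Extra arguments passed to [filter_config()]
#'   (e.g. `solver`).
#' @return An object of class `"eta_sweep"`: list with `eta_values`,
#'   `e_position`, `e_acceleration` (NA where no reference accelerations
#'   exist), `best_eta` and `best_index` (minimal position error).
#' @export
sweep_eta <- function(obs, reference = NULL, config = eta_sweep_config(),
                      filter_args = list()) {
  stopifnot(inherits(obs, "observation_series"))
  ref <- resolve_reference(obs, reference)
  etas <- config$eta_grid
  e_pos <- e_acc <- rep(NA_real_, length(etas))
  for (k in seq_along(etas)) {
    cfg <- do.call(filter_config, c(list(eta = etas[k]), filter_args))
    traj <- tryCatch(filter_track(obs, cfg), error = function(e) NULL)
    if (is.null(traj)) {
      e_pos[k] <- Inf
      next
    }
    e_pos[k] <- rms_error(traj$positions, ref$positions)
    if (!is.null(ref$accelerations)) {
      e_acc[k] <- rms_error(traj$accelerations, ref$accelerations)
    }
  }
  best <- which.min(e_pos)
  structure(list(eta_values = etas, e_position = e_pos,
                 e_acceleration = e_acc,
                 best_eta = etas[best], best_index = best),
            class = "eta_sweep")
}

#' @export
print.eta_sweep <- function(x, ...) {
  cat(sprintf("<eta_sweep> %d weights; best eta = %g (E-position = %.4g)\n",
              length(x$eta_values), x$best_eta,
              x$e_position[x$best_index]))
  invisible(x)
}

#' @export
as.data.frame.eta_sweep <- function(x, ...) {
  data.frame(eta = x$eta_values, e_position = x$e_position,
             e_acceleration = x$e_acceleration)
}

resolve_reference <- function(obs, reference) {
  if (is.null(reference)) {
    list(positions = obs$values, accelerations = NULL)
  } else if (inherits(reference, "phase_trajectory")) {
    if (length(reference$times) != length(obs$times)) {
      stop("reference trajectory must be aligned with the observation times",
           call. = FALSE)
    }
    list(positions = reference$positions,
         accelerations = reference$accelerations)
  } else if (is.list(reference) && !is.null(reference$positions)) {
    list(positions = as_coord_matrix(reference$positions),
         accelerations = if (!is.null(reference$accelerations))
           as_coord_matrix(reference$accelerations))
  } else {
    stop("`reference` must be NULL, a phase_trajectory, or a list with $positions",
         call. = FALSE)
  }
}

#' Optimize the smoothing weight by replicated simulation
#'
#' The simulation-sweep route to the weight: from a known (simulated) true
#' trajectory, generate `n_replicates` noisy observation sets at noise
#' variance `beta`, average the RMS error between each weight's
#' reconstruction and the *true* positions over the replicates, then
#' repeatedly narrow a log-spaced grid around the running argmin.  This is
#' the procedure that underlies the [eta_from_noise()] scaling relation,
#' usable directly when the sampling rate or dynamics fall outside that
#' relation's regime.
#'
#' @param true_track A [phase_trajectory()] serving as ground truth.
#' @param beta Noise variance in m^2, `> 0`.
#' @param config An [eta_sweep_config()]; its `seed` makes the replicate
#'   noise reproducible.
#' @return A list with `best_eta` and `history`, a list of `"eta_sweep"`
#'   objects (the broad sweep followed by one per refinement round;
#'   `e_position` entries are replicate-averaged true-position errors, and
#'   `e_acceleration` replicate-averaged true-acceleration errors).
#'   Weights at which every replicate fails score `Inf` rather than
#'   aborting the sweep.
#' @export
optimize_eta <- function(true_track, beta, config = eta_sweep_config()) {
  stopifnot(inherits(true_track, "phase_trajectory"))
  beta <- as.numeric(beta)
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a single value > 0", call. = FALSE)
  }
  n1 <- length(true_track$times)
  d <- ncol(true_track$positions)
  R <- config$n_replicates
  noise <- local_seed(config$seed, {
    array(stats::rnorm(n1 * d * R, sd = sqrt(beta)), dim = c(n1, d, R))
  })
  replicate_obs <- lapply(seq_len(R), function(r) {
    observation_series(true_track$times,
                       true_track$positions + noise[, , r],
                       error_variances = beta)
  })
  evaluate_grid <- function(etas) {
    e_pos <- e_acc <- rep(NA_real_, length(etas))
    for (k in seq_along(etas)) {
      cfg <- filter_config(eta = etas[k])
      pos_err <- acc_err <- rep(NA_real_, R)
      for (r in seq_len(R)) {
        traj <- tryCatch(filter_track(replicate_obs[[r]], cfg),
                         error = function(e) NULL)
        if (is.null(traj)) next
        pos_err[r] <- rms_error(traj$positions, true_track$positions)
        acc_err[r] <- rms_error(traj$accelerations, true_track$accelerations)
      }
      e_pos[k] <- if (all(is.na(pos_err))) Inf else mean(pos_err, na.rm = TRUE)
      e_acc[k] <- if (all(is.na(acc_err))) Inf else mean(acc_err, na.rm = TRUE)
    }
    best <- which.min(e_pos)
    structure(list(eta_values = etas, e_position = e_pos,
                   e_acceleration = e_acc,
                   best_eta = etas[best], best_index = best),
              class = "eta_sweep")
  }
  history <- list(evaluate_grid(sort(config$eta_grid, decreasing = TRUE)))
  span <- config$refinement_span
  for (round in seq_len(config$refinement_rounds)) {
    centre <- history[[length(history)]]$best_eta
    grid <- 10^seq(log10(centre) - span, log10(centre) + span,
                   length.out = config$refinement_points)
    history[[length(history) + 1L]] <- evaluate_grid(grid)
    span <- span / 2
  }
  list(best_eta = history[[length(history)]]$best_eta, history = history)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
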