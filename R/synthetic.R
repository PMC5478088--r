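#' Specification of a synthetic tracking experiment
#'
#' Describes a Newtonian ground-truth track and the GPS-like observation
#' process applied to it.  Defaults emulate high-rate avian GPS telemetry:
#' 0.2 s fixes, 0.4 m^2 error variance per coordinate, about 36% of fixes
#' lost to device dropouts, and accelerations a few m/s^2 in magnitude
#' (flight accelerations rarely exceed +-8 m/s^2).
#'
#' @param duration Track duration in seconds.
#' @param dt Sampling step in seconds (default 0.2).
#' @param accel_model One of `"piecewise_constant"` (i.i.d. uniform
#'   per-interval accelerations), `"smooth_random"` (temporally correlated
#'   random accelerations, smoothed over about 2 s), `"circular"` (planar
#'   loop at constant speed, the free-flight pattern) or `"sinusoid"`
#'   (out-of-phase sinusoidal oscillation per coordinate).
#' @param accel_scale Acceleration scale in m/s^2 (default 8, matching the
#'   +-8 m/s^2 envelope of pigeon flight accelerations): the uniform
#'   half-width for `piecewise_constant`, the envelope for
#'   `smooth_random`, the centripetal magnitude for `circular`, the peak
#'   for `sinusoid`.
#' @param noise_variance Observation-noise variance in m^2 per coordinate
#'   (default 0.4).
#' @param missing_fraction Fraction of fixes marked as device dropouts,
#'   in `[0, 1)` (default 0.36).
#' @param dims Number of spatial coordinates, 1-3 (default 2: flight is
#'   essentially planar).
#' @param seed Integer seed; simulation and observation are deterministic
#'   given the spec.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(duration,
                           dt = 0.2,
                           accel_model = c("piecewise_constant",
                                           "smooth_random",
                                           "circular", "sinusoid"),
                           accel_scale = 8,
                           noise_variance = 0.4,
                           missing_fraction = 0.36,
                           dims = 2L,
                           seed = 1L) {
  accel_model <- match.arg(accel_model)
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be > 0 seconds", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0 seconds", call. = FALSE)
  if (duration < 2 * dt) stop("`duration` must cover at least two steps", call. = FALSE)
  if (accel_scale < 0) stop("`accel_scale` must be >= 0", call. = FALSE)
  if (noise_variance < 0) stop("`noise_variance` must be >= 0", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("`missing_fraction` must lie in [0, 1)", call. = FALSE)
  }
  dims <- as.integer(dims)
  if (dims < 1L || dims > 3L) stop("`dims` must be 1, 2 or 3", call. = FALSE)
  if (accel_model == "circular" && dims < 2L) {
    stop("the circular model needs at least 2 dimensions", call. = FALSE)
  }
  structure(list(duration = duration, dt = dt, accel_model = accel_model,
                 accel_scale = accel_scale, noise_variance = noise_variance,
                 missing_fraction = missing_fraction, dims = dims,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %s, %g s at dt = %g s, %dD; accel scale %g m/s^2, noise %g m^2, %g%% dropout, seed %d\n",
              x$accel_model, x$duration, x$dt, x$dims, x$accel_scale,
              x$noise_variance, 100 * x$missing_fraction, x$seed))
  invisible(x)
}

#' Simulate a Newtonian ground-truth track
#'
#' Generates a [phase_trajectory()] (Newton-consistent by construction:
#' every model produces per-interval accelerations and propagates them
#' with [newton_propagate()]) according to the spec's acceleration model.
#' The circular model rotates the velocity by a fixed angle per interval,
#' so the speed at sample times is exactly constant and each interval's
#' acceleration is orthogonal to the mean of its endpoint velocities.
#'
#' @param spec A [synthetic_spec()].
#' @return A [phase_trajectory()] with `spec$dims` coordinates starting
#'   from the origin.
#' @export
simulate_true_track <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- as.integer(floor(spec$duration / spec$dt))
  times <- spec$dt * (0:n)
  d <- spec$dims
  s <- spec$accel_scale
  local_seed(spec$seed, {
    switch(spec$accel_model,
      piecewise_constant = {
        a <- matrix(stats::runif(n * d, -s, s), n, d)
        newton_propagate(numeric(d), numeric(d), a, times)
      },
      smooth_random = {
        # white noise smoothed over ~2 s, rescaled to RMS s/2
        w <- max(1L, as.integer(round(2 / spec$dt)))
        raw <- matrix(stats::rnorm((n + w) * d), n + w, d)
        sm <- apply(raw, 2L, function(col) {
          as.numeric(stats::filter(col, rep(1 / w, w), sides = 1L))[(w + 1L):(n + w)]
        })
        sm <- matrix(sm, n, d)
        scale <- (s / 2) / max(stats::sd(as.numeric(sm)), .Machine$double.eps)
        newton_propagate(numeric(d), numeric(d), sm * scale, times)
      },
      circular = {
        speed <- 10                       # m/s, typical cruising flight
        omega <- s / speed                # centripetal a = v * omega
        v0 <- c(speed, numeric(d - 1L))
        v <- matrix(0, n + 1L, d)
        v[1L, ] <- v0
        for (i in seq_len(n)) {
          th <- omega * spec$dt
          rot <- v[i, 1:2] %*% matrix(c(cos(th), -sin(th),
                                        sin(th), cos(th)), 2L, 2L)
          v[i + 1L, 1:2] <- rot
        }
        a <- diff(v) / spec$dt
        newton_propagate(numeric(d), v0, a, times)
      },
      sinusoid = {
        omega <- 2 * pi / 10              # 10 s oscillation period
        A <- s / omega^2
        phase <- (seq_len(d) - 1L) * pi / 2
        vs <- sapply(phase, function(ph) A * omega * cos(omega * times + ph))
        vs <- matrix(vs, n + 1L, d)
        a <- diff(vs) / spec$dt
        p0 <- A * sin(phase)
        newton_propagate(p0, vs[1L, ], a, times)
      })
  })
}

#' Observe a true track through a GPS-like measurement process
#'
#' Adds i.i.d. Gaussian noise of variance `spec$noise_variance` per
#' coordinate to the true positions and marks a random subset of
#' `floor(missing_fraction * (n + 1))` samples as interpolated
#' (`valid_flags = FALSE`), emulating device dropouts.  Deterministic
#' given the spec: the observation stream is seeded with `spec$seed + 1`
#' so it is reproducible yet independent of the draw that built the true
#' track.
#'
#' @param truth A [phase_trajectory()].
#' @param spec A [synthetic_spec()].
#' @param drop_missing If `TRUE`, remove the dropped-out fixes entirely
#'   (irregular grid) instead of flagging them.
#' @return An [observation_series()]; `error_variances` are set to the
#'   noise variance (or 1 when it is zero).
#' @export
observe_track <- function(truth, spec, drop_missing = FALSE) {
  stopifnot(inherits(truth, "phase_trajectory"), inherits(spec, "synthetic_spec"))
  n1 <- length(truth$times)
  d <- ncol(truth$positions)
  obs <- local_seed(spec$seed + 1L, {
    noisy <- truth$positions +
      matrix(stats::rnorm(n1 * d, sd = sqrt(spec$noise_variance)), n1, d)
    flags <- rep(TRUE, n1)
    n_miss <- floor(spec$missing_fraction * n1)
    if (n_miss > 0L) flags[sample.int(n1, n_miss)] <- FALSE
    observation_series(truth$times, noisy,
                       error_variances = max(spec$noise_variance, 1e-12),
                       valid_flags = flags)
  })
  if (drop_missing) drop_invalid(obs) else obs
}

#' Decimate a series to a coarser time resolution
#'
#' Keeps every `factor`-th sample starting from the first, emulating a
#' slower logging rate (e.g. factor 5 turns 0.2 s fixes into 1 s fixes
#' and a 1,500-point window into 300 points).
#'
#' @param obs An [observation_series()].
#' @param factor Integer decimation factor `>= 1`.
#' @return The decimated [observation_series()].
#' @export
decimate <- function(obs, factor) {
  stopifnot(inherits(obs, "observation_series"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be an integer >= 1", call. = FALSE)
  }
  subset_series(obs, seq(1L, length(obs$times), by = factor))
}

#' Segment a speed series into flight intervals
#'
#' A fix belongs to a flight phase when its speed strictly exceeds the
#' threshold (default 4 m/s, the standard flight/non-flight criterion for
#' pigeon telemetry).  Returns maximal runs of consecutive flying
#' samples.  Speed should be the magnitude of the filtered velocity when
#' available, else of a finite-difference velocity.
#'
#' @param speeds Numeric vector of speed magnitudes in m/s, finite.
#' @param threshold Flight threshold in m/s (default 4; strict
#'   inequality).
#' @return A data.frame with integer columns `start` and `end`: 1-based
#'   inclusive indices of each maximal flying run (zero rows when the
#'   animal never exceeds the threshold).
#' @examples
#' segment_flight(c(0, 5, 6, 1, 7))   # runs 2..3 and 5..5
#' @export
segment_flight <- function(speeds, threshold = 4) {
  speeds <- as.numeric(speeds)
  if (anyNA(speeds) || any(!is.finite(speeds))) {
    stop("`speeds` must be finite", call. = FALSE)
  }
  flying <- speeds > threshold
  r <- rle(flying)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}
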