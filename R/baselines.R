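#' Centered sliding-average smoother
#'
#' The simplest sequential baseline: estimate each position as the mean of
#' the `window` observations centered on it,
#' \eqn{p_i = \frac1n \sum_{j=i-(n-1)/2}^{i+(n-1)/2} P_j}.
#' Requires a regular time grid (the shadowing filter has no such
#' restriction).  Edges where the window overhangs the series are dropped
#' — no padding, which would fabricate data — so the output is shorter
#' than the input by `window - 1` samples.
#'
#' @param obs An [observation_series()] on a regular grid (constant step
#'   to a relative tolerance of 1e-9).
#' @param window Odd positive window length, at most the series length.
#' @return A matrix of smoothed positions with attribute `"times"` (the
#'   retained sample times) and `"window"`.
#' @export
sliding_average <- function(obs, window) {
  stopifnot(inherits(obs, "observation_series"))
  dt <- diff(obs$times)
  if (length(dt) >= 2L && max(abs(dt - dt[1L])) > 1e-9 * abs(dt[1L])) {
    stop("sliding_average needs a regular time grid; for irregular or gappy data use shadow_filter/filter_track",
         call. = FALSE)
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  n1 <- length(obs$times)
  if (window > n1) stop("`window` exceeds the series length", call. = FALSE)
  h <- (window - 1L) %/% 2L
  keep <- if (h == 0L) seq_len(n1) else (h + 1L):(n1 - h)
  sm <- apply(obs$values, 2L, function(col) {
    as.numeric(stats::filter(col, rep(1 / window, window), sides = 2L))[keep]
  })
  sm <- matrix(sm, ncol = ncol(obs$values),
               dimnames = list(NULL, colnames(obs$values)))
  attr(sm, "times") <- obs$times[keep]
  attr(sm, "window") <- window
  sm
}

#' Forward-difference phase-space reconstruction
#'
#' The standard post-processing that sequential filters need to recover
#' velocity and acceleration from smoothed positions:
#' \eqn{v_i = (p_{i+1} - p_i)/\Delta t} and
#' \eqn{a_i = (v_{i+1} - v_i)/\Delta t}.  Differencing amplifies any
#' residual noise — for i.i.d. position noise of variance \eqn{\beta} the
#' double difference has variance \eqn{6\beta/\Delta t^4} — which is the
#' baseline's characteristic failure and the reason the batch filter
#' reconstructs the full state from the fit instead.
#'
#' @param positions Numeric vector or matrix of positions (>= 3 rows).
#' @param dt Positive sampling step in seconds.
#' @return A list with `velocities` (one row shorter than `positions`)
#'   and `accelerations` (two rows shorter).
#' @examples
#' finite_difference_phase(c(0, 1, 4), dt = 1)
#' @export
finite_difference_phase <- function(positions, dt) {
  p <- as_coord_matrix(positions)
  if (nrow(p) < 3L) stop("need at least 3 positions", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive step", call. = FALSE)
  }
  v <- diff(p) / dt
  a <- diff(v) / dt
  list(velocities = v, accelerations = a)
}

#' Sliding-average + finite-difference baseline
#'
#' Convenience wrapper chaining [sliding_average()] and
#' [finite_difference_phase()] — the classical pipeline the shadowing
#' filter is compared against.
#'
#' @param obs An [observation_series()] on a regular grid.
#' @param window Odd smoothing window (default 5).
#' @return An object of class `"baseline_result"`: list with `times`
#'   (times of the retained smoothed positions), `positions`,
#'   `velocities`, `accelerations` and `window`.  Velocities are one
#'   sample shorter than positions and accelerations two shorter, by the
#'   forward-difference truncation.
#' @export
baseline_filter <- function(obs, window = 5L) {
  sm <- sliding_average(obs, window)
  dt <- diff(attr(sm, "times"))[1L]
  fd <- finite_difference_phase(sm, dt)
  structure(list(times = attr(sm, "times"),
                 positions = sm,
                 velocities = fd$velocities,
                 accelerations = fd$accelerations,
                 window = attr(sm, "window")),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> window = %d; %d smoothed samples, %d coordinate(s)\n",
              x$window, nrow(x$positions), ncol(x$positions)))
  invisible(x)
}
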