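#' Newton-consistent phase-space trajectory
#'
#' A reconstructed trajectory holding positions p_i and velocities v_i at
#' the sample times and one constant acceleration a_i per inter-sample
#' interval `[t_i, t_{i+1})`.  The three series obey the discrete Newton
#' recursions
#' \deqn{p_{i+1} = p_i + v_i T_i + \tfrac12 a_i T_i^2, \qquad
#'       v_{i+1} = v_i + a_i T_i,}
#' with `T_i = t_{i+1} - t_i`; the constructor enforces them to an
#' absolute tolerance of `1e-9` times the position scale.
#'
#' @param times Numeric sample times in seconds, strictly increasing,
#'   length `n + 1`.
#' @param positions Matrix (or vector) of positions in meters, `n + 1` rows.
#' @param velocities Matrix (or vector) of velocities in m/s, `n + 1` rows.
#' @param accelerations Matrix (or vector) of per-interval accelerations in
#'   m/s^2, `n` rows.
#' @param check If `TRUE` (default) verify the Newton-consistency
#'   invariant.
#'
#' @return An object of class `"phase_trajectory"`.
#' @seealso [newton_propagate()] which builds one from an initial state and
#'   accelerations.
#' @export
phase_trajectory <- function(times, positions, velocities, accelerations,
                             check = TRUE) {
  times <- as.numeric(times)
  positions <- as_coord_matrix(positions)
  velocities <- as_coord_matrix(velocities)
  accelerations <- as_coord_matrix(accelerations)
  colnames(velocities) <- colnames(positions)
  colnames(accelerations) <- colnames(positions)
  n1 <- length(times)
  if (n1 < 2L || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with at least 2 samples",
         call. = FALSE)
  }
  if (nrow(positions) != n1 || nrow(velocities) != n1 ||
      nrow(accelerations) != n1 - 1L) {
    stop("positions/velocities need one row per sample and accelerations one row per interval",
         call. = FALSE)
  }
  obj <- structure(
    list(times = times, positions = positions, velocities = velocities,
         accelerations = accelerations),
    class = "phase_trajectory"
  )
  if (check) {
    dev <- newton_deviation(obj)
    tol <- 1e-9 * max(1, max(abs(positions)))
    if (dev > tol) {
      stop(sprintf("trajectory violates the Newton recursions (max deviation %.3g > tol %.3g)",
                   dev, tol), call. = FALSE)
    }
  }
  obj
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory> %d samples, %d coordinate(s) [%s]\n",
              length(x$times), ncol(x$positions),
              paste(colnames(x$positions), collapse = ", ")))
  cat(sprintf("  t in [%g, %g] s; |a| up to %g m/s^2\n",
              x$times[1L], x$times[length(x$times)],
              max(abs(x$accelerations))))
  invisible(x)
}

#' @export
n_coords.phase_trajectory <- function(x) ncol(x$positions)

#' Maximum deviation from the Newton recursions
#'
#' Largest absolute violation of `p_{i+1} = p_i + v_i T_i + a_i T_i^2 / 2`
#' and `v_{i+1} = v_i + a_i T_i` over all intervals and coordinates;
#' zero (up to floating point) for every trajectory the package returns.
#'
#' @param traj A `phase_trajectory`.
#' @return Non-negative scalar (meters / meters-per-second mixed units;
#'   used as a consistency diagnostic only).
#' @export
newton_deviation <- function(traj) {
  Ti <- diff(traj$times)
  p <- traj$positions
  v <- traj$velocities
  a <- traj$accelerations
  n <- length(Ti)
  dp <- p[-1L, , drop = FALSE] -
    (p[-(n + 1L), , drop = FALSE] + v[-(n + 1L), , drop = FALSE] * Ti +
       0.5 * a * Ti^2)
  dv <- v[-1L, , drop = FALSE] - (v[-(n + 1L), , drop = FALSE] + a * Ti)
  max(abs(dp), abs(dv))
}

#' Propagate an initial state under piecewise-constant accelerations
#'
#' Integrates the Newton recursions exactly: given the state at `times[1]`
#' and one constant acceleration per interval, returns the unique
#' trajectory they generate.  This closed-form propagation is the building
#' block of the shadowing filter's reduced formulation, where the unknowns
#' are `(p0, v0, a)` and positions are affine in them.
#'
#' @param p0 Initial position(s), length-`d` numeric.
#' @param v0 Initial velocity(ies), length-`d` numeric.
#' @param accelerations Per-interval accelerations, vector or `n x d`
#'   matrix.
#' @param times Strictly increasing sample times, length `n + 1`.
#' @return A [phase_trajectory()].
#' @examples
#' newton_propagate(0, 0, c(2, 2), times = c(0, 1, 2))$positions
#' @export
newton_propagate <- function(p0, v0, accelerations, times) {
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with at least 2 samples",
         call. = FALSE)
  }
  a <- as_coord_matrix(accelerations)
  n <- length(times) - 1L
  if (nrow(a) != n) {
    stop(sprintf("need one acceleration per interval: %d interval(s) but %d acceleration row(s)",
                 n, nrow(a)), call. = FALSE)
  }
  d <- ncol(a)
  p0 <- rep_len(as.numeric(p0), d)
  v0 <- rep_len(as.numeric(v0), d)
  Ti <- diff(times)
  # v_{i+1} = v0 + sum_{j <= i} a_j T_j
  v <- matrix(v0, nrow = n + 1L, ncol = d, byrow = TRUE)
  v[-1L, ] <- v[-1L, , drop = FALSE] + col_cumsum(a * Ti)
  # p_{i+1} = p_i + v_i T_i + a_i T_i^2 / 2
  step <- v[-(n + 1L), , drop = FALSE] * Ti + 0.5 * a * Ti^2
  p <- matrix(p0, nrow = n + 1L, ncol = d, byrow = TRUE)
  p[-1L, ] <- p[-1L, , drop = FALSE] + col_cumsum(step)
  colnames(p) <- colnames(a)
  phase_trajectory(times, p, v, a, check = FALSE)
}

# Column-wise cumulative sum that always returns a matrix.
col_cumsum <- function(m) {
  matrix(apply(m, 2L, cumsum), nrow = nrow(m), ncol = ncol(m))
}

#' Per-sample acceleration series of a trajectory
#'
#' Accelerations live on intervals; for plotting or sample-aligned
#' comparison each a_i is assigned to the interval's left endpoint `t_i`
#' and the final sample repeats the last interval's value.
#'
#' @param traj A `phase_trajectory`.
#' @return An `(n + 1) x d` matrix of accelerations aligned with
#'   `traj$times`.
#' @export
sample_accelerations <- function(traj) {
  a <- traj$accelerations
  rbind(a, a[nrow(a), , drop = FALSE], deparse.level = 0)
}
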