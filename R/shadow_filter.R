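#' Shadowing-filter configuration
#'
#' Bundles the smoothing weight and solver options for the
#' Newtonian-constrained least-squares filter.
#'
#' @param eta Non-negative smoothing weight on the acceleration-energy
#'   penalty \eqn{\sum_i T_i a_i^2}.  Large values force straight-line
#'   motion; small values interpolate the observations.
#' @param solver `"reduced"` (default) eliminates the Newton constraints
#'   and solves a weighted linear least-squares system for
#'   `(p0, v0, a_0, ..., a_{n-1})` by singular value decomposition with
#'   the minimum-norm convention; `"kkt"` solves the full stationarity
#'   system of the Lagrangian including the multipliers, and exists mainly
#'   as a cross-check.
#' @param svd_rcond Relative singular-value cutoff for rank truncation,
#'   in (0, 1).
#' @param xi_bound Optional hard bound \eqn{\xi} on the root-mean
#'   acceleration energy.  Recorded for documentation only and never
#'   enforced: the bound's term is constant in all derivatives once
#'   \eqn{\eta} is treated as a fixed weight, which is how the filter is
#'   used in practice (the weight is swept or chosen from the noise
#'   level).
#'
#' @return An object of class `"filter_config"`.
#' @export
filter_config <- function(eta, solver = c("reduced", "kkt"),
                          svd_rcond = 1e-12, xi_bound = NULL) {
  eta <- as.numeric(eta)
  if (length(eta) != 1L || !is.finite(eta) || eta < 0) {
    stop("`eta` must be a single finite value >= 0", call. = FALSE)
  }
  solver <- match.arg(solver)
  if (!is.numeric(svd_rcond) || svd_rcond <= 0 || svd_rcond >= 1) {
    stop("`svd_rcond` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(eta = eta, solver = solver, svd_rcond = svd_rcond,
                 xi_bound = xi_bound),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf("<filter_config> eta = %g, solver = %s, svd_rcond = %g\n",
              x$eta, x$solver, x$svd_rcond))
  invisible(x)
}

# Minimum-norm least-squares solve via SVD with relative rank truncation.
lstsq_svd <- function(A, b, rcond = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rcond * max(sv$d, .Machine$double.xmin)
  rank <- sum(keep)
  coef <- crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep]
  x <- sv$v[, keep, drop = FALSE] %*% coef
  list(x = drop(x), rank = rank, n_unknowns = ncol(A),
       singular_values = sv$d)
}

# Coefficients of the closed-form propagation: row k (0-based sample k),
# column j (0-based interval j) holds d p_k / d a_j =
# T_j^2/2 + T_j (t_k - t_{j+1}) for j < k, else 0.  First two columns of
# the full design are d p_k / d p0 = 1 and d p_k / d v0 = t_k - t_0.
propagation_design <- function(times) {
  n1 <- length(times)
  n <- n1 - 1L
  Ti <- diff(times)
  tau <- times - times[1L]
  C <- matrix(0, n1, n)
  if (n >= 1L) {
    tk <- matrix(times, n1, n)
    tj1 <- matrix(times[-1L], n1, n, byrow = TRUE)
    base <- matrix(0.5 * Ti^2, n1, n, byrow = TRUE) +
      matrix(Ti, n1, n, byrow = TRUE) * (tk - tj1)
    mask <- outer(seq_len(n1) - 1L, seq_len(n), ">=")
    C <- base * mask
  }
  cbind(1, tau, C, deparse.level = 0)
}

#' Shadowing filter for one coordinate
#'
#' Finds the Newton-consistent trajectory (piecewise-constant
#' acceleration) minimizing
#' \deqn{J = \tfrac12 \sum_i \sigma_i^{-2} (P_i - p_i)^2
#'       + \eta \sum_i T_i a_i^2}
#' over all trajectories satisfying the discrete Newton recursions.
#' The whole observation window is used at once — the filter is a batch
#' smoother, not a sequential one — so the reconstructed velocity and
#' acceleration come from the fit itself and need no post-hoc
#' differentiation.
#'
#' With `solver = "reduced"` the constraints are eliminated: the unknowns
#' are `(p0, v0, a_0, ..., a_{n-1})`, positions are affine in them via
#' [newton_propagate()]'s closed form, observation rows are weighted by
#' `1/sigma_i` and acceleration-penalty rows by `sqrt(2 eta T_i)` (so the
#' squared residual norm equals `2J`), and the system is solved by SVD
#' with the minimum-norm convention.  `solver = "kkt"` delegates to
#' [kkt_solve()].
#'
#' The problem has `n + 2` unknowns for `n + 1` observations: with
#' `eta = 0` (or severe rank deficiency) it is underdetermined, and the
#' minimum-norm solution is returned with the deficiency flagged in the
#' attached condition report rather than treated as an error.
#'
#' @param obs An [observation_series()] with exactly one coordinate, at
#'   least 2 samples.
#' @param config A [filter_config()].
#' @return A [phase_trajectory()] with attributes `eta`, `solver` and
#'   `condition_report` (a list with `rank`, `n_unknowns`,
#'   `rank_deficient` and the extreme singular values).
#' @examples
#' t <- seq(0, 2, by = 0.2)
#' obs <- observation_series(t, 3 + 2 * t)
#' fit <- shadow_filter(obs, filter_config(eta = 0.05))
#' range(fit$accelerations)  # affine data: essentially zero
#' @export
shadow_filter <- function(obs, config) {
  stopifnot(inherits(obs, "observation_series"), inherits(config, "filter_config"))
  if (ncol(obs$values) != 1L) {
    stop("`shadow_filter` handles one coordinate; use `filter_track` for several",
         call. = FALSE)
  }
  if (length(obs$times) < 2L) {
    stop("need at least 2 samples", call. = FALSE)
  }
  if (config$solver == "kkt") {
    return(kkt_solve(obs, config)$trajectory)
  }
  times <- obs$times
  n <- length(times) - 1L
  Ti <- diff(times)
  w <- 1 / sqrt(obs$error_variances)
  D <- propagation_design(times)
  A <- rbind(D * w,
             cbind(0, 0, diag(sqrt(2 * config$eta * Ti), n, n),
                   deparse.level = 0),
             deparse.level = 0)
  b <- c(obs$values[, 1L] * w, numeric(n))
  sol <- lstsq_svd(A, b, config$svd_rcond)
  u <- sol$x
  traj <- newton_propagate(u[1L], u[2L], u[-(1:2)], times)
  colnames(traj$positions) <- colnames(obs$values)
  colnames(traj$velocities) <- colnames(obs$values)
  colnames(traj$accelerations) <- colnames(obs$values)
  attr(traj, "eta") <- config$eta
  attr(traj, "solver") <- "reduced"
  attr(traj, "condition_report") <- list(
    rank = sol$rank, n_unknowns = sol$n_unknowns,
    rank_deficient = sol$rank < sol$n_unknowns,
    sigma_max = max(sol$singular_values),
    sigma_min = min(sol$singular_values))
  traj
}

#' Apply the shadowing filter to a multi-coordinate track
#'
#' The filter treats a d-dimensional tracking problem as d independent
#' scalar problems sharing the time grid, so each coordinate's result is
#' identical to a scalar [shadow_filter()] call on that coordinate.
#'
#' @param obs An [observation_series()] with `d >= 1` coordinates.
#' @param config A [filter_config()].
#' @return A [phase_trajectory()] with `d` coordinates, carrying the same
#'   attributes as [shadow_filter()] (`condition_report` from the first
#'   coordinate; the grid, weights and penalty are shared so conditioning
#'   is identical across coordinates).
#' @export
filter_track <- function(obs, config) {
  stopifnot(inherits(obs, "observation_series"))
  d <- ncol(obs$values)
  per <- lapply(seq_len(d), function(k) {
    shadow_filter(
      observation_series(obs$times, obs$values[, k, drop = FALSE],
                         obs$error_variances, obs$valid_flags),
      config)
  })
  traj <- phase_trajectory(
    obs$times,
    do.call(cbind, lapply(per, function(tr) tr$positions)),
    do.call(cbind, lapply(per, function(tr) tr$velocities)),
    do.call(cbind, lapply(per, function(tr) tr$accelerations)),
    check = FALSE)
  colnames(traj$positions) <- colnames(obs$values)
  colnames(traj$velocities) <- colnames(obs$values)
  colnames(traj$accelerations) <- colnames(obs$values)
  attr(traj, "eta") <- config$eta
  attr(traj, "solver") <- config$solver
  attr(traj, "condition_report") <- attr(per[[1L]], "condition_report")
  traj
}

#' Solve the full stationarity (KKT) system
#'
#' Instead of eliminating the Newton constraints, this solver keeps the
#' positions, velocities, accelerations and the two families of Lagrange
#' multipliers as unknowns and zeroes every partial derivative of the
#' Lagrangian
#' \deqn{L = \tfrac12 \sum \sigma_i^{-2}(P_i - p_i)^2
#'   + \sum \lambda_{i+1}(p_{i+1} - p_i - \tfrac12 a_i T_i^2 - v_i T_i)
#'   + \sum \mu_{i+1}(v_{i+1} - v_i - a_i T_i)
#'   + \eta \sum T_i a_i^2.}
#' The stationarity equations are, for each sample i (indicator terms
#' vanish outside their index range):
#' \itemize{
#'   \item d/dp_i: \eqn{\sigma_i^{-2}(p_i - P_i) + \lambda_i - \lambda_{i+1} = 0}
#'   \item d/dv_i: \eqn{-T_i \lambda_{i+1} + \mu_i - \mu_{i+1} = 0}
#'   \item d/da_i: \eqn{2\eta T_i a_i - \tfrac12 T_i^2 \lambda_{i+1} - T_i \mu_{i+1} = 0}
#' }
#' together with the Newton constraints themselves.  This square linear
#' system of dimension `5n + 2` is solved by SVD; agreement of its
#' trajectory with the reduced solver is a strong internal consistency
#' check, since the two derivations share no algebra.
#'
#' @param obs An [observation_series()] with one coordinate.
#' @param config A [filter_config()]; `eta` should be positive (with
#'   `eta = 0` the acceleration stationarity rows lose their diagonal and
#'   the system is singular).
#' @return A list with `trajectory` (a [phase_trajectory()]) and
#'   `diagnostics`: `lambda_multipliers`, `mu_multipliers` (length n) and
#'   `stationarity_residual_max`, the largest absolute residual of the
#'   full system at the returned solution.
#' @export
kkt_solve <- function(obs, config) {
  stopifnot(inherits(obs, "observation_series"), inherits(config, "filter_config"))
  if (ncol(obs$values) != 1L) {
    stop("`kkt_solve` handles one coordinate", call. = FALSE)
  }
  times <- obs$times
  n <- length(times) - 1L
  if (n < 1L) stop("need at least 2 samples", call. = FALSE)
  Ti <- diff(times)
  eta <- config$eta
  P <- obs$values[, 1L]
  isig2 <- 1 / obs$error_variances
  # unknown order: p_0..p_n | v_0..v_n | a_0..a_{n-1} | lambda_1..n | mu_1..n
  ip <- seq_len(n + 1L)
  iv <- n + 1L + seq_len(n + 1L)
  ia <- 2L * (n + 1L) + seq_len(n)
  il <- 2L * (n + 1L) + n + seq_len(n)
  im <- 2L * (n + 1L) + 2L * n + seq_len(n)
  m <- 5L * n + 2L
  A <- matrix(0, m, m)
  b <- numeric(m)
  row <- 0L
  for (i in 0:n) {            # d/dp_i
    row <- row + 1L
    A[row, ip[i + 1L]] <- isig2[i + 1L]
    if (i >= 1L) A[row, il[i]] <- 1
    if (i <= n - 1L) A[row, il[i + 1L]] <- -1
    b[row] <- isig2[i + 1L] * P[i + 1L]
  }
  for (i in 0:n) {            # d/dv_i
    row <- row + 1L
    if (i <= n - 1L) A[row, il[i + 1L]] <- -Ti[i + 1L]
    if (i >= 1L) A[row, im[i]] <- 1
    if (i <= n - 1L) A[row, im[i + 1L]] <- -1
  }
  for (i in 0:(n - 1L)) {     # d/da_i
    row <- row + 1L
    A[row, ia[i + 1L]] <- 2 * eta * Ti[i + 1L]
    A[row, il[i + 1L]] <- -0.5 * Ti[i + 1L]^2
    A[row, im[i + 1L]] <- -Ti[i + 1L]
  }
  for (i in 0:(n - 1L)) {     # position constraint i
    row <- row + 1L
    A[row, ip[i + 2L]] <- 1
    A[row, ip[i + 1L]] <- -1
    A[row, ia[i + 1L]] <- -0.5 * Ti[i + 1L]^2
    A[row, iv[i + 1L]] <- -Ti[i + 1L]
  }
  for (i in 0:(n - 1L)) {     # velocity constraint i
    row <- row + 1L
    A[row, iv[i + 2L]] <- 1
    A[row, iv[i + 1L]] <- -1
    A[row, ia[i + 1L]] <- -Ti[i + 1L]
  }
  sol <- lstsq_svd(A, b, config$svd_rcond)
  if (sol$rank < m) {
    stop(structure(
      class = c("shadowtrack_degenerate_error", "error", "condition"),
      list(message = sprintf(
        "stationarity system is singular beyond svd_rcond (rank deficit %d of %d); increase eta or provide more samples",
        m - sol$rank, m),
        call = sys.call(-1L), rank_deficit = m - sol$rank)))
  }
  x <- sol$x
  # re-propagate from (p0, v0, a) so the Newton invariant holds exactly
  traj <- newton_propagate(x[ip[1L]], x[iv[1L]], x[ia], times)
  colnames(traj$positions) <- colnames(obs$values)
  colnames(traj$velocities) <- colnames(obs$values)
  colnames(traj$accelerations) <- colnames(obs$values)
  attr(traj, "eta") <- eta
  attr(traj, "solver") <- "kkt"
  diag_ <- list(lambda_multipliers = x[il], mu_multipliers = x[im],
                stationarity_residual_max = max(abs(A %*% x - b)))
  list(trajectory = traj, diagnostics = diag_)
}

#' Decompose the filter objective at a trajectory
#'
#' Evaluates the data-misfit and acceleration-penalty parts of the
#' shadowing-filter objective for a given Newton-consistent trajectory,
#' summing over all coordinates present.
#'
#' @param obs An [observation_series()].
#' @param traj A [phase_trajectory()] on the same time grid.
#' @param eta Non-negative smoothing weight.
#' @return A list with `misfit` \eqn{= \tfrac12\sum_i \sigma_i^{-2}
#'   \|P_i - p_i\|^2}, `penalty` \eqn{= \sum_i T_i \|a_i\|^2} and
#'   `total = misfit + eta * penalty`.
#' @export
objective_value <- function(obs, traj, eta) {
  stopifnot(inherits(obs, "observation_series"), inherits(traj, "phase_trajectory"))
  if (length(obs$times) != length(traj$times) ||
      ncol(obs$values) != ncol(traj$positions)) {
    stop("observation series and trajectory must share grid and coordinates",
         call. = FALSE)
  }
  res2 <- rowSums((obs$values - traj$positions)^2)
  misfit <- 0.5 * sum(res2 / obs$error_variances)
  Ti <- diff(obs$times)
  penalty <- sum(Ti * rowSums(traj$accelerations^2))
  list(total = misfit + eta * penalty, misfit = misfit, penalty = penalty)
}

#' Root-mean-square trajectory error
#'
#' \deqn{E = \sqrt{\frac1S \sum_{i=1}^{S} \|r_i - e_i\|^2}}
#' where the squared norm sums over however many coordinates are present
#' and `S` is the number of samples.  Used both against observations (how
#' closely the filter shadows the data) and against simulated truth.
#'
#' @param estimate,reference Numeric vectors or matrices of equal shape.
#' @return Non-negative scalar in the units of the inputs.
#' @examples
#' rms_error(c(0, 0, 0), c(3, 4, 0) * 0)        # 0
#' rms_error(matrix(0, 1, 3), matrix(c(3, 4, 0), 1)) # 5
#' @export
rms_error <- function(estimate, reference) {
  e <- as_coord_matrix(estimate)
  r <- as_coord_matrix(reference)
  if (!all(dim(e) == dim(r))) {
    stop("`estimate` and `reference` must have the same shape", call. = FALSE)
  }
  if (nrow(e) < 1L) stop("need at least one sample", call. = FALSE)
  sqrt(mean(rowSums((r - e)^2)))
}
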