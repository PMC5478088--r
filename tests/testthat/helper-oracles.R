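# Independent oracles and fixture builders shared across tests.

# Generic dense equality-constrained quadratic program:
#   min 1/2 x' H x - g' x   s.t.  C x = d
# solved through the saddle-point (bordered) system.  Used as an
# implementation-independent oracle for the filter: it knows nothing about
# the reduced design-matrix construction or the hand-derived stationarity
# equations.
solve_eq_qp <- function(H, g, C, d) {
  m <- nrow(C)
  K <- rbind(cbind(H, t(C)), cbind(C, matrix(0, m, m)))
  sol <- solve(K, c(g, d))
  list(x = sol[seq_len(ncol(H))], multipliers = sol[-seq_len(ncol(H))])
}

# Build the filter objective and Newton constraints explicitly in the full
# variable vector (p_0..p_n, v_0..v_n, a_0..a_{n-1}) and solve with the QP
# oracle.  Returns positions/velocities/accelerations.
qp_oracle_filter <- function(obs, eta) {
  times <- obs$times
  n <- length(times) - 1L
  Ti <- diff(times)
  P <- obs$values[, 1L]
  isig2 <- 1 / obs$error_variances
  nv <- 3L * n + 2L  # p: n+1, v: n+1, a: n
  ip <- seq_len(n + 1L)
  iv <- n + 1L + seq_len(n + 1L)
  ia <- 2L * (n + 1L) + seq_len(n)
  H <- matrix(0, nv, nv)
  diag(H)[ip] <- isig2
  diag(H)[ia] <- 2 * eta * Ti
  g <- numeric(nv)
  g[ip] <- isig2 * P
  C <- matrix(0, 2L * n, nv)
  d <- numeric(2L * n)
  for (i in seq_len(n)) {
    C[i, ip[i + 1L]] <- 1; C[i, ip[i]] <- -1
    C[i, iv[i]] <- -Ti[i]; C[i, ia[i]] <- -0.5 * Ti[i]^2
    C[n + i, iv[i + 1L]] <- 1; C[n + i, iv[i]] <- -1
    C[n + i, ia[i]] <- -Ti[i]
  }
  sol <- solve_eq_qp(H, g, C, d)
  list(positions = sol$x[ip], velocities = sol$x[iv],
       accelerations = sol$x[ia])
}

# Random scalar observation instance on an irregular grid.
random_instance <- function(n_samples, seed) {
  set.seed(seed)
  times <- cumsum(runif(n_samples, 0.1, 0.6))
  observation_series(times, stats::rnorm(n_samples, sd = 3),
                     error_variances = runif(n_samples, 0.5, 2))
}

# Finite-difference gradient of a scalar function.
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1L))
}

# The filter objective J as a function of the reduced unknowns (p0, v0, a).
reduced_objective <- function(u, obs, eta) {
  traj <- newton_propagate(u[1L], u[2L], u[-(1:2)], obs$times)
  objective_value(obs, traj, eta)$total
}
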