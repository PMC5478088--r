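test_that("unpenalized affine motion is fitted exactly", {
  t <- seq(0, 2, by = 0.2)
  obs <- observation_series(t, 3 + 2 * t, error_variances = runif(11, 0.5, 2))
  fit <- shadow_filter(obs, filter_config(eta = 0.05))
  expect_equal(drop(fit$positions), 3 + 2 * t, tolerance = 1e-9)
  expect_equal(drop(fit$velocities), rep(2, 11), tolerance = 1e-9)
  expect_lt(max(abs(fit$accelerations)), 1e-9)
})

test_that("noiseless Newtonian tracks are recovered up to the alternating gauge mode", {
  # Positions identify the trajectory only up to a one-dimensional gauge:
  # a mode with zero position at every sample (velocity flipping sign each
  # interval, a_i = -2 v_i / T_i) is invisible to the data, and the
  # penalty fixes its amplitude.  Positions recover as eta -> 0; the
  # velocity/acceleration error converges to exactly that gauge mode.
  set.seed(42)
  times <- seq(0, by = 0.2, length.out = 80)
  n <- 79
  truth <- newton_propagate(0, 0, runif(n, -2, 2), times)
  obs <- observation_series(times, truth$positions)
  fit <- shadow_filter(obs, filter_config(eta = 1e-12))
  expect_lt(rms_error(fit$positions, truth$positions), 1e-6)
  # gauge mode: w_v alternates +-1, w_a = -2 w_v / T
  Ti <- diff(times)
  w_a <- -2 * (-1)^(0:(n - 1)) / Ti
  a_err <- fit$accelerations[, 1L] - truth$accelerations[, 1L]
  c_star <- -sum(Ti * truth$accelerations[, 1L] * w_a) / sum(Ti * w_a^2)
  expect_lt(max(abs(a_err - c_star * w_a)), 1e-5)
  # removing the gauge component leaves near-exact recovery
  resid <- a_err - sum(a_err * w_a) / sum(w_a^2) * w_a
  expect_lt(sqrt(mean(resid^2)), 1e-5)
})

test_that("reduced solver, KKT solver and the dense QP oracle agree", {
  for (seed in c(1, 7, 23, 101)) {
    obs <- random_instance(sample(4:20, 1L), seed = seed)
    eta <- 10^runif(1, -3, 0.5)
    red <- shadow_filter(obs, filter_config(eta))
    kkt <- kkt_solve(obs, filter_config(eta))
    qp <- qp_oracle_filter(obs, eta)
    scale <- max(abs(qp$positions))
    expect_equal(drop(red$positions), qp$positions, tolerance = 1e-8 * scale)
    expect_equal(drop(kkt$trajectory$positions), qp$positions,
                 tolerance = 1e-8 * scale)
    expect_equal(drop(red$velocities), qp$velocities,
                 tolerance = 1e-8 * max(abs(qp$velocities)))
    expect_equal(drop(red$accelerations), qp$accelerations,
                 tolerance = 1e-8 * max(1, max(abs(qp$accelerations))))
    # objective at the reduced solution matches the oracle optimum
    j_red <- objective_value(obs, red, eta)$total
    qp_traj <- newton_propagate(qp$positions[1L], qp$velocities[1L],
                                qp$accelerations, obs$times)
    j_qp <- objective_value(obs, qp_traj, eta)$total
    expect_equal(j_red, j_qp, tolerance = 1e-8)
  }
})

test_that("the solution is a stationary point of the reduced objective", {
  obs <- random_instance(8, seed = 5)
  eta <- 0.1
  fit <- shadow_filter(obs, filter_config(eta))
  u <- c(fit$positions[1L], fit$velocities[1L], fit$accelerations[, 1L])
  g <- num_grad(function(x) reduced_objective(x, obs, eta), u, h = 1e-5)
  expect_lt(max(abs(g)), 1e-6 * max(1, abs(reduced_objective(u, obs, eta))))
})

test_that("KKT multipliers vanish on exactly representable data", {
  t <- seq(0, 1, by = 0.25)
  obs <- observation_series(t, 1 - 3 * t)
  res <- kkt_solve(obs, filter_config(eta = 0.2))
  expect_lt(max(abs(res$diagnostics$lambda_multipliers)), 1e-9)
  expect_lt(max(abs(res$diagnostics$mu_multipliers)), 1e-9)
  expect_lt(res$diagnostics$stationarity_residual_max, 1e-9)
})

test_that("eta = 0 yields the flagged minimum-norm solution, not an error", {
  obs <- random_instance(6, seed = 2)
  fit <- shadow_filter(obs, filter_config(eta = 0))
  rep <- attr(fit, "condition_report")
  expect_true(rep$rank_deficient)
  expect_equal(rep$n_unknowns - rep$rank, 1L)
  # the data are still interpolated exactly (n+1 equations, rank n+1)
  expect_lt(rms_error(fit$positions, obs$values), 1e-8)
})

test_that("objective_value decomposes misfit and penalty", {
  # trivial: positions equal observations, zero acceleration
  t <- 0:3
  obs <- observation_series(t, 2 * t + 1)
  traj <- newton_propagate(1, 2, c(0, 0, 0), t)
  val <- objective_value(obs, traj, eta = 0.7)
  expect_equal(unlist(val), c(total = 0, misfit = 0, penalty = 0))
  # single interval, worked by hand: residuals (1, 0), a = 2, T = 1
  obs1 <- observation_series(c(0, 1), c(1, 0))
  traj1 <- newton_propagate(0, -1, 2, c(0, 1))
  expect_equal(drop(traj1$positions), c(0, 0))
  val1 <- objective_value(obs1, traj1, eta = 0.5)
  expect_equal(val1$misfit, 0.5)
  expect_equal(val1$penalty, 4)
  expect_equal(val1$total, 2.5)
})

test_that("scaling noise variances is equivalent to scaling eta", {
  obs <- random_instance(9, seed = 31)
  eta <- 0.05
  c_scale <- 3.7
  # objective algebra under sigma^2 -> c sigma^2
  traj <- shadow_filter(obs, filter_config(eta))
  scaled_obs <- observation_series(obs$times, obs$values,
                                   obs$error_variances * c_scale)
  v0 <- objective_value(obs, traj, eta)
  v1 <- objective_value(scaled_obs, traj, eta)
  expect_equal(v1$misfit, v0$misfit / c_scale)
  expect_equal(v1$penalty, v0$penalty)
  # the minimizer under sigma^2 -> c sigma^2 equals the minimizer under
  # eta -> c eta
  fit_scaled_sig <- shadow_filter(scaled_obs, filter_config(eta))
  fit_scaled_eta <- shadow_filter(obs, filter_config(eta * c_scale))
  expect_equal(fit_scaled_sig$positions, fit_scaled_eta$positions,
               tolerance = 1e-9)
  expect_equal(fit_scaled_sig$accelerations, fit_scaled_eta$accelerations,
               tolerance = 1e-9)
})

test_that("huge eta reproduces the weighted affine regression", {
  set.seed(8)
  t <- cumsum(runif(12, 0.2, 0.8))
  w <- runif(12, 0.5, 3)
  y <- 4 - 1.5 * t + rnorm(12)
  obs <- observation_series(t, y, error_variances = w)
  fit <- shadow_filter(obs, filter_config(eta = 1e12))
  ref <- stats::lm(y ~ t, weights = 1 / w)
  expect_lt(max(abs(fit$accelerations)), 1e-6)
  expect_equal(drop(fit$positions), unname(stats::predict(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$velocities[1L, 1L]), unname(stats::coef(ref)[2L]),
               tolerance = 1e-6)
})

test_that("misfit grows and penalty shrinks along an increasing eta grid", {
  set.seed(12)
  t <- seq(0, 6, by = 0.3)
  obs <- observation_series(t, sin(t) + rnorm(length(t), sd = 0.3))
  etas <- sort(default_eta_grid())
  vals <- lapply(etas, function(e) {
    objective_value(obs, shadow_filter(obs, filter_config(e)), e)
  })
  misfits <- vapply(vals, `[[`, numeric(1L), "misfit")
  penalties <- vapply(vals, `[[`, numeric(1L), "penalty")
  expect_true(all(diff(misfits) >= -1e-10 * max(misfits)))
  expect_true(all(diff(penalties) <= 1e-10 * max(penalties)))
})

test_that("the filter is Galilean invariant", {
  obs <- random_instance(10, seed = 77)
  alpha <- 5; beta <- -2.5
  shifted <- observation_series(obs$times,
                                obs$values + alpha + beta * obs$times,
                                obs$error_variances)
  for (eta in c(0.01, 1)) {
    f0 <- shadow_filter(obs, filter_config(eta))
    f1 <- shadow_filter(shifted, filter_config(eta))
    scale <- max(abs(f1$positions))
    expect_equal(drop(f1$positions),
                 drop(f0$positions) + alpha + beta * obs$times,
                 tolerance = 1e-8 * scale)
    expect_equal(drop(f1$velocities), drop(f0$velocities) + beta,
                 tolerance = 1e-8 * scale)
    expect_equal(f1$accelerations, f0$accelerations,
                 tolerance = 1e-8 * scale)
  }
})

test_that("device dropouts are equivalent to a series without those samples", {
  obs <- random_instance(15, seed = 4)
  keep <- c(1:5, 8:11, 13:15)
  gappy <- subset_series(obs, keep)
  fresh <- observation_series(obs$times[keep], obs$values[keep, , drop = FALSE],
                              obs$error_variances[keep])
  f1 <- shadow_filter(gappy, filter_config(0.05))
  f2 <- shadow_filter(fresh, filter_config(0.05))
  expect_identical(f1$positions, f2$positions)
  expect_identical(f1$accelerations, f2$accelerations)
})

test_that("filter_track applies the scalar filter per coordinate", {
  set.seed(90)
  t <- cumsum(runif(12, 0.1, 0.4))
  vals <- cbind(x = rnorm(12), y = rnorm(12, 5), z = rnorm(12, -3))
  obs <- observation_series(t, vals, error_variances = runif(12, 0.5, 2))
  cfg <- filter_config(0.08)
  tr <- filter_track(obs, cfg)
  for (k in 1:3) {
    scalar <- shadow_filter(
      observation_series(t, vals[, k, drop = FALSE], obs$error_variances), cfg)
    expect_identical(tr$positions[, k], scalar$positions[, 1L])
    expect_identical(tr$velocities[, k], scalar$velocities[, 1L])
    expect_identical(tr$accelerations[, k], scalar$accelerations[, 1L])
  }
  # permuting coordinates permutes outputs identically
  perm <- c(3, 1, 2)
  obs_p <- observation_series(t, vals[, perm], obs$error_variances)
  tr_p <- filter_track(obs_p, cfg)
  expect_identical(unname(tr_p$positions), unname(tr$positions[, perm]))
  # 1-D filter_track matches shadow_filter
  obs1 <- observation_series(t, vals[, 1L, drop = FALSE], obs$error_variances)
  expect_identical(filter_track(obs1, cfg)$positions,
                   shadow_filter(obs1, cfg)$positions)
})

test_that("every returned trajectory is Newton-consistent", {
  for (seed in c(3, 14)) {
    obs <- random_instance(12, seed = seed)
    for (eta in c(0, 1e-4, 1, 1e6)) {
      fit <- shadow_filter(obs, filter_config(eta))
      expect_lt(newton_deviation(fit), 1e-9 * max(1, max(abs(fit$positions))))
    }
  }
})

test_that("rms_error implements the per-sample mean of squared norms", {
  expect_equal(rms_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rms_error(matrix(0, 1, 3), matrix(c(3, 4, 0), 1, 3)), 5)
  expect_equal(rms_error(matrix(0, 2, 3),
                         matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)), 1)
  expect_error(rms_error(1:3, 1:4), "same shape")
})

test_that("filter input validation catches bad cases", {
  expect_error(shadow_filter(observation_series(0, 1), filter_config(0.1)),
               "at least 2")
  obs2 <- observation_series(0:3, cbind(1:4, 5:8))
  expect_error(shadow_filter(obs2, filter_config(0.1)), "one coordinate")
  expect_error(filter_config(-1), "eta")
  expect_error(filter_config(0.1, svd_rcond = 2), "svd_rcond")
})
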