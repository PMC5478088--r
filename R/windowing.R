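#' Windowing test: convergence under growing observation windows
#'
#' How much data does the filter need?  The windowing test filters
#' suffixes of the observation sequence of increasing length n — always
#' anchored at the most recent sample — at a fixed smoothing weight, and
#' compares each suffix reconstruction to the corresponding observations:
#' \deqn{D_{j,n} = \|P_{N-j} - q_{N-j,\eta,n}\|, \qquad 0 \le j < n.}
#' Once the window is long enough, the estimate of the most recent state
#' stops changing as more history is added; the smallest such window is
#' the minimum observation length required for tracking (see
#' [min_window_length()]).
#'
#' @param obs An [observation_series()] of length N+1.
#' @param eta Positive smoothing weight.
#' @param window_lengths Integer window lengths (numbers of samples) to
#'   test.  The full window is always included as the reference; lengths
#'   below 2 are skipped with a warning record.
#' @param filter_args Extra arguments passed to [filter_config()].
#' @return An object of class `"windowing_result"`: list with
#'   `window_lengths` (sorted, full length last position included),
#'   `distances` (one numeric vector per window, `distances[[k]][j + 1]`
#'   holding `D_{j,n}` for `j = 0, ..., n-1`), `last_state_estimates`
#'   (matrix, one row per window: reconstructed position at the final
#'   time), `full_length` and `skipped` (requested lengths below 2).
#' @export
windowing_test <- function(obs, eta, window_lengths, filter_args = list()) {
  stopifnot(inherits(obs, "observation_series"))
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0) {
    stop("`eta` must be a single positive weight", call. = FALSE)
  }
  N1 <- length(obs$times)
  window_lengths <- as.integer(window_lengths)
  if (any(window_lengths > N1)) {
    stop(sprintf("window lengths exceed the series length (%d samples)", N1),
         call. = FALSE)
  }
  skipped <- window_lengths[window_lengths < 2L]
  if (length(skipped)) {
    warning(sprintf("skipping window length(s) below 2 samples: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  lengths <- sort(unique(c(window_lengths[window_lengths >= 2L], N1)))
  cfg <- do.call(filter_config, c(list(eta = eta), filter_args))
  dists <- vector("list", length(lengths))
  names(dists) <- as.character(lengths)
  last_states <- matrix(NA_real_, length(lengths), ncol(obs$values),
                        dimnames = list(as.character(lengths),
                                        colnames(obs$values)))
  for (k in seq_along(lengths)) {
    n <- lengths[k]
    suffix <- subset_series(obs, (N1 - n + 1L):N1)
    traj <- filter_track(suffix, cfg)
    resid <- sqrt(rowSums((suffix$values - traj$positions)^2))
    dists[[k]] <- rev(resid)              # index j+1 holds D_{j,n}
    last_states[k, ] <- traj$positions[n, ]
  }
  structure(list(window_lengths = lengths, distances = dists,
                 last_state_estimates = last_states,
                 full_length = N1, eta = eta, skipped = skipped),
            class = "windowing_result")
}

#' @export
print.windowing_result <- function(x, ...) {
  cat(sprintf("<windowing_result> eta = %g; windows tested: %s (full = %d)\n",
              x$eta, paste(x$window_lengths, collapse = ", "), x$full_length))
  invisible(x)
}

#' Minimum observation-window length
#'
#' From a [windowing_test()] result, the smallest tested window length n
#' such that the last-state estimate of *every* tested window of at least
#' n samples lies within `tol` of the full-window estimate — a uniform
#' tail criterion, not a first crossing, so a window that momentarily
#' dips within tolerance but diverges again does not qualify.
#'
#' @param result A `"windowing_result"`.
#' @param tol Convergence tolerance in meters.  The default,
#'   [window_tol()], is 0.05 m, or one tenth of the noise standard
#'   deviation when a noise variance is supplied to that helper.
#' @return The minimum window length (integer), or `NA` (printed as
#'   "not reached") when no tested window satisfies the criterion.
#' @export
min_window_length <- function(result, tol = window_tol()) {
  stopifnot(inherits(result, "windowing_result"))
  full_row <- which(result$window_lengths == result$full_length)
  ref <- result$last_state_estimates[full_row, ]
  dev <- sqrt(rowSums(sweep(result$last_state_estimates, 2L, ref)^2))
  ok <- dev <= tol
  # uniform over the tail: n qualifies iff every tested n' >= n is ok
  tail_ok <- rev(cumprod(rev(ok))) > 0
  if (!any(tail_ok)) return(NA_integer_)
  result$window_lengths[which(tail_ok)[1L]]
}

#' Default windowing convergence tolerance
#'
#' @param noise_variance Optional observation-noise variance in m^2.
#' @return `max(0.05, sqrt(noise_variance) / 10)` meters (0.05 m when no
#'   variance is given).
#' @export
window_tol <- function(noise_variance = NULL) {
  if (is.null(noise_variance)) return(0.05)
  max(0.05, sqrt(noise_variance) / 10)
}

#' @export
as.data.frame.windowing_result <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$window_lengths), function(k) {
    n <- x$window_lengths[k]
    data.frame(n = n, j = seq_len(n) - 1L, distance = x$distances[[k]])
  }))
}
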