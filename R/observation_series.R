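#' Time-stamped position observations
#'
#' Container for a sequence of noisy position fixes on a strictly
#' increasing (possibly irregular) time grid, as logged by a GPS device.
#' Each sample carries an observation-error variance and a validity flag
#' (`TRUE` = logged by the device, `FALSE` = interpolated afterwards,
#' mirroring the `signal` column convention of high-rate avian GPS files).
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, length `n + 1`.
#' @param values Numeric vector (one coordinate) or matrix with one column
#'   per coordinate, positions in meters; `n + 1` rows.
#' @param error_variances Numeric vector of per-sample observation-error
#'   variances in m^2, all strictly positive.  Recycled from length 1.
#'   Default 1 for every sample.
#' @param valid_flags Logical vector; `FALSE` marks fixes that were
#'   interpolated rather than measured.  Recycled from length 1.
#'
#' @return An object of class `"observation_series"`: a list with elements
#'   `times`, `values` (always a matrix with named columns),
#'   `error_variances` and `valid_flags`.
#' @examples
#' obs <- observation_series(times = 0:4 / 5, values = sin(0:4))
#' n_coords(obs)
#' @export
observation_series <- function(times, values,
                               error_variances = 1,
                               valid_flags = TRUE) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("`times` must be finite and non-missing", call. = FALSE)
  }
  if (length(times) >= 2L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("`times` must be strictly increasing; sample %d (t = %g) does not advance",
                 bad, times[bad]), call. = FALSE)
  }
  values <- as_coord_matrix(values)
  if (nrow(values) != length(times)) {
    stop("`values` must have one row per time sample", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite and non-missing", call. = FALSE)
  }
  error_variances <- rep_len(as.numeric(error_variances), length(times))
  if (anyNA(error_variances) || any(error_variances <= 0)) {
    stop("`error_variances` must all be strictly positive", call. = FALSE)
  }
  valid_flags <- rep_len(as.logical(valid_flags), length(times))
  if (anyNA(valid_flags)) {
    stop("`valid_flags` must be TRUE/FALSE without missing values", call. = FALSE)
  }
  structure(
    list(times = times, values = values,
         error_variances = error_variances, valid_flags = valid_flags),
    class = "observation_series"
  )
}

#' @export
print.observation_series <- function(x, ...) {
  cat(sprintf("<observation_series> %d samples, %d coordinate(s) [%s]\n",
              length(x$times), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  cat(sprintf("  t in [%g, %g] s; %d interpolated fix(es)\n",
              x$times[1L], x$times[length(x$times)], sum(!x$valid_flags)))
  invisible(x)
}

#' Number of coordinates of a series or trajectory
#'
#' @param x An `observation_series` or `phase_trajectory`.
#' @return Integer number of spatial coordinates.
#' @export
n_coords <- function(x) {
  UseMethod("n_coords")
}

#' @export
n_coords.observation_series <- function(x) ncol(x$values)

#' Subset an observation series by sample index
#'
#' Keeps the selected samples of every per-sample field.  Used for
#' decimation, dropout removal and suffix windows; filtering the subset is
#' identical to filtering a series that never contained the dropped
#' samples.
#'
#' @param obs An `observation_series`.
#' @param idx Integer indices of samples to keep (in increasing order).
#' @return An `observation_series` with the selected samples.
#' @export
subset_series <- function(obs, idx) {
  stopifnot(inherits(obs, "observation_series"))
  idx <- as.integer(idx)
  observation_series(obs$times[idx], obs$values[idx, , drop = FALSE],
                     obs$error_variances[idx], obs$valid_flags[idx])
}

#' Drop interpolated fixes from a series
#'
#' Removes every sample whose validity flag is `FALSE`, leaving the
#' device-logged fixes on their original (now gappier) time grid.
#'
#' @param obs An `observation_series`.
#' @return An `observation_series` containing only valid fixes.
#' @export
drop_invalid <- function(obs) {
  stopifnot(inherits(obs, "observation_series"))
  subset_series(obs, which(obs$valid_flags))
}

# Coerce a vector or matrix of coordinates to a named-column matrix.
as_coord_matrix <- function(values, default_names = c("x", "y", "z")) {
  if (is.null(dim(values))) {
    values <- matrix(as.numeric(values), ncol = 1L)
  } else {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
  }
  if (is.null(colnames(values))) {
    if (ncol(values) <= length(default_names)) {
      colnames(values) <- default_names[seq_len(ncol(values))]
    } else {
      colnames(values) <- paste0("x", seq_len(ncol(values)))
    }
  }
  values
}
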