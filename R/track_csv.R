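#' Read a track CSV into an observation series
#'
#' The track dialect has a header `t,x[,y[,z]][,signal]`: `t` in seconds,
#' coordinates in meters, and an optional `signal` column where 1 marks a
#' device-logged fix and 0 an interpolated one.  Rows missing from the
#' file simply make the grid irregular — the filter needs no resampling.
#' Lines starting with `#` are treated as comments.
#'
#' @param path Path to a CSV file.
#' @param coords Coordinate column names to read, in order; default every
#'   column except `t` and `signal`.
#' @param exclude_interpolated If `TRUE`, drop rows with `signal == 0`
#'   (the default behavior of the command-line `track` tool, since the
#'   filter handles the resulting gaps natively).
#' @param error_variance Per-sample observation-error variance(s) to
#'   attach (default 1).
#' @return An [observation_series()].
#' @export
read_track_csv <- function(path, coords = NULL,
                           exclude_interpolated = FALSE,
                           error_variance = 1) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"t" %in% names(df)) stop("track CSV must have a `t` column", call. = FALSE)
  if (is.null(coords)) coords <- setdiff(names(df), c("t", "signal"))
  missing_cols <- setdiff(coords, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing coordinate column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("t", coords)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop(sprintf("non-numeric value in column `%s` at data row %d", col,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  t <- df$t
  if (anyNA(t)) {
    stop(sprintf("missing time at data row %d", which(is.na(t))[1L]),
         call. = FALSE)
  }
  if (length(t) >= 2L && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing; data row %d (t = %g) does not advance",
                 bad, t[bad]), call. = FALSE)
  }
  flags <- if ("signal" %in% names(df)) df$signal != 0 else rep(TRUE, nrow(df))
  obs <- observation_series(t, as.matrix(df[coords]),
                            error_variances = error_variance,
                            valid_flags = flags)
  if (exclude_interpolated) drop_invalid(obs) else obs
}

#' Write a series or trajectory to a track CSV
#'
#' An [observation_series()] is written with header `t,<coords>,signal`.
#' A [phase_trajectory()] is written with one block of columns per
#' coordinate, `t,<c>,<c>_v,<c>_a`, the per-interval acceleration
#' assigned to its interval's left endpoint with the final sample
#' repeating the last value; provenance (`# eta=...`, `# solver=...`)
#' goes into leading comment lines when the trajectory carries those
#' attributes.  Numbers are written with `%.17g` so a re-read reproduces
#' the doubles bitwise, and rewriting the same object yields a
#' byte-identical file.
#'
#' @param x An `observation_series` or `phase_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_track_csv <- function(x, path) {
  UseMethod("write_track_csv")
}

#' @export
write_track_csv.observation_series <- function(x, path) {
  header <- paste(c("t", colnames(x$values), "signal"), collapse = ",")
  rows <- apply(cbind(fmt_num(x$times),
                      matrix(fmt_num(x$values), nrow = nrow(x$values)),
                      as.integer(x$valid_flags)),
                1L, paste, collapse = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @export
write_track_csv.phase_trajectory <- function(x, path) {
  comments <- character(0)
  if (!is.null(attr(x, "eta"))) {
    comments <- c(comments, sprintf("# eta=%s", fmt_num(attr(x, "eta"))))
  }
  if (!is.null(attr(x, "solver"))) {
    comments <- c(comments, sprintf("# solver=%s", attr(x, "solver")))
  }
  cn <- colnames(x$positions)
  header <- paste(c("t", as.vector(rbind(cn, paste0(cn, "_v"), paste0(cn, "_a")))),
                  collapse = ",")
  a_full <- sample_accelerations(x)
  blocks <- do.call(cbind, lapply(seq_along(cn), function(k) {
    cbind(fmt_num(x$positions[, k]), fmt_num(x$velocities[, k]),
          fmt_num(a_full[, k]))
  }))
  rows <- apply(cbind(fmt_num(x$times), blocks), 1L, paste, collapse = ",")
  writeLines(c(comments, header, rows), path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)
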