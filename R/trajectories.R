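#' Single-motor trajectory
#'
#' Time-ordered positions of one tracked motor, in physical units (seconds and
#' nanometres) so downstream analysis is decoupled from acquisition settings.
#'
#' @param track_id identifier.
#' @param t_s strictly increasing sample times, seconds.
#' @param x_nm,y_nm positions, nanometres.
#' @export
Trajectory <- function(track_id, t_s, x_nm, y_nm) {
  stopifnot(length(t_s) == length(x_nm), length(t_s) == length(y_nm))
  if (length(t_s) < 2L) stop("a trajectory needs at least 2 samples", call. = FALSE)
  if (any(diff(t_s) <= 0)) {
    stop(sprintf("track %s: sample times must be strictly increasing", track_id),
         call. = FALSE)
  }
  structure(
    list(track_id = as.character(track_id), t_s = as.numeric(t_s),
         x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm)),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s: %d samples over %.3g s\n",
              x$track_id, length(x$t_s), lifetime(x)))
  invisible(x)
}

#' Trajectory lifetime in seconds
#' @param traj a [Trajectory].
#' @export
lifetime <- function(traj) traj$t_s[length(traj$t_s)] - traj$t_s[1]

#' Set of trajectories from one movie
#'
#' @param trajectories list of [Trajectory] objects.
#' @param movie_duration_s movie length, seconds; all sample times must fall
#'   inside `[0, movie_duration_s]`.
#' @param pixel_size_nm pixel calibration of the source movie.
#' @param field_id label of the imaged field.
#' @export
TrajectorySet <- function(trajectories, movie_duration_s, pixel_size_nm,
                          field_id = "field") {
  stopifnot(is.list(trajectories), movie_duration_s > 0, pixel_size_nm > 0)
  for (tr in trajectories) {
    stopifnot(inherits(tr, "Trajectory"))
    if (tr$t_s[1] < 0 || tr$t_s[length(tr$t_s)] > movie_duration_s + 1e-9) {
      stop(sprintf("track %s: sample times outside [0, movie duration]",
                   tr$track_id), call. = FALSE)
    }
  }
  structure(
    list(trajectories = trajectories,
         movie_duration_s = as.numeric(movie_duration_s),
         pixel_size_nm = as.numeric(pixel_size_nm),
         field_id = field_id),
    class = "TrajectorySet"
  )
}

#' @export
print.TrajectorySet <- function(x, ...) {
  cat(sprintf("TrajectorySet '%s': %d tracks, %.3g s movie, %g nm/px\n",
              x$field_id, length(x$trajectories), x$movie_duration_s,
              x$pixel_size_nm))
  invisible(x)
}

#' @export
length.TrajectorySet <- function(x) length(x$trajectories)

#' Read a trajectory table
#'
#' Reads a CSV with columns `track_id, frame, t_s, x_nm, y_nm` (the interchange
#' format standing in for the output of single-particle tracking software),
#' groups rows by track and sorts each track by time. Tracks with fewer than
#' two samples cannot carry motility information and are dropped with a
#' warning.
#'
#' @param path CSV path.
#' @param movie_duration_s,pixel_size_nm,field_id acquisition metadata for the
#'   returned set; `movie_duration_s` defaults to the last sample time.
#' @return a [TrajectorySet].
#' @export
read_trajectory_table <- function(path, movie_duration_s = NULL,
                                  pixel_size_nm = 1, field_id = "field") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_s", "x_nm", "y_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("trajectory table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  groups <- split(df, df$track_id)
  n_dropped <- 0L
  trajs <- list()
  for (g in groups) {
    g <- g[order(g$t_s), , drop = FALSE]
    if (anyDuplicated(g$t_s)) {
      stop(sprintf("track %s: duplicate sample times", g$track_id[1]),
           call. = FALSE)
    }
    if (nrow(g) < 2L) {
      n_dropped <- n_dropped + 1L
      next
    }
    trajs[[length(trajs) + 1L]] <- Trajectory(g$track_id[1], g$t_s, g$x_nm, g$y_nm)
  }
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d track(s) with < 2 samples", n_dropped),
            call. = FALSE)
  }
  if (is.null(movie_duration_s)) {
    movie_duration_s <- if (length(trajs)) max(df$t_s) else 1
  }
  TrajectorySet(trajs, movie_duration_s, pixel_size_nm, field_id)
}

#' Write a trajectory table
#'
#' Inverse of [read_trajectory_table()]; frame numbers are recovered from the
#' time stamps only as a running sample index within each track.
#'
#' @param tset a [TrajectorySet].
#' @param path output CSV path.
#' @export
write_trajectory_table <- function(tset, path) {
  stopifnot(inherits(tset, "TrajectorySet"))
  rows <- lapply(tset$trajectories, function(tr) {
    data.frame(track_id = tr$track_id, frame = seq_along(tr$t_s) - 1L,
               t_s = tr$t_s, x_nm = tr$x_nm, y_nm = tr$y_nm,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = character(), frame = integer(), t_s = numeric(),
               x_nm = numeric(), y_nm = numeric())
  write_table(df, path)
}

#' Write a result table as deterministic CSV
#'
#' Numeric columns are written with full double precision (`%.17g`) so that a
#' write-read-write cycle is byte-identical; an empty collection produces a
#' header-only file.
#'
#' @param records a data.frame, or a list of assay-result objects that have an
#'   `as.data.frame` method (rows are bound in order).
#' @param path output CSV path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    if (is.list(records) && length(records) > 0) {
      records <- do.call(rbind, lapply(records, as.data.frame))
    } else if (is.list(records)) {
      stop("cannot infer columns from an empty list; pass a data.frame",
           call. = FALSE)
    }
  }
  cols <- lapply(records, format_full)
  header <- paste(names(records), collapse = ",")
  body <- if (nrow(records) > 0) do.call(paste, c(cols, sep = ",")) else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
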