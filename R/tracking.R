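#' Create a continuous-measurement tracker
#'
#' A tracker logs one or more time-varying quantities within each trial at
#' whatever rate the caller's clock ticks (for a VR head-mounted display,
#' typically the 90 Hz refresh rate). The canonical use is the position and
#' rotation of a tracked object (see [pos_rot_tracker()]), but any measured
#' fields work -- e.g., a single `pressure` channel. The library never owns a
#' frame loop: an external clock drives [record()].
#'
#' Each trial's buffer is handed to the session's write queue when the trial
#' ends, producing one CSV per tracker per trial named
#' `<tracker>_T<trial_num>.csv` (trial number zero-padded to 3), so continuous
#' files join behavioral rows on `trial_num`.
#'
#' @param name Tracker name; becomes the file-name prefix, so it must be a
#'   clean path component.
#' @param fields Measured column names, not counting `time` (always first).
#' @return An object of class `tk_tracker`.
#' @export
tracker <- function(name, fields) {
  check_path_component(name, "name")
  if (!is.character(fields) || length(fields) < 1L || any(!nzchar(fields))) {
    stop_invalid("`fields` must be one or more non-empty column names")
  }
  tr <- new.env(parent = emptyenv())
  tr$name <- name
  tr$fields <- fields
  tr$header <- c("time", fields)
  tr$trial <- NULL
  tr$buffer <- list()
  tr$n_rows <- 0L
  tr$last_time <- -Inf
  class(tr) <- "tk_tracker"
  tr
}

#' Position-and-rotation tracker
#'
#' The standard six-channel tracker for a rigid object's pose: position in
#' meters (`pos_x` lateral, `pos_y` vertical/up, `pos_z` anterior-posterior)
#' and rotation as Euler angles in degrees (`rot_x`, `rot_y`, `rot_z`). Units
#' are recorded as-is, never converted.
#'
#' @param name Tracker name (default `"head"`, the head-tracking use case).
#' @return A `tk_tracker` with header
#'   `time,pos_x,pos_y,pos_z,rot_x,rot_y,rot_z`.
#' @export
pos_rot_tracker <- function(name = "head") {
  tracker(name, c("pos_x", "pos_y", "pos_z", "rot_x", "rot_y", "rot_z"))
}

#' Attach a tracker to a session
#'
#' Attached trackers are armed automatically at each [begin_trial()] and
#' their buffers are queued for writing at each [end_trial()].
#'
#' @param session A `tk_session`.
#' @param tracker A `tk_tracker`.
#' @return The session, invisibly.
#' @export
attach_tracker <- function(session, tracker) {
  check_session(session)
  if (!inherits(tracker, "tk_tracker")) stop_invalid("`tracker` must be a tk_tracker")
  if (any(vapply(session$trackers, function(t) t$name, "") == tracker$name)) {
    stop_invalid(sprintf("a tracker named '%s' is already attached", tracker$name))
  }
  session$trackers <- c(session$trackers, tracker)
  invisible(session)
}

tracker_begin_trial <- function(tracker, trial) {
  tracker$trial <- trial
  tracker$buffer <- list()
  tracker$n_rows <- 0L
  tracker$last_time <- -Inf
  invisible(tracker)
}

#' Record one tracker sample
#'
#' Appends a row to the current trial's buffer. Time is seconds since the
#' trial began and must strictly increase row to row; recording outside an
#' in-progress trial is a lifecycle error.
#'
#' @param tracker A `tk_tracker` attached to a session with a trial in
#'   progress.
#' @param time Sample time, seconds since trial begin.
#' @param values Numeric vector, one value per tracker field.
#' @return The tracker, invisibly.
#' @export
record <- function(tracker, time, values) {
  if (!inherits(tracker, "tk_tracker")) stop_invalid("`tracker` must be a tk_tracker")
  trial <- tracker$trial
  if (is.null(trial) || trial$status != "in_progress") {
    stop_lifecycle(sprintf("tracker '%s': cannot record outside an in-progress trial", tracker$name))
  }
  if (!is.numeric(time) || length(time) != 1L || is.na(time) || time < 0) {
    stop_invalid("`time` must be a single non-negative number")
  }
  if (time <= tracker$last_time) {
    tk_stop("tk_rejected_row", sprintf(
      "tracker '%s': non-increasing time %.6f (last %.6f)", tracker$name, time, tracker$last_time))
  }
  if (length(values) != length(tracker$fields)) {
    stop_invalid(sprintf("tracker '%s': expected %d value(s), got %d",
                         tracker$name, length(tracker$fields), length(values)))
  }
  tracker$n_rows <- tracker$n_rows + 1L
  tracker$buffer[[tracker$n_rows]] <- c(time, as.numeric(values))
  tracker$last_time <- time
  invisible(tracker)
}

#' Record a batch of tracker samples
#'
#' Equivalent to calling [record()] once per row of `samples`, but vectorized;
#' used by simulations that produce a whole trial's trace at once. The same
#' contracts apply: an in-progress trial, strictly increasing times (also
#' against anything already buffered), one column per field after `time`.
#'
#' @param tracker A `tk_tracker`.
#' @param samples Data frame or matrix whose first column is `time` followed
#'   by the tracker's fields.
#' @return The tracker, invisibly.
#' @export
record_many <- function(tracker, samples) {
  if (!inherits(tracker, "tk_tracker")) stop_invalid("`tracker` must be a tk_tracker")
  trial <- tracker$trial
  if (is.null(trial) || trial$status != "in_progress") {
    stop_lifecycle(sprintf("tracker '%s': cannot record outside an in-progress trial", tracker$name))
  }
  m <- as.matrix(samples)
  if (ncol(m) != length(tracker$header)) {
    stop_invalid(sprintf("tracker '%s': expected %d columns, got %d",
                         tracker$name, length(tracker$header), ncol(m)))
  }
  if (nrow(m) == 0L) return(invisible(tracker))
  times <- m[, 1L]
  if (any(is.na(times)) || any(times < 0) || any(diff(times) <= 0) || times[1L] <= tracker$last_time) {
    tk_stop("tk_rejected_row", sprintf("tracker '%s': times must be strictly increasing", tracker$name))
  }
  for (i in seq_len(nrow(m))) {
    tracker$n_rows <- tracker$n_rows + 1L
    tracker$buffer[[tracker$n_rows]] <- unname(m[i, ])
  }
  tracker$last_time <- times[length(times)]
  invisible(tracker)
}

#' Rows currently buffered for the ongoing trial
#' @param tracker A `tk_tracker`.
#' @return Integer row count.
#' @export
buffered_rows <- function(tracker) {
  if (!inherits(tracker, "tk_tracker")) stop_invalid("`tracker` must be a tk_tracker")
  tracker$n_rows
}

#' Flush a tracker's buffer for a finished trial into a write task
#'
#' Produces the write task for this tracker/trial pair -- destination
#' `<session dir>/<tracker>_T<nnn>.csv`, header always present, one line per
#' buffered sample -- and clears the buffer. Called automatically by
#' [end_trial()] for attached trackers.
#'
#' @param tracker A `tk_tracker`.
#' @param trial The finished (`done`) `tk_trial` the buffer belongs to.
#' @return A `tk_write_task`.
#' @export
flush_trial <- function(tracker, trial) {
  if (!inherits(tracker, "tk_tracker")) stop_invalid("`tracker` must be a tk_tracker")
  check_trial(trial)
  if (trial$status != "done") stop_lifecycle("flush_trial requires a finished trial")
  lines <- csv_line(tracker$header)
  if (tracker$n_rows > 0L) {
    m <- do.call(rbind, tracker$buffer[seq_len(tracker$n_rows)])
    body <- apply(m, 1L, function(r) paste(formatC(r, format = "g", digits = 10), collapse = ","))
    lines <- c(lines, body)
  }
  dest <- file.path(trial$session$paths$dir, tracker_filename(tracker$name, trial$trial_num))
  tracker$buffer <- list()
  tracker$n_rows <- 0L
  tracker$last_time <- -Inf
  tracker$trial <- NULL
  write_task(dest, lines)
}

tracker_filename <- function(name, trial_num) {
  sprintf("%s_T%03d.csv", name, as.integer(trial_num))
}

#' @export
print.tk_tracker <- function(x, ...) {
  cat(sprintf("<tk_tracker> '%s' [%s], %d row(s) buffered\n",
              x$name, paste(x$header, collapse = ","), x$n_rows))
  invisible(x)
}
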