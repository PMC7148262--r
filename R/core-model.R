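#' Create an experiment session
#'
#' A session encapsulates one full run of the experiment by one participant.
#' It owns the block and trial hierarchy, the root of the settings cascade,
#' the lifecycle event registry, the attached trackers, and the deferred write
#' queue that makes its data files durable at [end_session()].
#'
#' Trial and block numbers are generated automatically as positive integers in
#' creation order; trial numbers run globally across the whole session (block
#' 2's first trial continues the count), which is what makes per-trial files
#' and behavioral rows join on `trial_num` alone.
#'
#' @param experiment_name Name of the experiment (first level of the output
#'   directory layout `experiment > participant > session`).
#' @param ppid Participant ID (second level).
#' @param session_num Session number, a positive integer (third level,
#'   rendered `S001`, `S002`, ...).
#' @param settings Named list of session-level settings.
#' @param base_dir Root directory for data output.
#' @param profile Optional named list (e.g., from [load_profile()]) attached
#'   above the session in the cascade; programmatic session settings shadow it.
#' @param overwrite Allow reuse of an existing session directory. Off by
#'   default so a ppid/session collision cannot silently clobber collected
#'   data.
#' @param clock Zero-argument function returning seconds from a monotonic
#'   clock. The default reads process elapsed time; simulations inject
#'   [sim_clock()] to control time explicitly. All trial timestamps are
#'   relative to the moment the session begins.
#' @return An object of class `tk_session`, state `created`, with zero blocks.
#' @seealso [create_block()], [begin_trial()], [end_session()]
#' @export
create_session <- function(experiment_name, ppid, session_num = 1L,
                           settings = list(), base_dir = "data",
                           profile = NULL, overwrite = FALSE,
                           clock = monotonic_clock()) {
  if (!is_string(experiment_name) || !nzchar(experiment_name)) {
    stop_invalid("`experiment_name` must be a non-empty string")
  }
  if (!is_string(ppid) || !nzchar(ppid)) stop_invalid("`ppid` must be a non-empty string")
  if (!is_count(session_num)) stop_invalid("`session_num` must be a positive integer")
  if (!is.function(clock)) stop_invalid("`clock` must be a function")

  root_parent <- NULL
  if (!is.null(profile)) {
    if (!is.list(profile) || (length(profile) && is.null(names(profile)))) {
      stop_invalid("`profile` must be a named list (see load_profile())")
    }
    root_parent <- settings_node(profile, level = "profile")
  }

  s <- new.env(parent = emptyenv())
  s$experiment_name <- experiment_name
  s$ppid <- ppid
  s$session_num <- as.integer(session_num)
  s$blocks <- list()
  s$trials <- list()
  s$settings <- settings_node(settings, parent = root_parent, level = "session")
  s$state <- "created"
  s$clock <- clock
  s$clock_origin <- NA_real_
  s$hooks <- list(session_begin = list(), trial_begin = list(),
                  trial_end = list(), session_end = list())
  s$result_columns <- character()
  s$settings_of_record <- character()
  s$trackers <- list()
  s$log_lines <- character()
  s$paths <- session_paths(base_dir, experiment_name, ppid, session_num)
  if (dir.exists(s$paths$dir) && !isTRUE(overwrite)) {
    stop_lifecycle(sprintf(
      "session directory already exists: %s (pass overwrite = TRUE to reuse it)",
      s$paths$dir))
  }
  s$queue <- write_queue(base_dir)
  class(s) <- "tk_session"
  log_event(s, sprintf("session created: %s/%s/S%03d", experiment_name, ppid, s$session_num))
  s
}

#' Register a lifecycle event hook
#'
#' Hooks let task code attach behavior to the stages of a session -- e.g.,
#' present a stimulus when a trial begins -- without owning the control flow.
#' Hooks fire in registration order and receive the relevant object (the
#' session for session events, the trial for trial events). A hook that throws
#' is caught and logged; it never corrupts session state or aborts the run.
#'
#' @param session A `tk_session`.
#' @param event One of `"session_begin"`, `"trial_begin"`, `"trial_end"`,
#'   `"session_end"`.
#' @param hook Function of one argument.
#' @return The session, invisibly.
#' @export
on_event <- function(session, event, hook) {
  check_session(session)
  event <- match.arg(event, names(session$hooks))
  if (!is.function(hook)) stop_invalid("`hook` must be a function")
  session$hooks[[event]] <- c(session$hooks[[event]], hook)
  invisible(session)
}

fire_hooks <- function(session, event, object) {
  for (hook in session$hooks[[event]]) {
    tryCatch(hook(object), error = function(e) {
      log_event(session, sprintf("hook error on %s: %s", event, conditionMessage(e)))
    })
  }
  invisible(NULL)
}

#' Append a block of trials to a session
#'
#' The new block receives the next block number; its `n_trials` trials receive
#' consecutive session-global trial numbers continuing from the trials already
#' created. Blocks and trials can also be created one at a time (see
#' [create_trial()]) to support adaptive or staircase procedures.
#'
#' @param session A `tk_session` that has not ended.
#' @param n_trials Number of trials to create in the block (may be 0).
#' @param settings Named list of block-level settings; trials in this block
#'   resolve them unless they override locally.
#' @return The new `tk_block`.
#' @export
create_block <- function(session, n_trials = 0L, settings = list()) {
  check_session(session)
  if (session$state == "ended") stop_lifecycle("cannot add a block to an ended session")
  if (!is_count(n_trials, min = 0L)) stop_invalid("`n_trials` must be a non-negative integer")
  b <- new.env(parent = emptyenv())
  b$session <- session
  b$block_num <- length(session$blocks) + 1L
  b$trials <- list()
  b$settings <- settings_node(settings, parent = session$settings, level = "block")
  class(b) <- "tk_block"
  session$blocks[[b$block_num]] <- b
  for (i in seq_len(n_trials)) create_trial(b)
  b
}

#' Append a single trial to a block
#'
#' @param block A `tk_block`.
#' @param settings Named list of trial-level settings (the "fine" end of the
#'   cascade).
#' @return The new `tk_trial`, status `not_started`.
#' @export
create_trial <- function(block, settings = list()) {
  if (!inherits(block, "tk_block")) stop_invalid("`block` must be a tk_block")
  session <- block$session
  if (session$state == "ended") stop_lifecycle("cannot add a trial to an ended session")
  t <- new.env(parent = emptyenv())
  t$session <- session
  t$block_num <- block$block_num
  t$trial_num <- length(session$trials) + 1L
  t$status <- "not_started"
  t$start_time <- NA_real_
  t$end_time <- NA_real_
  t$results <- list()
  t$settings <- settings_node(settings, parent = block$settings, level = "trial")
  class(t) <- "tk_trial"
  block$trials[[length(block$trials) + 1L]] <- t
  session$trials[[t$trial_num]] <- t
  t
}

#' Begin a trial
#'
#' Records the trial's start timestamp (seconds since the session began, from
#' the session clock) and fires `trial_begin` hooks. Beginning the first trial
#' promotes the session from `created` to `in_progress`, captures the clock
#' origin, and fires `session_begin` hooks.
#'
#' @param trial A `tk_trial` with status `not_started`.
#' @return The trial, invisibly.
#' @export
begin_trial <- function(trial) {
  check_trial(trial)
  session <- trial$session
  if (session$state == "ended") stop_lifecycle("session has ended")
  if (trial$status != "not_started") {
    stop_lifecycle(sprintf("trial %d already begun (status: %s)", trial$trial_num, trial$status))
  }
  if (session$state == "created") {
    session$state <- "in_progress"
    session$clock_origin <- session$clock()
    log_event(session, "session begin")
    fire_hooks(session, "session_begin", session)
  }
  trial$start_time <- session$clock() - session$clock_origin
  trial$status <- "in_progress"
  for (tr in session$trackers) tracker_begin_trial(tr, trial)
  log_event(session, sprintf("trial %d begin (t=%s)", trial$trial_num, fmt_time(trial$start_time)))
  fire_hooks(session, "trial_begin", trial)
  invisible(trial)
}

#' End a trial
#'
#' Records the end timestamp, marks the trial `done`, hands each attached
#' tracker's buffer to the write queue as one file per tracker (written at
#' drain), and fires `trial_end` hooks.
#'
#' @param trial A `tk_trial` with status `in_progress`.
#' @return The trial, invisibly.
#' @export
end_trial <- function(trial) {
  check_trial(trial)
  session <- trial$session
  if (trial$status != "in_progress") {
    stop_lifecycle(sprintf("cannot end trial %d with status '%s'", trial$trial_num, trial$status))
  }
  trial$end_time <- session$clock() - session$clock_origin
  trial$status <- "done"
  for (tr in session$trackers) {
    enqueue(session$queue, flush_trial(tr, trial))
  }
  log_event(session, sprintf("trial %d end (t=%s)", trial$trial_num, fmt_time(trial$end_time)))
  fire_hooks(session, "trial_end", trial)
  invisible(trial)
}

#' Record an observation in a trial's results
#'
#' Observations (dependent variables) can be added at any point once the trial
#' has begun -- during the trial or after it ended, which permits post-hoc
#' scoring. Each distinct result name becomes a column of the behavioral
#' output, registered session-wide in first-seen order; trials that never set
#' a name get a blank cell in that column.
#'
#' @param trial A begun `tk_trial`.
#' @param name Result (column) name.
#' @param value Scalar observation; re-adding a name overwrites its value.
#' @return The trial, invisibly.
#' @export
add_result <- function(trial, name, value) {
  check_trial(trial)
  if (!is_string(name) || !nzchar(name)) stop_invalid("result `name` must be a non-empty string")
  if (trial$status == "not_started") {
    stop_lifecycle(sprintf("cannot add result '%s': trial %d has not begun", name, trial$trial_num))
  }
  trial$results[[name]] <- value
  session <- trial$session
  if (!name %in% session$result_columns) {
    session$result_columns <- c(session$result_columns, name)
  }
  invisible(trial)
}

#' Register settings-of-record for the behavioral output
#'
#' Each named key becomes a column of the behavioral table, filled per trial
#' by resolving the key through that trial's cascade. This is how per-trial
#' parameters (stored at any level) appear alongside results in the output,
#' in first-seen order.
#'
#' @param session A `tk_session`.
#' @param keys Character vector of setting names.
#' @return The session, invisibly.
#' @export
log_setting <- function(session, keys) {
  check_session(session)
  if (!is.character(keys) || any(!nzchar(keys))) stop_invalid("`keys` must be non-empty strings")
  new <- setdiff(keys, session$settings_of_record)
  session$settings_of_record <- c(session$settings_of_record, new)
  invisible(session)
}

#' End a session
#'
#' Writes the behavioral table (one row per begun trial), the session log, and
#' the participant-visible files by draining the deferred write queue; the
#' call returns only once every queued file is durably on disk. Fires
#' `session_end` hooks and moves the session to state `ended`, after which no
#' further lifecycle operations are accepted. Write failures recorded during
#' the drain are reported as a warning, never as a mid-session error.
#'
#' @param session A `tk_session` in state `in_progress` (or `created`, for a
#'   session whose trials were never begun -- it still produces a valid,
#'   possibly empty, behavioral file).
#' @return The session directory path, invisibly.
#' @export
end_session <- function(session) {
  check_session(session)
  if (session$state == "ended") stop_lifecycle("session already ended")
  open_trials <- Filter(function(t) t$status == "in_progress", session$trials)
  for (t in open_trials) end_trial(t)
  enqueue(session$queue, write_task(
    file.path(session$paths$dir, "trial_results.csv"),
    behavioral_lines(session)
  ))
  log_event(session, "session end")
  enqueue(session$queue, write_task(
    file.path(session$paths$dir, "log.txt"),
    session$log_lines
  ))
  drain(session$queue)
  fire_hooks(session, "session_end", session)
  session$state <- "ended"
  failures <- queue_failures(session$queue)
  if (nrow(failures) > 0L) {
    warning(sprintf("%d write task(s) failed; see queue_failures()", nrow(failures)))
  }
  invisible(session$paths$dir)
}

check_session <- function(session) {
  if (!inherits(session, "tk_session")) stop_invalid("`session` must be a tk_session")
  invisible(session)
}

check_trial <- function(trial) {
  if (!inherits(trial, "tk_trial")) stop_invalid("`trial` must be a tk_trial")
  invisible(trial)
}

log_event <- function(session, msg) {
  stamp <- if (is.na(session$clock_origin)) "--.---" else fmt_time(session$clock() - session$clock_origin)
  session$log_lines <- c(session$log_lines, sprintf("[%s] %s", stamp, msg))
  invisible(NULL)
}

#' A manually advanced clock for simulations
#'
#' Sessions normally timestamp trials from a monotonic wall clock. Simulated
#' experiments instead inject this clock and advance it explicitly, which
#' makes timestamps deterministic (e.g., contiguous 10-s trials).
#'
#' @param start Initial time in seconds.
#' @return A function of zero or one argument: called with no argument it
#'   returns the current time; `clk(advance = dt)` moves time forward `dt`
#'   seconds and returns the new time.
#' @examples
#' clk <- sim_clock()
#' clk()            # 0
#' clk(advance = 10)
#' clk()            # 10
#' @export
sim_clock <- function(start = 0) {
  now <- start
  function(advance = NULL) {
    if (!is.null(advance)) now <<- now + advance
    now
  }
}

#' @export
print.tk_session <- function(x, ...) {
  cat(sprintf("<tk_session> %s / %s / S%03d  state: %s  blocks: %d  trials: %d\n",
              x$experiment_name, x$ppid, x$session_num, x$state,
              length(x$blocks), length(x$trials)))
  invisible(x)
}

#' @export
print.tk_block <- function(x, ...) {
  cat(sprintf("<tk_block> block %d, %d trial(s)\n", x$block_num, length(x$trials)))
  invisible(x)
}

#' @export
print.tk_trial <- function(x, ...) {
  cat(sprintf("<tk_trial> trial %d (block %d)  status: %s  [%s, %s]\n",
              x$trial_num, x$block_num, x$status,
              fmt_time(x$start_time), fmt_time(x$end_time)))
  invisible(x)
}
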