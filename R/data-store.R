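#' Session output paths
#'
#' All files of a session live under `base_dir/experiment/ppid/S<nnn>`, the
#' experiment > participant > session layout; two sessions of one participant
#' share the ppid directory. Name components are checked rather than silently
#' rewritten: a path separator or parent reference in an experiment name or
#' ppid is an error.
#'
#' @param base_dir Root data directory.
#' @param experiment_name,ppid,session_num Session identity.
#' @return A list with `base_dir`, `experiment_name`, `ppid`, `session_num`,
#'   and the derived session directory `dir`.
#' @export
session_paths <- function(base_dir, experiment_name, ppid, session_num) {
  check_path_component(experiment_name, "experiment_name")
  check_path_component(ppid, "ppid")
  if (!is_count(session_num)) stop_invalid("`session_num` must be a positive integer")
  structure(list(
    base_dir = base_dir,
    experiment_name = experiment_name,
    ppid = ppid,
    session_num = as.integer(session_num),
    dir = file.path(base_dir, experiment_name, ppid, sprintf("S%03d", as.integer(session_num)))
  ), class = "tk_session_paths")
}

check_path_component <- function(x, what) {
  if (!is_string(x) || !nzchar(x)) stop_invalid(sprintf("`%s` must be a non-empty string", what))
  if (grepl("[/\\\\]", x) || x %in% c(".", "..")) {
    stop_invalid(sprintf("`%s` must not contain path separators or be a relative reference: '%s'", what, x))
  }
  invisible(x)
}

#' Create a deferred write queue
#'
#' Data files are not written at the moment they are produced: tasks are
#' queued in FIFO order and written one by one when the queue is drained (at
#' session end, or explicitly). This keeps the task's execution path -- in the
#' original setting, a 90 Hz render loop -- free of file I/O latency while
#' guaranteeing that nothing is lost: [drain()] returns only when every queued
#' task is durably on disk.
#'
#' @param base_dir Root directory the queue is allowed to write under. A task
#'   whose destination escapes this tree is refused at enqueue time.
#' @return An object of class `tk_write_queue`.
#' @export
write_queue <- function(base_dir) {
  if (!is_string(base_dir) || !nzchar(base_dir)) stop_invalid("`base_dir` must be a non-empty string")
  q <- new.env(parent = emptyenv())
  q$base_dir <- base_dir
  q$tasks <- list()
  q$next_task <- 1L
  q$written <- 0L
  q$failures <- list()
  class(q) <- "tk_write_queue"
  q
}

#' Build a write task
#'
#' A task pairs a destination path with the text lines to write and an
#' optional ordered list of completion hooks. Hooks receive the written path
#' and fire exactly once, only after a successful write -- this is the
#' extension point for post-write actions such as uploading the file to
#' remote storage; the core itself does no network I/O.
#'
#' @param destination File path to write.
#' @param lines Character vector of lines (a header-only file is a length-1
#'   vector; an empty file, `character(0)`).
#' @param hooks List of functions of one argument (the written path).
#' @return An object of class `tk_write_task`.
#' @export
write_task <- function(destination, lines, hooks = list()) {
  if (!is_string(destination) || !nzchar(destination)) {
    stop_invalid("`destination` must be a non-empty path")
  }
  if (is.function(hooks)) hooks <- list(hooks)
  task <- new.env(parent = emptyenv())
  task$destination <- destination
  task$lines <- as.character(lines)
  task$hooks <- hooks
  task$written <- FALSE
  class(task) <- "tk_write_task"
  task
}

# TRUE iff `path` stays inside `base` once both are made absolute and "."/".."
# components are resolved lexically (the file need not exist yet).
path_inside <- function(path, base) {
  canon <- function(p) {
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(getwd(), p)
    parts <- strsplit(p, "[/\\\\]+")[[1]]
    out <- character()
    for (part in parts) {
      if (part == "" || part == ".") next
      if (part == "..") out <- out[-length(out)] else out <- c(out, part)
    }
    paste(out, collapse = "/")
  }
  cp <- canon(path)
  cb <- canon(base)
  cp == cb || startsWith(cp, paste0(cb, "/"))
}

#' Queue a write task
#'
#' Accepts the task in FIFO order without performing any I/O. Tasks aimed at
#' the same destination are written in enqueue order, so the final content of
#' a path is that of the last task queued for it.
#'
#' @param queue A `tk_write_queue`.
#' @param task A `tk_write_task` whose destination lies inside the queue's
#'   `base_dir` (anything else is refused with a `tk_path_escape` error).
#' @return The queue, invisibly.
#' @export
enqueue <- function(queue, task) {
  if (!inherits(queue, "tk_write_queue")) stop_invalid("`queue` must be a tk_write_queue")
  if (!inherits(task, "tk_write_task")) stop_invalid("`task` must be a tk_write_task")
  if (!path_inside(task$destination, queue$base_dir)) {
    tk_stop("tk_path_escape", sprintf(
      "refusing task outside the data directory: %s (base: %s)",
      task$destination, queue$base_dir))
  }
  queue$tasks[[length(queue$tasks) + 1L]] <- task
  invisible(queue)
}

#' Drain the write queue
#'
#' Writes every pending task to disk, in order, creating directories as
#' needed. Returns only when all previously enqueued tasks have been handled.
#' A failed write never raises into the caller: it is recorded per task
#' (see [queue_failures()]) and the drain continues with the next task.
#' Draining an empty (or already drained) queue is a no-op.
#'
#' @param queue A `tk_write_queue`.
#' @return Number of tasks written in this call, invisibly.
#' @export
drain <- function(queue) {
  if (!inherits(queue, "tk_write_queue")) stop_invalid("`queue` must be a tk_write_queue")
  n_done <- 0L
  while (queue$next_task <= length(queue$tasks)) {
    task <- queue$tasks[[queue$next_task]]
    queue$next_task <- queue$next_task + 1L
    if (task$written) next
    # failures are recorded, not raised: connection warnings would only
    # duplicate the per-task error message, so they are muted here
    ok <- tryCatch(suppressWarnings({
      dir.create(dirname(task$destination), recursive = TRUE, showWarnings = FALSE)
      writeLines(task$lines, task$destination, sep = "\n")
      TRUE
    }), error = function(e) {
      queue$failures[[length(queue$failures) + 1L]] <-
        list(destination = task$destination, error = conditionMessage(e))
      FALSE
    })
    if (ok) {
      task$written <- TRUE
      queue$written <- queue$written + 1L
      n_done <- n_done + 1L
      for (hook in task$hooks) {
        tryCatch(hook(task$destination), error = function(e) NULL)
      }
    }
  }
  invisible(n_done)
}

#' Write failures recorded by a queue
#'
#' @param queue A `tk_write_queue`.
#' @return Data frame with columns `destination` and `error`, one row per
#'   failed task (zero rows when everything was written).
#' @export
queue_failures <- function(queue) {
  if (!inherits(queue, "tk_write_queue")) stop_invalid("`queue` must be a tk_write_queue")
  if (length(queue$failures) == 0L) {
    return(data.frame(destination = character(), error = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    destination = vapply(queue$failures, `[[`, "", "destination"),
    error = vapply(queue$failures, `[[`, "", "error"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.tk_write_queue <- function(x, ...) {
  cat(sprintf("<tk_write_queue> %d queued, %d written, %d failed (base: %s)\n",
              length(x$tasks) - (x$next_task - 1L), x$written, length(x$failures), x$base_dir))
  invisible(x)
}

# ---- behavioral table ------------------------------------------------------

behavioral_header <- function(session) {
  c("experiment", "ppid", "session_num", "trial_num", "block_num",
    "start_time", "end_time", session$settings_of_record, session$result_columns)
}

# One CSV row per begun trial; settings-of-record resolved through each
# trial's cascade (blank when absent anywhere), results blank where never set.
behavioral_lines <- function(session) {
  header <- behavioral_header(session)
  rows <- character()
  for (t in session$trials) {
    if (t$status == "not_started") next
    cells <- c(
      session$experiment_name, session$ppid, session$session_num,
      t$trial_num, t$block_num, fmt_time(t$start_time), fmt_time(t$end_time)
    )
    for (key in session$settings_of_record) {
      cells <- c(cells, if (has_setting(t, key)) fmt_cell(resolve_setting(t, key)) else "")
    }
    for (name in session$result_columns) {
      cells <- c(cells, if (name %in% names(t$results)) fmt_cell(t$results[[name]]) else "")
    }
    rows <- c(rows, csv_line(cells))
  }
  c(csv_line(header), rows)
}

#' Behavioral table of a session as a data frame
#'
#' One row per begun trial: identity columns (`experiment`, `ppid`,
#' `session_num`), numbering (`trial_num`, `block_num`), timestamps
#' (`start_time`, `end_time`, seconds since session begin), then one column
#' per registered setting-of-record and per result name, in first-seen order.
#' This is exactly what `trial_results.csv` contains after [end_session()].
#'
#' @param session A `tk_session`.
#' @return A data frame (zero rows, header only, if no trial was begun).
#' @export
behavioral_table <- function(session) {
  check_session(session)
  utils::read.csv(text = paste(behavioral_lines(session), collapse = "\n"),
                  stringsAsFactors = FALSE)
}

# ---- participant registry --------------------------------------------------

#' Open (or create) a participant registry
#'
#' The registry is a single CSV (`participant_list.csv`) of participant
#' demographics kept at the top of the data directory, shared across sessions
#' and experiments, so a returning participant's details are entered once. Its
#' columns are the union of all demographic fields ever recorded, with `ppid`
#' as the unique key.
#'
#' @param base_dir Data directory; the registry file lives directly under it.
#' @return An object of class `tk_registry`.
#' @export
participant_registry <- function(base_dir) {
  if (!is_string(base_dir) || !nzchar(base_dir)) stop_invalid("`base_dir` must be a non-empty string")
  r <- new.env(parent = emptyenv())
  r$path <- file.path(base_dir, "participant_list.csv")
  r$records <- list()   # ppid -> named list of fields
  r$fields <- character()
  if (file.exists(r$path)) {
    df <- utils::read.csv(r$path, stringsAsFactors = FALSE, colClasses = "character")
    r$fields <- setdiff(names(df), "ppid")
    for (i in seq_len(nrow(df))) {
      rec <- as.list(df[i, r$fields, drop = FALSE])
      r$records[[df$ppid[i]]] <- rec
    }
  }
  class(r) <- "tk_registry"
  r
}

#' Insert or update a participant record
#'
#' A new ppid appends a record; an existing one has its fields updated and
#' extended (the registry can be topped up as measurements arrive, e.g.,
#' height and arm span collected mid-task). The registry file is rewritten
#' immediately so the record survives a crash.
#'
#' @param registry A `tk_registry`.
#' @param ppid Participant ID (unique key).
#' @param demographics Named list of fields, e.g.
#'   `list(age = 27, gender = "f")`. Field set is open-ended.
#' @return The registry, invisibly.
#' @export
upsert_participant <- function(registry, ppid, demographics = list()) {
  if (!inherits(registry, "tk_registry")) stop_invalid("`registry` must be a tk_registry")
  if (!is_string(ppid) || !nzchar(ppid)) stop_invalid("`ppid` must be a non-empty string")
  if (length(demographics) && (is.null(names(demographics)) || any(!nzchar(names(demographics))))) {
    stop_invalid("`demographics` must be a fully named list")
  }
  rec <- registry$records[[ppid]]
  if (is.null(rec)) rec <- list()
  for (field in names(demographics)) {
    rec[[field]] <- demographics[[field]]
    if (!field %in% registry$fields) registry$fields <- c(registry$fields, field)
  }
  registry$records[[ppid]] <- rec
  write_registry(registry)
  invisible(registry)
}

#' Look up a participant record
#'
#' @param registry A `tk_registry`.
#' @param ppid Participant ID.
#' @return Named list of the participant's fields; unknown ppid is an error
#'   of class `tk_not_found`.
#' @export
get_participant <- function(registry, ppid) {
  if (!inherits(registry, "tk_registry")) stop_invalid("`registry` must be a tk_registry")
  rec <- registry$records[[ppid]]
  if (is.null(rec)) tk_stop("tk_not_found", sprintf("no participant '%s' in registry", ppid))
  rec
}

write_registry <- function(registry) {
  header <- c("ppid", registry$fields)
  lines <- csv_line(header)
  for (ppid in names(registry$records)) {
    rec <- registry$records[[ppid]]
    cells <- c(ppid, vapply(registry$fields, function(f) {
      if (f %in% names(rec)) fmt_cell(rec[[f]]) else ""
    }, ""))
    lines <- c(lines, csv_line(cells))
  }
  dir.create(dirname(registry$path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, registry$path, sep = "\n")
  invisible(registry)
}

#' @export
print.tk_registry <- function(x, ...) {
  cat(sprintf("<tk_registry> %d participant(s), fields: %s (%s)\n",
              length(x$records), paste(x$fields, collapse = ", "), x$path))
  invisible(x)
}
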