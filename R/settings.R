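#' Hierarchical experiment settings with upward cascade
#'
#' Settings hold the independent variables of an experiment as key/value pairs
#' attached at one of several levels: trial, block, session, or an optional
#' settings profile loaded from JSON. Looking up a key on a trial that does not
#' define it cascades upward -- block, then session, then profile -- so a value
#' can be stored "gross" (once for the whole session) or "fine" (overridden on
#' a single trial) within the same system.
#'
#' @param local Named list of initial key/value pairs.
#' @param parent Parent `settings_node` searched when a key is absent locally,
#'   or `NULL` at the top of the chain.
#' @param level Label for the level this node represents (used in error
#'   messages), e.g. `"trial"`, `"block"`, `"session"`, `"profile"`.
#' @return An object of class `settings_node`.
#' @examples
#' sess <- settings_node(list(stimulus = "A"), level = "session")
#' tr <- settings_node(parent = sess, level = "trial")
#' resolve_setting(tr, "stimulus") # "A", found by cascading up
#' set_setting(tr, "stimulus", "B")
#' resolve_setting(tr, "stimulus") # "B", local value shadows the session
#' @export
settings_node <- function(local = list(), parent = NULL, level = "node") {
  if (length(local) && (is.null(names(local)) || any(!nzchar(names(local))))) {
    stop_invalid("settings mappings must have non-empty names for every entry")
  }
  if (!is.null(parent) && !inherits(parent, "settings_node")) {
    stop_invalid("`parent` must be a settings_node or NULL")
  }
  node <- new.env(parent = emptyenv())
  node$local <- as.list(local)
  node$parent <- parent
  node$level <- level
  class(node) <- "settings_node"
  node
}

# Atomic vectors, NULL, and (nested) lists of them map cleanly onto JSON;
# functions, environments, connections, etc. do not.
json_compatible <- function(value) {
  if (is.null(value) || (is.atomic(value) && !is.raw(value))) return(TRUE)
  if (is.list(value) && !is.environment(value)) {
    return(all(vapply(value, json_compatible, TRUE)))
  }
  FALSE
}

settings_of <- function(x) {
  if (inherits(x, "settings_node")) return(x)
  if (is.environment(x) && !is.null(x$settings)) return(x$settings)
  stop_invalid("expected a settings_node, session, block, or trial")
}

chain_levels <- function(node) {
  lv <- character()
  while (!is.null(node)) {
    lv <- c(lv, node$level)
    node <- node$parent
  }
  lv
}

#' Resolve a setting, cascading from the given level upward
#'
#' Returns the value stored closest to `x`: its own level if present, else the
#' first ancestor that defines `key`. A key absent at every level is an error
#' (class `tk_missing_setting`) naming the key and the levels searched, so a
#' mistyped setting name surfaces immediately rather than as a silent `NULL`.
#'
#' @param x A `settings_node`, or a session/block/trial (its settings are used).
#' @param key Setting name; keys are case-sensitive exact strings.
#' @return The stored value, verbatim (nested profile objects come back as
#'   named lists).
#' @export
resolve_setting <- function(x, key) {
  if (!is_string(key) || !nzchar(key)) stop_invalid("`key` must be a non-empty string")
  node <- settings_of(x)
  probe <- node
  while (!is.null(probe)) {
    if (key %in% names(probe$local)) return(probe$local[[key]])
    probe <- probe$parent
  }
  tk_stop("tk_missing_setting", sprintf(
    "setting '%s' not found at any level (searched: %s)",
    key, paste(chain_levels(node), collapse = " -> ")
  ))
}

#' Test whether a setting is defined at any level of the chain
#' @inheritParams resolve_setting
#' @return `TRUE` if [resolve_setting()] would succeed.
#' @export
has_setting <- function(x, key) {
  node <- settings_of(x)
  while (!is.null(node)) {
    if (key %in% names(node$local)) return(TRUE)
    node <- node$parent
  }
  FALSE
}

#' Store a setting at one level
#'
#' The value is stored in `x`'s own mapping, shadowing any ancestor value for
#' `x` and everything below it; siblings and ancestors are unaffected.
#'
#' @inheritParams resolve_setting
#' @param value Any JSON-serializable value (atomic scalar/vector or list).
#' @return `x`, invisibly.
#' @export
set_setting <- function(x, key, value) {
  if (!is_string(key) || !nzchar(key)) stop_invalid("`key` must be a non-empty string")
  if (!json_compatible(value)) {
    stop_invalid(sprintf("value for '%s' is not JSON-serializable", key))
  }
  node <- settings_of(x)
  node$local[[key]] <- value
  invisible(x)
}

#' Load a JSON settings profile
#'
#' A settings profile is a plain-text JSON document holding one object of
#' session-level parameters. Keeping manipulations in a profile lets the
#' experimenter change the design (e.g., assessment duration, oscillation
#' amplitude) without touching code, and lets several variants of one task
#' live side by side as named profiles.
#'
#' `source` may be a file path or a zero-argument function returning JSON text,
#' so a remote fetcher (e.g., settings served from a web URL) can stand in for
#' a local file.
#'
#' @param source Path to a `.json` file, or a function returning its text.
#' @return A named list of settings. Nested objects are returned as nested
#'   named lists, verbatim.
#' @export
load_profile <- function(source) {
  txt <- if (is.function(source)) {
    paste(source(), collapse = "\n")
  } else if (is_string(source)) {
    if (!file.exists(source)) stop_invalid(sprintf("settings profile not found: %s", source))
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    stop_invalid("`source` must be a file path or a function returning JSON text")
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) tk_stop("tk_parse_error", sprintf("malformed settings profile: %s", conditionMessage(e)))
  )
  if (!is.list(parsed) || (length(parsed) > 0L && is.null(names(parsed)))) {
    tk_stop("tk_invalid_profile", "settings profile root must be a JSON object")
  }
  parsed
}

#' Locate a named profile in a config directory
#'
#' Profiles live as `<name>.json` files in a directory; the experimenter picks
#' one by name when launching a session (the command-line `--profile` flag).
#'
#' @param name Profile name, with or without the `.json` extension.
#' @param config_dir Directory holding profile files.
#' @return The profile file path.
#' @export
find_profile <- function(name, config_dir = ".") {
  fname <- if (grepl("\\.json$", name)) name else paste0(name, ".json")
  path <- file.path(config_dir, fname)
  if (!file.exists(path)) {
    tk_stop("tk_not_found", sprintf("no settings profile '%s' in %s", name, config_dir))
  }
  path
}

#' @export
print.settings_node <- function(x, ...) {
  cat(sprintf("<settings: %s> %d local key(s): %s\n",
              x$level, length(x$local), paste(names(x$local), collapse = ", ")))
  invisible(x)
}
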