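# Internal helpers: classed conditions, seeded RNG scopes, number formatting.

tk_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "trialkit_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_invalid <- function(message) tk_stop("tk_invalid_argument", message)
stop_lifecycle <- function(message) tk_stop("tk_lifecycle_error", message)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards
# so that seeded simulators never disturb the global stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-unit seed from a master seed, stable under changes in how many
# units are drawn and kept inside 32-bit integer range.
derive_seed <- function(master_seed, index, stream = 0L) {
  (as.double(master_seed) + 7919 * as.double(index) + 104729 * as.double(stream)) %% 2147483647
}

# Seconds with fixed 3-decimal serialization (millisecond resolution output).
fmt_time <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = 3))
}

# Scalar -> CSV cell. Logicals as lower-case true/false; NA as empty cell.
fmt_cell <- function(x) {
  if (length(x) != 1L || is.na(x)) return("")
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(format(x, scientific = FALSE, trim = TRUE, digits = 15))
  as.character(x)
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

csv_line <- function(cells) paste(csv_quote(as.character(cells)), collapse = ",")

monotonic_clock <- function() {
  function() unname(proc.time()["elapsed"])
}
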