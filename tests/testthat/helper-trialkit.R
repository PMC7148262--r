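# Shared fixtures: everything is generated in code at test time.

tmp_dir <- function(env = parent.frame()) {
  d <- tempfile("tk-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# A session on a simulation clock with a given block structure, ready to run.
new_test_session <- function(base_dir, blocks = c(5L, 5L), ...,
                             experiment = "exp", ppid = "P01") {
  s <- create_session(experiment, ppid, 1L, base_dir = base_dir,
                      clock = sim_clock(), ...)
  for (n in blocks) create_block(s, n_trials = n)
  s
}

run_all_trials <- function(session, duration = 1) {
  for (t in session$trials) {
    begin_trial(t)
    session$clock(advance = duration)
    end_trial(t)
  }
  invisible(session)
}

# Independent oracle: path length by explicit pairwise loop.
path_length_naive <- function(pos) {
  total <- 0
  for (i in seq_len(nrow(pos) - 1L)) {
    total <- total + sqrt(sum((pos[i + 1L, ] - pos[i, ])^2))
  }
  total
}

# Independent oracle: settings resolution by linear search of an explicit
# chain list (innermost first).
resolve_oracle <- function(chain_locals, key) {
  for (m in chain_locals) {
    if (key %in% names(m)) return(m[[key]])
  }
  NULL
}
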