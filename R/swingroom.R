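#' Swinging-room parameters
#'
#' Geometry and oscillation parameters of the virtual room used in the
#' moving-room postural-sway paradigm: the walls and ceiling of a simple room
#' pitch sinusoidally about the x-axis through the point on the floor at the
#' room's center, perturbing vision while the floor (and hence kinesthetic
#' information) stays fixed.
#'
#' @param amplitude_deg Oscillation amplitude in degrees (default 5).
#' @param freq_hz Oscillation frequency in Hz (default 0.25).
#' @param duration_s Trial duration in seconds (default 10).
#' @param sample_rate_hz Logging rate in Hz (default 90, a typical HMD refresh
#'   rate). `duration_s * sample_rate_hz` must be an integer.
#' @param height_m,width_m,depth_m Room dimensions in meters (default 3, 6, 6).
#' @return A list of class `swing_room_params`.
#' @export
swing_room_params <- function(amplitude_deg = 5, freq_hz = 0.25, duration_s = 10,
                              sample_rate_hz = 90, height_m = 3, width_m = 6,
                              depth_m = 6) {
  vals <- c(amplitude_deg = amplitude_deg, freq_hz = freq_hz,
            duration_s = duration_s, sample_rate_hz = sample_rate_hz,
            height_m = height_m, width_m = width_m, depth_m = depth_m)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("all swing-room parameters must be positive finite numbers")
  }
  n <- duration_s * sample_rate_hz
  if (abs(n - round(n)) > 1e-9) {
    stop_invalid("`duration_s * sample_rate_hz` must be an integer number of samples")
  }
  structure(list(amplitude_deg = amplitude_deg, freq_hz = freq_hz,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 height_m = height_m, width_m = width_m, depth_m = depth_m),
            class = "swing_room_params")
}

#' Synthetic sway-model parameters
#'
#' The human participants of the original paradigm are replaced here by an
#' explicitly invented stochastic head-sway model: a mean-reverting random
#' walk (discrete Ornstein-Uhlenbeck process) per axis, plus a visual-coupling
#' term that displaces the head along the anterior-posterior (z) axis in
#' proportion to the change in room pitch. The model is a stand-in chosen for
#' its two tunable directional effects -- children noisier than adults, an
#' oscillating room adding sway -- not for biomechanical realism.
#'
#' @param group `"adult"` or `"child"`; selects the default per-tick noise
#'   scale (0.8 mm for adults, 1.6 mm for children) when `noise_sd_m` is not
#'   given.
#' @param noise_sd_m Standard deviation, in meters, of the i.i.d. Gaussian
#'   per-axis displacement added each tick.
#' @param mean_reversion Fraction (0-1) of the displacement from rest pulled
#'   back each tick (default 0.02).
#' @param coupling_m_per_deg Head displacement along z, in meters, per degree
#'   of room-pitch change (default 0.002, i.e. 2 mm/deg).
#' @param rest_height_m Rest head height above the floor in meters (default
#'   1.6, a typical adult eye height; has no effect on path length).
#' @param seed RNG seed making a simulated trial reproducible.
#' @return A list of class `sway_params`.
#' @export
sway_params <- function(group = c("adult", "child"), noise_sd_m = NULL,
                        mean_reversion = 0.02, coupling_m_per_deg = 0.002,
                        rest_height_m = 1.6, seed = 1L) {
  group <- match.arg(group)
  if (is.null(noise_sd_m)) noise_sd_m <- if (group == "adult") 0.0008 else 0.0016
  if (!is.numeric(noise_sd_m) || noise_sd_m < 0) stop_invalid("`noise_sd_m` must be >= 0")
  if (!is.numeric(coupling_m_per_deg) || coupling_m_per_deg < 0) {
    stop_invalid("`coupling_m_per_deg` must be >= 0")
  }
  if (!is.numeric(mean_reversion) || mean_reversion < 0 || mean_reversion > 1) {
    stop_invalid("`mean_reversion` must lie in [0, 1]")
  }
  structure(list(group = group, noise_sd_m = noise_sd_m,
                 mean_reversion = mean_reversion,
                 coupling_m_per_deg = coupling_m_per_deg,
                 rest_height_m = rest_height_m, seed = seed),
            class = "sway_params")
}

#' Room pitch angle at time t
#'
#' In the oscillating condition the room pitches as
#' `amplitude_deg * sin(2 * pi * freq_hz * t)`; in the normal (static)
#' condition the angle is identically zero.
#'
#' @param t Time in seconds (vectorized, must be non-negative).
#' @param params A [swing_room_params()] object.
#' @param condition `"oscillating"` or `"normal"`.
#' @return Pitch angle(s) in degrees.
#' @examples
#' room_angle(1, swing_room_params()) # 5: peak of a 0.25 Hz sine at t = 1 s
#' @export
room_angle <- function(t, params = swing_room_params(),
                       condition = c("oscillating", "normal")) {
  condition <- match.arg(condition)
  if (any(t < 0)) stop_invalid("`t` must be non-negative")
  if (condition == "normal") return(rep(0, length(t)))
  params$amplitude_deg * sin(2 * pi * params$freq_hz * t)
}

#' Simulate one trial's head trajectory
#'
#' Generates `duration_s * sample_rate_hz` pose samples at trial-relative
#' times `0, 1/rate, 2/rate, ...`. Starting from rest, each tick updates the
#' head position as
#' \deqn{p_{i+1} = p_i + \lambda (rest - p_i) + \eta_i + c\,\Delta\theta_i\,\hat z}
#' with mean-reversion rate \eqn{\lambda}, i.i.d. Gaussian noise \eqn{\eta_i}
#' of per-axis scale `noise_sd_m`, visual coupling `c` (meters per degree)
#' acting on the z axis only, and \eqn{\Delta\theta_i} the change in room
#' pitch over the tick (zero in the normal condition). The trajectory is
#' deterministic given `sway$seed`.
#'
#' @param condition `"normal"` or `"oscillating"`.
#' @param sway A [sway_params()] object.
#' @param room A [swing_room_params()] object.
#' @return Data frame of samples: `time`, `pos_x`, `pos_y`, `pos_z` (meters),
#'   `rot_x`, `rot_y`, `rot_z` (degrees; zero -- head orientation is not
#'   modeled).
#' @export
simulate_sway_trial <- function(condition = c("normal", "oscillating"),
                                sway = sway_params(), room = swing_room_params()) {
  condition <- match.arg(condition)
  n <- as.integer(round(room$duration_s * room$sample_rate_hz))
  times <- (seq_len(n) - 1L) / room$sample_rate_hz
  theta <- room_angle(times, room, condition)
  drive_z <- sway$coupling_m_per_deg * diff(theta)   # per-step pitch change, n-1 steps

  eta <- with_seed(sway$seed,
                   matrix(stats::rnorm(3L * (n - 1L), sd = sway$noise_sd_m), ncol = 3L))
  decay <- 1 - sway$mean_reversion
  # deviation from rest per axis: d[i+1] = decay * d[i] + input[i], d[1] = 0
  ar1 <- function(input) {
    if (length(input) == 0L) return(numeric(0))
    as.numeric(stats::filter(input, decay, method = "recursive"))
  }
  rest <- c(0, sway$rest_height_m, 0)
  dx <- c(0, ar1(eta[, 1L]))
  dy <- c(0, ar1(eta[, 2L]))
  dz <- c(0, ar1(eta[, 3L] + drive_z))
  data.frame(
    time = times,
    pos_x = rest[1L] + dx,
    pos_y = rest[2L] + dy,
    pos_z = rest[3L] + dz,
    rot_x = 0, rot_y = 0, rot_z = 0
  )
}

#' Path length of a trajectory
#'
#' The sum of Euclidean distances between consecutive 3-D position samples --
#' the proxy measure of postural stability used in the moving-room paradigm
#' (a longer head path indicates more sway, i.e., worse stability). Rotation
#' columns, if present, are ignored.
#'
#' @param samples Data frame with `pos_x`, `pos_y`, `pos_z` columns (e.g.,
#'   from [simulate_sway_trial()]), or a numeric matrix with one position
#'   column per axis.
#' @return Path length in meters; 0 for a single sample.
#' @export
path_length <- function(samples) {
  pos <- if (is.data.frame(samples)) {
    if (!all(c("pos_x", "pos_y", "pos_z") %in% names(samples))) {
      stop_invalid("`samples` must have pos_x, pos_y, pos_z columns")
    }
    as.matrix(samples[, c("pos_x", "pos_y", "pos_z")])
  } else if (is.matrix(samples) && is.numeric(samples)) {
    samples
  } else {
    stop_invalid("`samples` must be a data frame or numeric matrix")
  }
  if (nrow(pos) < 1L) stop_invalid("`samples` must contain at least one sample")
  if (nrow(pos) == 1L) return(0)
  steps <- diff(pos)
  sum(sqrt(rowSums(steps^2)))
}

#' Dominant frequency of a uniformly sampled signal
#'
#' Location of the largest discrete-Fourier-transform magnitude over the
#' positive frequencies (DC excluded). Used to check that a generated room
#' oscillation concentrates its power at the configured frequency.
#'
#' @param x Numeric signal sampled at `sample_rate_hz`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Frequency in Hz of the spectral peak.
#' @export
dominant_frequency <- function(x, sample_rate_hz) {
  n <- length(x)
  if (n < 4L) stop_invalid("signal too short for a spectral estimate")
  mag <- Mod(stats::fft(x - mean(x)))
  half <- 2:(floor(n / 2) + 1L)
  k <- half[which.max(mag[half])]
  (k - 1L) * sample_rate_hz / n
}

#' Run the synthetic swinging-room study
#'
#' Simulates a cohort study of postural sway: `n_adults` + `n_children`
#' synthetic participants each perform one session of two trials -- a normal
#' (static room) and an oscillating condition, in per-participant random
#' order -- with the head pose logged through a tracker at the room's sample
#' rate and the per-trial path length stored as a behavioral result. Each
#' participant produces a full session directory (behavioral CSV, one
#' continuous CSV per trial, log), participants are upserted into the
#' registry, and a tidy summary is written to `study_results.csv` under
#' `base_dir`.
#'
#' Everything derives deterministically from `master_seed`: per-participant
#' substreams fix the condition order and the trial noise, and are stable
#' under changes in cohort size (participant `i` of a group keeps their data
#' when `n` grows).
#'
#' @param n_adults,n_children Participants per group (>= 1).
#' @param sway_adult,sway_child Group default [sway_params()]; the seeds they
#'   carry are ignored in favor of per-participant substreams. Children
#'   default to twice the adult noise scale.
#' @param room A [swing_room_params()] object.
#' @param base_dir Output directory for session data and the study summary.
#' @param master_seed Integer master seed.
#' @return Data frame with one row per trial: `ppid`, `group`, `condition`,
#'   `path_length_m`.
#' @export
run_study <- function(n_adults = 50L, n_children = 50L,
                      sway_adult = sway_params("adult"),
                      sway_child = sway_params("child"),
                      room = swing_room_params(),
                      base_dir = "data", master_seed = 1L) {
  if (!is_count(n_adults) || !is_count(n_children)) {
    stop_invalid("`n_adults` and `n_children` must be positive integers")
  }
  registry <- participant_registry(base_dir)
  rows <- vector("list", 2L * (n_adults + n_children))
  row_i <- 0L

  run_participant <- function(group, index, stream, sway) {
    ppid <- sprintf("%s%03d", if (group == "adult") "A" else "C", index)
    pseed <- derive_seed(master_seed, index, stream = stream)
    cond_order <- with_seed(pseed, sample(c("normal", "oscillating")))
    upsert_participant(registry, ppid, list(group = group))
    session <- create_session("swingroom", ppid, 1L,
                              settings = list(duration_s = room$duration_s,
                                              sample_rate_hz = room$sample_rate_hz),
                              base_dir = base_dir, overwrite = TRUE,
                              clock = sim_clock())
    attach_tracker(session, pos_rot_tracker("head"))
    log_setting(session, "condition")
    block <- create_block(session, n_trials = 0L)
    # Both conditions reuse the participant's intrinsic noise substream
    # (common random numbers): the condition contrast is then paired, as in
    # the within-participant design it emulates.
    trial_sway <- sway
    trial_sway$seed <- derive_seed(pseed, 1L, stream = stream + 10L)
    for (j in seq_along(cond_order)) {
      trial <- create_trial(block, settings = list(condition = cond_order[j]))
      traj <- simulate_sway_trial(cond_order[j], trial_sway, room)
      begin_trial(trial)
      record_many(session$trackers[[1L]], traj)
      session$clock(advance = room$duration_s)
      end_trial(trial)
      pl <- path_length(traj)
      add_result(trial, "path_length_m", pl)
      row_i <<- row_i + 1L
      rows[[row_i]] <<- data.frame(ppid = ppid, group = group,
                                   condition = cond_order[j],
                                   path_length_m = pl,
                                   stringsAsFactors = FALSE)
    }
    end_session(session)
  }

  for (i in seq_len(n_adults)) run_participant("adult", i, 1L, sway_adult)
  for (i in seq_len(n_children)) run_participant("child", i, 2L, sway_child)

  results <- do.call(rbind, rows)
  lines <- c(csv_line(names(results)),
             vapply(seq_len(nrow(results)), function(i) {
               csv_line(c(results$ppid[i], results$group[i], results$condition[i],
                          fmt_cell(results$path_length_m[i])))
             }, ""))
  dir.create(base_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, file.path(base_dir, "study_results.csv"), sep = "\n")
  results
}

#' Stimulus sequence of the number-doubling demonstration
#'
#' The ten stimuli of the worked two-block doubling task, in trial order.
#'
#' @return Integer vector of length 10.
#' @export
doubling_stimuli <- function() {
  c(8L, 3L, 4L, 7L, 4L, 9L, 5L, 10L, 6L, 3L)
}

#' Run the number-doubling demonstration session
#'
#' A minimal end-to-end session exercising the whole stack: the participant
#' sees a number `x` and must answer `2x`. The session is built as two blocks
#' (first `ceiling(n/2)` trials, then the rest) with a session-level setting
#' `manipulation = FALSE` overridden to `TRUE` at block 2 -- the cascade means
#' no per-trial storage of the flag -- and a per-trial setting `x`. The
#' `responder` function plays the participant, its answer stored as the
#' `response` result. The behavioral CSV therefore carries `manipulation`,
#' `x`, and `response` columns alongside numbering, timestamps, and identity.
#'
#' @param x_values Stimulus sequence (default [doubling_stimuli()]).
#' @param responder Function mapping a stimulus to a response (default exact
#'   doubling).
#' @param ppid,session_num,base_dir,overwrite Session identity and output
#'   location, as in [create_session()].
#' @param profile Optional settings profile (named list) for the session.
#' @param trial_duration_s Simulated duration of each trial; trials run back
#'   to back on a simulation clock, so trial `k` starts where `k - 1` ended.
#' @return Invisibly, a list with `dir` (the session directory) and `table`
#'   (the behavioral data frame).
#' @export
doubling_demo <- function(x_values = doubling_stimuli(),
                          responder = function(x) 2 * x,
                          ppid = "P01", session_num = 1L, base_dir = "data",
                          profile = NULL, overwrite = FALSE,
                          trial_duration_s = 1) {
  if (length(x_values) < 1L) stop_invalid("`x_values` must be non-empty")
  if (!is.function(responder)) stop_invalid("`responder` must be a function")
  n <- length(x_values)
  n1 <- ceiling(n / 2)
  session <- create_session("doubling", ppid, session_num,
                            settings = list(manipulation = FALSE),
                            base_dir = base_dir, profile = profile,
                            overwrite = overwrite, clock = sim_clock())
  log_setting(session, c("manipulation", "x"))
  b1 <- create_block(session)
  b2 <- create_block(session, settings = list(manipulation = TRUE))
  for (k in seq_len(n)) {
    block <- if (k <= n1) b1 else b2
    create_trial(block, settings = list(x = x_values[[k]]))
  }
  for (trial in session$trials) {
    begin_trial(trial)
    x <- resolve_setting(trial, "x")
    session$clock(advance = trial_duration_s)
    end_trial(trial)
    add_result(trial, "response", responder(x))
  }
  tbl <- behavioral_table(session)
  dir <- end_session(session)
  invisible(list(dir = dir, table = tbl))
}
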