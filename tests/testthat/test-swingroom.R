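test_that("the room pitch is a sinusoid with the configured amplitude and frequency", {
  room <- swing_room_params()
  expect_identical(room_angle(0, room), 0)
  expect_equal(room_angle(1, room), 5)            # quarter period of 0.25 Hz
  expect_equal(room_angle(3, room), -5)
  expect_identical(room_angle(c(0, 1, 2), room, condition = "normal"), c(0, 0, 0))
  expect_error(room_angle(-1, room), class = "tk_invalid_argument")

  # spectral peak of a 40-s trace at 90 Hz sits exactly at the driving frequency
  t <- seq(0, 40 - 1 / 90, by = 1 / 90)
  expect_equal(dominant_frequency(room_angle(t, room), 90), 0.25)
  expect_equal(max(abs(room_angle(t, room))), 5, tolerance = 1e-6)

  expect_error(swing_room_params(amplitude_deg = 0), class = "tk_invalid_argument")
  expect_error(swing_room_params(duration_s = 1.005, sample_rate_hz = 90),
               class = "tk_invalid_argument")
})

test_that("the sway simulator is seed-deterministic and degenerates correctly", {
  room <- swing_room_params()
  sway <- sway_params("adult", seed = 77)
  a <- simulate_sway_trial("oscillating", sway, room)
  b <- simulate_sway_trial("oscillating", sway, room)
  expect_identical(a, b)
  expect_identical(nrow(a), 900L)
  expect_identical(a$time, (0:899) / 90)

  # no noise, no coupling: the head never leaves rest
  still <- sway_params("adult", noise_sd_m = 0, coupling_m_per_deg = 0, seed = 1)
  traj <- simulate_sway_trial("oscillating", still, room)
  expect_identical(unique(traj$pos_x), 0)
  expect_identical(unique(traj$pos_y), still$rest_height_m)
  expect_identical(unique(traj$pos_z), 0)
  expect_identical(path_length(traj), 0)

  # no noise, coupling only: oscillating moves, normal does not, and with zero
  # mean reversion the path length has the closed form c * sum(|dtheta|)
  drv <- sway_params("adult", noise_sd_m = 0, mean_reversion = 0,
                     coupling_m_per_deg = 0.002, seed = 1)
  osc <- simulate_sway_trial("oscillating", drv, room)
  nor <- simulate_sway_trial("normal", drv, room)
  expect_identical(path_length(nor), 0)
  expect_gt(path_length(osc), 0)
  theta <- room_angle(a$time, room)
  expect_equal(path_length(osc), 0.002 * sum(abs(diff(theta))), tolerance = 1e-12)
})

test_that("the simulator's recursive update matches the naive step-by-step loop", {
  room <- swing_room_params(duration_s = 2)
  sway <- sway_params("child", seed = 13)
  traj <- simulate_sway_trial("oscillating", sway, room)

  n <- 180L
  times <- (0:179) / 90
  theta <- room_angle(times, room)
  eta <- trialkit:::with_seed(13, matrix(stats::rnorm(3 * (n - 1), sd = sway$noise_sd_m), ncol = 3))
  p <- c(0, sway$rest_height_m, 0)
  rest <- p
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- p
  for (i in seq_len(n - 1)) {
    p <- p + sway$mean_reversion * (rest - p) + eta[i, ] +
      c(0, 0, sway$coupling_m_per_deg * (theta[i + 1] - theta[i]))
    pos[i + 1, ] <- p
  }
  expect_equal(traj$pos_x, pos[, 1], tolerance = 1e-12)
  expect_equal(traj$pos_y, pos[, 2], tolerance = 1e-12)
  expect_equal(traj$pos_z, pos[, 3], tolerance = 1e-12)
})

test_that("path length matches the pairwise oracle and is frame-invariant", {
  expect_identical(path_length(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 0.1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(path_length(two), 0.1)
  expect_error(path_length(matrix(numeric(), 0, 3)), class = "tk_invalid_argument")

  set.seed(2024)
  for (rep in 1:5) {
    pos <- matrix(stats::rnorm(900 * 3), ncol = 3)
    pl <- path_length(pos)
    expect_equal(pl, path_length_naive(pos), tolerance = 1e-12)

    # translation of the frame
    shifted <- sweep(pos, 2, stats::rnorm(3, sd = 10), `+`)
    expect_equal(path_length(shifted), pl, tolerance = 1e-9)
    # rotation of the frame (random orthonormal basis)
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    expect_equal(path_length(pos %*% rot), pl, tolerance = 1e-9)
  }

  # data-frame input uses the position columns and ignores rotations
  df <- data.frame(pos_x = pos[, 1], pos_y = pos[, 2], pos_z = pos[, 3],
                   rot_x = 99, rot_y = 99, rot_z = 99)
  expect_equal(path_length(df), path_length(pos))
})

test_that("expected path length is non-decreasing in the noise scale", {
  room <- swing_room_params(duration_s = 2)
  levels <- c(0.0004, 0.0008, 0.0016, 0.0032)
  set.seed(6)
  seeds <- sample.int(2^31 - 1, 200)
  pl <- sapply(levels, function(nv) {
    vapply(seeds, function(sd) {
      path_length(simulate_sway_trial("normal", sway_params("adult", noise_sd_m = nv, seed = sd), room))
    }, 0)
  })
  means <- colMeans(pl)
  expect_true(all(diff(means) > 0))
  rank_cor <- stats::cor(rep(levels, each = 200), as.vector(pl), method = "spearman")
  expect_gt(rank_cor, 0)
})

test_that("with zero coupling the two conditions give identical traces at matched seeds", {
  room <- swing_room_params(duration_s = 2)
  sway <- sway_params("adult", coupling_m_per_deg = 0, seed = 21)
  expect_identical(simulate_sway_trial("oscillating", sway, room),
                   simulate_sway_trial("normal", sway, room))
})

test_that("a small study produces complete, joinable, reproducible output", {
  dir <- tmp_dir()
  room <- swing_room_params(duration_s = 2)
  res <- run_study(n_adults = 1, n_children = 1, room = room,
                   base_dir = dir, master_seed = 5)
  expect_identical(nrow(res), 4L)                      # 2 rows per participant
  expect_identical(sort(table(res$ppid)), sort(table(c("A001", "A001", "C001", "C001"))))
  expect_setequal(res$condition[res$ppid == "A001"], c("normal", "oscillating"))
  expect_true(all(res$path_length_m >= 0))

  # session directories carry behavioral + continuous files that join on trial_num
  sess_dir <- file.path(dir, "swingroom", "A001", "S001")
  beh <- utils::read.csv(file.path(sess_dir, "trial_results.csv"))
  expect_identical(beh$trial_num, 1:2)
  expect_setequal(beh$condition, c("normal", "oscillating"))
  for (tn in beh$trial_num) {
    cont <- utils::read.csv(file.path(sess_dir, sprintf("head_T%03d.csv", tn)))
    expect_identical(nrow(cont), 180L)                 # duration x rate
    expect_equal(path_length(cont), beh$path_length_m[beh$trial_num == tn],
                 tolerance = 1e-6)
  }
  expect_identical(length(validate_session(sess_dir)), 0L)

  # registry records both participants with their group
  reg <- participant_registry(dir)
  expect_identical(get_participant(reg, "C001")$group, "child")

  # the whole study is a pure function of the master seed
  dir2 <- tmp_dir()
  res2 <- run_study(n_adults = 1, n_children = 1, room = room,
                    base_dir = dir2, master_seed = 5)
  expect_identical(res, res2)
  expect_identical(readLines(file.path(dir, "study_results.csv")),
                   readLines(file.path(dir2, "study_results.csv")))
  # and participant 1's data is stable when the cohort grows
  dir3 <- tmp_dir()
  res3 <- run_study(n_adults = 2, n_children = 1, room = room,
                    base_dir = dir3, master_seed = 5)
  kept <- res3[res3$ppid %in% c("A001", "C001"), ]
  rownames(kept) <- NULL
  expect_identical(kept, res)
})

test_that("the doubling demo reproduces the worked example's structure", {
  dir <- tmp_dir()
  res <- doubling_demo(base_dir = dir)
  tbl <- res$table
  expect_identical(nrow(tbl), 10L)
  expect_identical(tbl$block_num, rep(1:2, each = 5))
  expect_identical(tbl$x, doubling_stimuli())
  expect_identical(tbl$response, 2L * doubling_stimuli())
  expect_identical(tbl$manipulation, rep(c("false", "true"), each = 5))

  # manipulation=true on block 2 comes from the block-level override, with no
  # per-trial storage: an extra trial added to block 2 resolves it by cascade
  s <- create_session("doubling", "P09", 1, settings = list(manipulation = FALSE),
                      base_dir = dir, clock = sim_clock())
  b2 <- create_block(create_session("d2", "P09", 1, base_dir = dir,
                                    clock = sim_clock()),
                     settings = list(manipulation = TRUE))
  t_extra <- create_trial(b2)
  expect_length(t_extra$settings$local, 0L)
  expect_true(resolve_setting(t_extra, "manipulation"))

  # identity responder: response column equals the stimulus column
  res_id <- doubling_demo(responder = function(x) x, ppid = "P02", base_dir = dir)
  expect_identical(res_id$table$response, res_id$table$x)

  # odd-length stimulus lists split ceiling/floor across the two blocks
  res_odd <- doubling_demo(x_values = 1:7, ppid = "P03", base_dir = dir)
  expect_identical(res_odd$table$block_num, rep(1:2, c(4, 3)))
})
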