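tg <- target_spec()

test_that("evaluation window starts where the hand leaves the start zone", {
  # trajectory that starts outside the zone: window starts at first sample
  st <- stationary_trajectory(x = 0, y = 0)
  w <- detect_window(st, tg)
  expect_equal(w$t_s, 0)
  expect_equal(w$t_e, 1.46)

  # ideal movement: exit after ~ 0.015 / 0.3762 s of arc (one-sample slack)
  tr <- ideal_trajectory(tg)
  w2 <- detect_window(tr, tg)
  expect_lt(abs(w2$t_s - 0.015 / 0.3762), 0.004)
  expect_equal(w2$t_e - w2$t_s, 1.46)

  # hand never leaves the zone -> error naming the trial
  at_start <- stationary_trajectory(x = 0, y = 0.1)
  expect_error(detect_window(at_start, tg), "never left the start zone")
  # too short to cover the window
  short <- dplyr::filter(ideal_trajectory(tg), t < 0.8)
  expect_error(detect_window(short, tg), "ends .* before")
})

test_that("instantaneous error is the Euclidean distance to the matched target point", {
  tr <- ideal_trajectory(tg)
  expect_equal(compute_err(tr, tg, c(0.1, 0.7, 1.3)), rep(0, 3),
               tolerance = 1e-12)
  # hand at centre vs target on the circle: error = radius
  st <- stationary_trajectory(0, 0)
  expect_equal(compute_err(st, tg, 0.5), 0.10, tolerance = 1e-12)
  # 3-4-5 triangle offset
  off <- dplyr::mutate(ideal_trajectory(tg), x = x + 0.03, y = y + 0.04)
  expect_equal(compute_err(off, tg, 0.5), 0.05, tolerance = 1e-12)
  expect_error(compute_err(st, tg, 99), "outside")
})

test_that("trial score is the affine time-average of the windowed error", {
  expect_equal(compute_trial_score(ideal_trajectory(tg), tg), 100,
               tolerance = 1e-9)
  # ERR == E_max everywhere -> 0
  expect_equal(compute_trial_score(stationary_trajectory(0, 0), tg), 0,
               tolerance = 1e-9)
  # ERR == E_max / 2 everywhere -> 50 (hand halfway to the centre)
  half <- dplyr::mutate(ideal_trajectory(tg), x = x / 2, y = y / 2)
  expect_equal(compute_trial_score(half, tg), 50, tolerance = 1e-9)
})

test_that("position error depends only on radial deviation", {
  expect_equal(compute_position_error(ideal_trajectory(tg), tg), 0,
               tolerance = 1e-12)
  out <- dplyr::mutate(ideal_trajectory(tg), x = 1.2 * x, y = 1.2 * y)
  expect_equal(compute_position_error(out, tg), 0.02, tolerance = 1e-12)
  # absolute value prevents inside/outside cancellation
  tr <- ideal_trajectory(tg)
  half_in <- dplyr::mutate(
    tr, f = ifelse(seq_len(dplyr::n()) %% 2 == 0, 0.8, 1.2),
    x = f * x, y = f * y, f = NULL
  )
  expect_equal(compute_position_error(half_in, tg), 0.02, tolerance = 1e-12)
  # a stopped clock at the right radius scores 0 even though timing is wrong
  frozen <- stationary_trajectory(x = 0.1 * cos(1), y = 0.1 * sin(1))
  expect_equal(compute_position_error(frozen, tg), 0, tolerance = 1e-12)
})

test_that("velocity estimation matches analytic derivatives", {
  tr <- ideal_trajectory(tg)
  vel <- estimate_velocity(tr)
  spd <- sqrt(vel$vx^2 + vel$vy^2)
  inner <- vel$t > 0.01 & vel$t < 1.6 # constant-speed portion, interior
  expect_lt(max(abs(spd[inner] - 0.3762)) / 0.3762, 0.001)

  st <- stationary_trajectory(0.05, 0)
  vst <- estimate_velocity(st)
  expect_equal(vst$vx, rep(0, nrow(vst)))
  expect_equal(vst$vy, rep(0, nrow(vst)))

  lin <- tibble::tibble(t = seq(0, 1, by = 0.01), x = t, y = 0)
  vlin <- estimate_velocity(lin)
  expect_equal(vlin$vx, rep(1, nrow(vlin)), tolerance = 1e-9)

  dup <- tibble::tibble(t = c(0, 0.1, 0.1, 0.2), x = 0, y = 0)
  expect_error(estimate_velocity(dup), "strictly increasing")
})

test_that("velocity error against the constant-speed target", {
  # matched velocity -> 0 (finite differences leave a tiny residual)
  expect_lt(compute_velocity_error(ideal_trajectory(tg), tg), 2e-4)
  # stationary hand -> the target speed itself
  expect_equal(compute_velocity_error(stationary_trajectory(0, 0), tg),
               0.3762, tolerance = 1e-9)
  # exactly opposite velocity -> twice the speed
  p0 <- target_position(tg, 0)
  mirrored <- dplyr::mutate(ideal_trajectory(tg),
                            x = 2 * p0$x - x, y = 2 * p0$y - y)
  expect_equal(compute_velocity_error(mirrored, tg), 2 * 0.3762,
               tolerance = 1e-3)
})

test_that("metrics are invariant to rotating the whole frame about the centre", {
  delta <- 0.7
  tcfg <- trajectory_config(radius_bias_factor = 1.13,
                            speed_bias_factor = 1.07)
  hand <- generate_trajectory(list(alpha = 0, beta = 0), 0, tcfg, tg)
  rot <- dplyr::mutate(hand,
    x0 = x, y0 = y,
    x = cos(delta) * x0 - sin(delta) * y0,
    y = sin(delta) * x0 + cos(delta) * y0,
    x0 = NULL, y0 = NULL
  )
  tg_rot <- target_spec(start_angle = pi / 2 + delta)
  expect_equal(compute_position_error(rot, tg_rot),
               compute_position_error(hand, tg), tolerance = 1e-10)
  expect_equal(compute_velocity_error(rot, tg_rot),
               compute_velocity_error(hand, tg), tolerance = 1e-10)
  expect_equal(compute_trial_score(rot, tg_rot),
               compute_trial_score(hand, tg), tolerance = 1e-10)
})

test_that("subsampling a noise-free trajectory barely changes the position error", {
  tr <- ideal_trajectory(tg)
  wob <- dplyr::mutate(tr,
    r0 = sqrt(x^2 + y^2), phi = atan2(y, x),
    r1 = r0 * (1.2 + 0.05 * sin(7 * phi)),
    x = r1 * cos(phi), y = r1 * sin(phi),
    r0 = NULL, r1 = NULL, phi = NULL
  )
  e_full <- compute_position_error(wob, tg)
  e_half <- compute_position_error(wob[seq(1, nrow(wob), by = 2), ], tg)
  expect_lt(abs(e_full - e_half) / e_full, 0.01)
})

test_that("score of 100 happens iff the windowed error vanishes", {
  tr <- ideal_trajectory(tg)
  w <- detect_window(tr, tg)
  expect_equal(max(compute_err(tr, tg, tr$t[w$idx])), 0, tolerance = 1e-12)
  nudged <- dplyr::mutate(tr, x = x + 1e-4)
  expect_lt(compute_trial_score(nudged, tg), 100)
})

test_that("metrics_table evaluates only non-excluded trials but counts all", {
  cfg <- generator_config(n_subjects = 2, trials_per_session = 5,
                          seed = 4)
  traj <- generate_trajectories(cfg)
  # flag one specific trial excluded
  traj$excluded <- traj$subject == "S01" & traj$session == 0 & traj$trial == 3
  mt <- metrics_table(traj)
  expect_equal(nrow(mt), 2 * 2 * 5 - 1)
  counts <- trial_counts(mt)
  c_s01_0 <- dplyr::filter(counts, subject == "S01", session == 0)
  expect_equal(c_s01_0$n_trials, 5)
  expect_equal(c_s01_0$n_evaluated, 4)

  empty <- metrics_table(traj[0, ])
  expect_equal(nrow(empty), 0)
})
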