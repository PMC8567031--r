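test_that("degenerate noise collapses latents to their closed forms", {
  cfg <- generator_config(n_subjects = 5, sigma_alpha = 0, sigma_beta = 0,
                          seed = 1)
  lat <- draw_subject_latents(cfg)
  expect_equal(lat$beta, rep(cfg$mu_beta, 5))
  expect_equal(lat$alpha, rep(cfg$theta * cfg$mu_beta + cfg$gamma, 5))

  # theta = 0 decouples alpha from beta entirely
  cfg0 <- generator_config(n_subjects = 5, theta = 0, sigma_alpha = 0,
                           seed = 2)
  lat0 <- draw_subject_latents(cfg0)
  expect_equal(lat0$alpha, rep(cfg0$gamma, 5))
  expect_gt(sd(lat0$beta), 0)
})

test_that("latent moments match the generative equations (law of large numbers)", {
  cfg <- generator_config(
    n_subjects = 10000, theta = -1.0, gamma = 0.019, mu_beta = -0.002,
    sigma_beta = 0.006, sigma_alpha = 0.002, seed = 42
  )
  lat <- draw_subject_latents(cfg)
  # E[alpha] = theta * mu_beta + gamma = 0.021
  se_alpha <- sqrt(cfg$theta^2 * cfg$sigma_beta^2 + cfg$sigma_alpha^2) /
    sqrt(cfg$n_subjects)
  expect_lt(abs(mean(lat$alpha) - 0.021), 3 * se_alpha)
  expect_lt(abs(mean(lat$beta) - cfg$mu_beta),
            3 * cfg$sigma_beta / sqrt(cfg$n_subjects))
  # negative coupling shows up as a negative alpha-beta correlation
  expect_lt(cor(lat$alpha, lat$beta), 0)
  # sd(alpha)^2 = theta^2 sigma_beta^2 + sigma_alpha^2
  expect_equal(sd(lat$alpha),
               sqrt(cfg$theta^2 * cfg$sigma_beta^2 + cfg$sigma_alpha^2),
               tolerance = 0.05)
})

test_that("metric dataset has the session structure and exact noise-free values", {
  cfg <- generator_config(n_subjects = 4, trials_per_session = 6,
                          sigma_obs = 0, seed = 3)
  d <- generate_metric_dataset(cfg)
  lat <- attr(d, "latents")
  expect_equal(nrow(d), 4 * 2 * 6)
  s0 <- dplyr::filter(d, session == 0)
  expect_equal(s0$y, lat$alpha[match(s0$subject, lat$subject)])
  s1 <- dplyr::filter(d, session == 1)
  expect_equal(
    s1$y,
    (lat$alpha + lat$beta)[match(s1$subject, lat$subject)]
  )
})

test_that("evaluated-row count and exclusion bookkeeping", {
  cfg <- generator_config(n_subjects = 20, trials_per_session = 15,
                          exclusion_rate = 0, seed = 5)
  d <- generate_metric_dataset(cfg)
  expect_equal(sum(!d$excluded), 600)

  cfg_ex <- generator_config(n_subjects = 20, trials_per_session = 15,
                             exclusion_rate = 0.3, seed = 5)
  d_ex <- generate_metric_dataset(cfg_ex)
  expect_equal(nrow(d_ex), 600) # excluded trials are emitted, not dropped
  expect_true(all(is.na(d_ex$y[d_ex$excluded])))
  expect_true(all(!is.na(d_ex$y[!d_ex$excluded])))
  expect_gt(sum(d_ex$excluded), 0)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_subjects = 6, seed = 11, exclusion_rate = 0.1)
  expect_identical(generate_metric_dataset(cfg), generate_metric_dataset(cfg))
  expect_identical(draw_subject_latents(cfg), draw_subject_latents(cfg))
  tcfg <- trajectory_config(kinematic_noise_sd = 0.003)
  lat <- list(alpha = 0.02, beta = -0.005)
  expect_identical(generate_trajectory(lat, 1, tcfg, seed = 7),
                   generate_trajectory(lat, 1, tcfg, seed = 7))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_subjects = 1), "n_subjects")
  expect_error(generator_config(trials_per_session = 0), "trials")
  expect_error(generator_config(sigma_obs = -1), "sigma_obs")
  expect_error(generator_config(exclusion_rate = 1), "exclusion_rate")
})

test_that("trajectory biases map onto the position metric", {
  tg <- target_spec()
  # perfect subject: zero bias, zero noise
  tr0 <- generate_trajectory(list(alpha = 0, beta = 0), 0,
                             trajectory_config(radius_bias_factor = 1))
  expect_equal(compute_position_error(tr0, tg), 0, tolerance = 1e-12)
  # constant radial offset: bias 1.2 on a 10 cm circle -> E_p = 2 cm
  tr <- generate_trajectory(list(alpha = 0, beta = 0), 0,
                            trajectory_config(radius_bias_factor = 1.2))
  expect_equal(compute_position_error(tr, tg), 0.02, tolerance = 1e-12)
  # latent-driven bias recovers alpha + beta * session
  lat <- list(alpha = 0.02, beta = -0.008)
  tr1 <- generate_trajectory(lat, 1)
  expect_equal(compute_position_error(tr1, tg), 0.012, tolerance = 1e-12)
})

test_that("noisy trajectories recover the folded-normal position error", {
  tg <- target_spec()
  tcfg <- trajectory_config(radius_bias_factor = 1.2,
                            kinematic_noise_sd = 0.003)
  reps <- vapply(1:100, function(i) {
    tr <- generate_trajectory(list(alpha = 0, beta = 0), 0, tcfg, tg,
                              seed = 1000 + i)
    compute_position_error(tr, tg)
  }, numeric(1))
  # radial deviation ~ N(m = 0.02, s = 0.003); E|.| is the folded-normal mean
  m <- 0.02; s <- 0.003
  folded <- s * sqrt(2 / pi) * exp(-m^2 / (2 * s^2)) +
    m * (1 - 2 * pnorm(-m / s))
  expect_lt(abs(mean(reps) - folded) / folded, 0.10)
})

test_that("trajectory round trip: latent -> trajectories -> metrics recovers means", {
  cfg <- generator_config(n_subjects = 3, trials_per_session = 4,
                          gamma = 0.022, sigma_obs = 0, seed = 9)
  traj <- generate_trajectories(cfg, trajectory_config(kinematic_noise_sd = 0.002))
  lat <- attr(traj, "latents")
  mt <- metrics_table(traj)
  means <- mt |>
    dplyr::group_by(subject, session) |>
    dplyr::summarise(e_p = mean(e_p), .groups = "drop")
  truth <- lat$alpha[match(means$subject, lat$subject)] +
    lat$beta[match(means$subject, lat$subject)] * means$session
  # kinematic noise inflates |r_h - r| slightly; tolerance covers it
  expect_lt(max(abs(means$e_p - truth)), 0.0015)
})

test_that("simulate_study assembles both metrics with shared exclusions", {
  st <- simulate_study(
    generator_config(n_subjects = 5, trials_per_session = 4,
                     exclusion_rate = 0.2),
    seed = 21
  )
  expect_named(st, c("subject", "session", "trial", "e_p", "e_v", "excluded"))
  expect_equal(nrow(st), 5 * 2 * 4)
  expect_true(all(is.na(st$e_p[st$excluded])))
  expect_true(all(is.na(st$e_v[st$excluded])))
  # velocity scale is roughly an order of magnitude above position
  expect_gt(mean(st$e_v, na.rm = TRUE), 3 * mean(st$e_p, na.rm = TRUE))
})
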