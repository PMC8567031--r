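test_that("model structure exposes the expected free parameters", {
  d <- small_data(n_subjects = 5, trials = 3, seed = 1)
  f1 <- suppressWarnings(
    fit_skill_model(d, 1, config = quick_fit(iter = 100, warmup = 50))
  )
  expect_setequal(colnames(f1$draws), c("alpha", "beta", "sigma"))

  f4 <- suppressWarnings(
    fit_skill_model(d, 4, config = quick_fit(iter = 100, warmup = 50))
  )
  J <- 5
  expect_equal(ncol(f4$draws), 2 * J + 6) # alphas, betas, theta, gamma,
                                          # mu_beta, sigma_alpha, sigma_beta, sigma
  expect_true(all(c("theta", "gamma", "mu_beta", "sigma_alpha",
                    "sigma_beta", "sigma") %in% colnames(f4$draws)))
  expect_true(all(f4$draws[, "sigma"] > 0))
  expect_true(all(f4$draws[, "sigma_alpha"] > 0))

  f2 <- suppressWarnings(
    fit_skill_model(d, 2, config = quick_fit(iter = 100, warmup = 50))
  )
  expect_equal(ncol(f2$draws), 1 + J + 3)
  f3 <- suppressWarnings(
    fit_skill_model(d, 3, config = quick_fit(iter = 100, warmup = 50))
  )
  expect_equal(ncol(f3$draws), J + 4)
})

test_that("fitting is reproducible under a fixed seed", {
  d <- small_data(seed = 2)
  f_a <- suppressWarnings(
    fit_skill_model(d, 2, config = quick_fit(seed = 7, iter = 200,
                                             warmup = 100))
  )
  f_b <- suppressWarnings(
    fit_skill_model(d, 2, config = quick_fit(seed = 7, iter = 200,
                                             warmup = 100))
  )
  expect_identical(f_a$draws, f_b$draws)
})

test_that("a subject missing one session triggers an identifiability warning", {
  d <- small_data(n_subjects = 4, trials = 3, seed = 3)
  d1 <- dplyr::filter(d, !(subject == "S01" & session == 1))
  w <- testthat::capture_warnings(
    fit_skill_model(d1, 4, config = quick_fit(iter = 100, warmup = 50))
  )
  expect_true(any(grepl("lack trials", w)))
})

test_that("pointwise log-likelihood equals the direct normal density", {
  data <- tibble::tibble(
    subject = c("A", "A", "B"), session = c(0L, 1L, 0L),
    trial = 1:3, y = c(0.02, 0.015, 0.03)
  )
  draws <- cbind(alpha = c(0.02, 0.025), beta = c(-0.005, 0.0),
                 sigma = c(0.01, 0.02))
  fit <- fake_fit(draws, data, model = 1)
  ll <- pointwise_loglik(fit, data)
  manual <- matrix(NA_real_, 2, 3)
  for (s in 1:2) for (i in 1:3) {
    manual[s, i] <- dnorm(data$y[i],
                          draws[s, "alpha"] + draws[s, "beta"] * data$session[i],
                          draws[s, "sigma"], log = TRUE)
  }
  expect_equal(ll, manual, tolerance = 1e-12)

  # observation exactly at the draw's mean: log density = -log(sigma*sqrt(2*pi))
  at_peak <- tibble::tibble(subject = "A", session = 0L, trial = 1L, y = 0.02)
  ll_peak <- pointwise_loglik(fake_fit(draws, at_peak), at_peak)
  expect_equal(ll_peak[1, 1], -log(0.01 * sqrt(2 * pi)), tolerance = 1e-12)
  # doubling sigma lowers the peak log density by log 2
  draws2 <- draws; draws2[, "sigma"] <- 2 * draws[, "sigma"]
  ll2 <- pointwise_loglik(fake_fit(draws2, at_peak), at_peak)
  expect_equal(ll_peak[1, 1] - ll2[1, 1], log(2), tolerance = 1e-12)
})

test_that("per-subject draws are matched to the right observations", {
  data <- tibble::tibble(
    subject = c("A", "B"), session = c(0L, 0L), trial = 1:2, y = c(0.1, 0.2)
  )
  draws <- cbind(`alpha[1]` = c(0.1, 0.1), `alpha[2]` = c(0.2, 0.2),
                 `beta[1]` = c(0, 0), `beta[2]` = c(0, 0),
                 sigma = c(0.05, 0.05))
  ll <- pointwise_loglik(fake_fit(draws, data, model = 4), data)
  expect_equal(ll[1, 1], dnorm(0.1, 0.1, 0.05, log = TRUE))
  expect_equal(ll[1, 2], dnorm(0.2, 0.2, 0.05, log = TRUE))
})

test_that("pooled model recovers the generative slope on near-noiseless data", {
  cfg <- generator_config(n_subjects = 8, trials_per_session = 10,
                          sigma_alpha = 0, sigma_beta = 0,
                          sigma_obs = 1e-4, seed = 8)
  d <- as_skill_data(generate_metric_dataset(cfg))
  fit <- fit_skill_model(d, 1, config = quick_fit(seed = 8))
  beta_hat <- mean(fit$draws[, "beta"])
  beta_sd <- sd(fit$draws[, "beta"])
  expect_lt(abs(beta_hat - cfg$mu_beta), 2 * beta_sd)
  expect_lt(abs(beta_hat - cfg$mu_beta), 1e-4)
})

test_that("identical sessions give a slope posterior concentrated at zero", {
  cfg <- generator_config(n_subjects = 6, trials_per_session = 8,
                          mu_beta = 0, sigma_beta = 0, seed = 10)
  d <- as_skill_data(generate_metric_dataset(cfg))
  # make the two sessions literally identical
  d$y[d$session == 1] <- d$y[d$session == 0]
  fit <- fit_skill_model(d, 1, config = quick_fit(seed = 10))
  expect_lt(abs(mean(fit$draws[, "beta"])), 3 * sd(fit$draws[, "beta"]))
  expect_lt(sd(fit$draws[, "beta"]), sd(d$y))
})

test_that("sigma posterior concentrates on the generative noise as trials grow", {
  fits <- lapply(c(15, 150), function(k) {
    cfg <- generator_config(n_subjects = 8, trials_per_session = k, seed = 12)
    d <- as_skill_data(generate_metric_dataset(cfg))
    suppressWarnings(
      fit_skill_model(d, 4, config = quick_fit(seed = 12, iter = 800,
                                               warmup = 400))
    )
  })
  post_sd <- vapply(fits, function(f) sd(f$draws[, "sigma"]), numeric(1))
  expect_lt(post_sd[2], post_sd[1] / 2) # 10x the data shrinks the posterior
  expect_lt(abs(mean(fits[[2]]$draws[, "sigma"]) - 0.005), 0.05 * 0.005)
})

test_that("variational and MCMC posteriors agree for the pooled model", {
  cfg <- generator_config(
    n_subjects = 10, trials_per_session = 100, metric = "velocity",
    sigma_alpha = 0, sigma_beta = 0, mu_beta = -0.02, seed = 14
  )
  d <- as_skill_data(generate_metric_dataset(cfg))
  f_mcmc <- fit_skill_model(d, 1, config = quick_fit(seed = 14, iter = 1000,
                                                     warmup = 500))
  f_vi <- fit_skill_model(d, 1,
                          config = fit_config(method = "vi", seed = 14,
                                              vi_iterations = 4000,
                                              vi_draws = 4000))
  for (p in c("alpha", "beta", "sigma")) {
    m_ref <- mean(f_mcmc$draws[, p])
    expect_lt(abs(mean(f_vi$draws[, p]) - m_ref) / abs(m_ref), 0.05)
  }
})

test_that("model 4 with theta fixed at 0 matches model 3 (gamma <-> mu_alpha)", {
  # slope-homogeneous data so the two slope structures coincide
  cfg <- generator_config(n_subjects = 10, trials_per_session = 15,
                          sigma_beta = 0, seed = 16)
  d <- as_skill_data(generate_metric_dataset(cfg))
  f3 <- suppressWarnings(
    fit_skill_model(d, 3, config = quick_fit(seed = 16, iter = 1500,
                                             warmup = 500))
  )
  f4 <- suppressWarnings(
    fit_skill_model(d, 4, theta_fixed = 0,
                    config = quick_fit(seed = 17, iter = 1500,
                                       warmup = 500))
  )
  expect_false("theta" %in% colnames(f4$draws))
  g4 <- f4$draws[, "gamma"]
  a3 <- f3$draws[, "mu_alpha"]
  pooled_sd <- sqrt((sd(g4)^2 + sd(a3)^2) / 2)
  expect_lt(abs(mean(g4) - mean(a3)), 0.5 * pooled_sd)
  # population slope agrees with model 3's common slope
  expect_lt(abs(mean(f4$draws[, "mu_beta"]) - mean(f3$draws[, "beta"])),
            0.5 * sqrt((sd(f4$draws[, "mu_beta"])^2 +
                          sd(f3$draws[, "beta"])^2) / 2))
})
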