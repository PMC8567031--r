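# shared fixtures: small configs and hand-built objects

# short sampler settings for unit tests (2 chains keep R-hat available)
quick_fit <- function(seed = 1, iter = 600, warmup = 300, chains = 2) {
  fit_config(chains = chains, iter = iter, warmup = warmup, adapt = 300,
             seed = seed)
}

# small synthetic dataset at the position scale
small_data <- function(n_subjects = 6, trials = 5, seed = 1, ...) {
  cfg <- generator_config(n_subjects = n_subjects, trials_per_session = trials,
                          seed = seed, ...)
  as_skill_data(generate_metric_dataset(cfg))
}

# a minimal skill_fit with hand-specified draws, for log-lik/boundary tests
fake_fit <- function(draws, data, model = 1) {
  subjects <- sort(unique(as.character(data$subject)))
  fit <- list(
    model = model, method = "mcmc", draws = draws, mcmc = NULL,
    diagnostics = tibble::tibble(parameter = colnames(draws),
                                 rhat = NA_real_, ess = NA_real_),
    subjects = subjects, data = data, priors = prior_config(),
    config = NULL, seed = 1, theta_fixed = NULL, metric = "position"
  )
  class(fit) <- "skill_fit"
  fit
}

# ideal hand trajectory: exactly the reference movement
ideal_trajectory <- function(target = target_spec(), duration = 1.998,
                             rate = 500) {
  tr <- target_position(target, seq(0, duration, by = 1 / rate))
  dplyr::mutate(tr, subject = "S01", session = 0L, trial = 1L)
}

# stationary hand at a fixed point (outside the start zone by default)
stationary_trajectory <- function(x = 0, y = 0, duration = 1.6, rate = 500) {
  tibble::tibble(
    subject = "S01", session = 0L, trial = 1L,
    t = seq(0, duration, by = 1 / rate), x = x, y = y
  )
}
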