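#' Target circle specification
#'
#' Geometry and kinematics of the reference movement: a circle of radius
#' `radius` drawn counter-clockwise from the 12 o'clock position at constant
#' peripheral speed. The reference completes one full revolution in
#' \eqn{2\pi r / \|v\|} seconds (about 1.67 s at the defaults) and then rests
#' at the start point; the trial itself lasts `duration` seconds. The
#' acceleration/deceleration period applies to the robot guidance phase, not
#' to the constant-speed scoring reference.
#'
#' @param radius target circle radius in metres (default 0.10).
#' @param center numeric length-2, workspace centre in metres.
#' @param peripheral_speed target speed along the circle in m/s
#'   (default 0.3762).
#' @param duration nominal trial duration in seconds (default 2.0).
#' @param accel_decel_period robot guidance ramp time in seconds
#'   (default 0.2; metadata only).
#' @param start_angle angular start position in radians measured from the
#'   +x axis (default `pi/2`, i.e. 12 o'clock).
#' @return an object of class `target_spec`.
#' @examples
#' tg <- target_spec()
#' target_position(tg, c(0, 0.5, 1))
#' @export
target_spec <- function(radius = 0.10, center = c(0, 0),
                        peripheral_speed = 0.3762, duration = 2.0,
                        accel_decel_period = 0.2, start_angle = pi / 2) {
  stopifnot(
    radius > 0, peripheral_speed > 0,
    length(center) == 2, is.finite(center),
    duration > 2 * accel_decel_period
  )
  structure(
    list(
      radius = radius, center = as.numeric(center),
      peripheral_speed = peripheral_speed, duration = duration,
      accel_decel_period = accel_decel_period, start_angle = start_angle,
      direction = "ccw"
    ),
    class = "target_spec"
  )
}

#' Synthetic study generator configuration
#'
#' Parameters of the generative model behind the synthetic study data. Each
#' subject \eqn{j} has a session-to-session change
#' \eqn{\beta_j \sim N(\mu_\beta, \sigma_\beta^2)} and an initial skill
#' level coupled to it, \eqn{\alpha_j = \theta \beta_j + \gamma +
#' N(0, \sigma_\alpha^2)}; each trial observation is
#' \eqn{y = \alpha_j + \beta_j x + N(0, \sigma_{obs}^2)} with session
#' \eqn{x \in \{0, 1\}}. Defaults emulate the study conditions at the
#' position-error scale (boundary \eqn{\gamma} = 0.019 m); `metric =
#' "velocity"` switches to defaults at the velocity-error scale (boundary
#' 0.175 m/s), scaled by the ratio of the two boundaries.
#'
#' @param n_subjects number of subjects (default 20).
#' @param trials_per_session trials per session (default 15).
#' @param theta intercept-slope coupling coefficient (default -1).
#' @param gamma true initial-skill boundary, metric units.
#' @param mu_beta population mean slope, metric units.
#' @param sigma_beta slope SD across subjects, metric units.
#' @param sigma_alpha residual intercept SD around the coupling line.
#' @param sigma_obs trial-level observation noise SD.
#' @param exclusion_rate probability a trial is flagged as having left the
#'   safe area (excluded from evaluation but still counted), default 0.
#' @param metric `"position"` (metres) or `"velocity"` (m/s); selects the
#'   default scale for the parameters left `NULL`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return an object of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 1)
#' head(draw_subject_latents(cfg))
#' @export
generator_config <- function(n_subjects = 20, trials_per_session = 15,
                             theta = -1.0, gamma = NULL, mu_beta = NULL,
                             sigma_beta = NULL, sigma_alpha = NULL,
                             sigma_obs = NULL, exclusion_rate = 0,
                             metric = c("position", "velocity"),
                             seed = NULL) {
  metric <- match.arg(metric)
  defaults <- if (metric == "position") {
    list(gamma = 0.019, mu_beta = -0.002, sigma_beta = 0.006,
         sigma_alpha = 0.002, sigma_obs = 0.005)
  } else {
    list(gamma = 0.175, mu_beta = -0.018, sigma_beta = 0.055,
         sigma_alpha = 0.018, sigma_obs = 0.045)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    trials_per_session = as.integer(trials_per_session),
    theta = theta,
    gamma = gamma %||% defaults$gamma,
    mu_beta = mu_beta %||% defaults$mu_beta,
    sigma_beta = sigma_beta %||% defaults$sigma_beta,
    sigma_alpha = sigma_alpha %||% defaults$sigma_alpha,
    sigma_obs = sigma_obs %||% defaults$sigma_obs,
    exclusion_rate = exclusion_rate,
    metric = metric,
    seed = seed
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 2) {
    stop("generator_config: n_subjects must be >= 2", call. = FALSE)
  }
  if (cfg$trials_per_session < 1) {
    stop("generator_config: trials_per_session must be >= 1", call. = FALSE)
  }
  for (nm in c("sigma_beta", "sigma_alpha", "sigma_obs")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop(sprintf("generator_config: %s must be a finite non-negative SD", nm),
           call. = FALSE)
    }
  }
  if (cfg$exclusion_rate < 0 || cfg$exclusion_rate >= 1) {
    stop("generator_config: exclusion_rate must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Trajectory generator configuration
#'
#' Controls how a latent skill level is turned into a noisy drawn circle.
#' The hand moves on a circle whose radius is the target radius times
#' `radius_bias_factor` and whose angular progression is the target's times
#' `speed_bias_factor`, plus isotropic Gaussian noise on every sample. When
#' `radius_bias_factor` is `NULL` it is derived from the subject's latent
#' position error so that the metrics stage recovers
#' \eqn{E_p \approx \alpha_j + \beta_j \cdot session}.
#'
#' @param radius_bias_factor multiplicative radius distortion, or `NULL` to
#'   derive it from the subject latents.
#' @param speed_bias_factor multiplicative angular-speed distortion
#'   (default 1).
#' @param kinematic_noise_sd isotropic per-sample position noise SD in
#'   metres (default 0).
#' @param sample_rate sampling rate in Hz (default 500).
#' @param duration recorded trial duration in seconds (default 2.0).
#' @return an object of class `trajectory_config`.
#' @export
trajectory_config <- function(radius_bias_factor = NULL,
                              speed_bias_factor = 1,
                              kinematic_noise_sd = 0,
                              sample_rate = 500, duration = 2.0) {
  stopifnot(
    sample_rate > 0, duration > 0,
    kinematic_noise_sd >= 0, speed_bias_factor > 0,
    is.null(radius_bias_factor) || radius_bias_factor > 0
  )
  structure(
    list(
      radius_bias_factor = radius_bias_factor,
      speed_bias_factor = speed_bias_factor,
      kinematic_noise_sd = kinematic_noise_sd,
      sample_rate = sample_rate, duration = duration
    ),
    class = "trajectory_config"
  )
}

#' Prior configuration for the skill-change models
#'
#' Every prior choice is explicit and overridable. Scalar fixed effects get
#' vague normals parameterised by *precision* (BUGS convention:
#' `fixed_effect_precision = 1e-5` means SD about 316). Scale parameters
#' (\eqn{\sigma, \sigma_\alpha, \sigma_\beta}) get half-Cauchy priors with
#' scale `half_cauchy_scale`, in the metric's units. The coupling
#' coefficients \eqn{\theta} and \eqn{\gamma} get flat priors; in the MCMC
#' backend flatness is realised as a uniform on `[-flat_bound, flat_bound]`,
#' wide relative to the data scale.
#'
#' @param fixed_effect_precision precision of the vague normal prior on
#'   scalar intercepts/slopes and hypermeans (default 1e-5).
#' @param half_cauchy_scale half-Cauchy scale for all SD parameters
#'   (default 5, in metric units — effectively flat for metre-scale data).
#' @param flat_bound half-width of the uniform standing in for the flat
#'   prior on theta and gamma (default 100).
#' @param interval_prob credible-interval mass used downstream
#'   (default 0.94).
#' @param interval_method `"hdi"` or `"eti"`.
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(fixed_effect_precision = 1e-5,
                         half_cauchy_scale = 5,
                         flat_bound = 100,
                         interval_prob = 0.94,
                         interval_method = c("hdi", "eti")) {
  stopifnot(
    fixed_effect_precision > 0, half_cauchy_scale > 0, flat_bound > 0,
    interval_prob > 0, interval_prob < 1
  )
  structure(
    list(
      fixed_effect_precision = fixed_effect_precision,
      half_cauchy_scale = half_cauchy_scale,
      flat_bound = flat_bound,
      interval_prob = interval_prob,
      interval_method = match.arg(interval_method)
    ),
    class = "prior_config"
  )
}

#' Sampler configuration
#'
#' @param method `"mcmc"` (JAGS Gibbs sampling) or `"vi"` (mean-field
#'   variational approximation).
#' @param chains MCMC chains (default 4).
#' @param iter posterior draws per chain after warmup (default 2000).
#' @param warmup warmup/burn-in iterations per chain (default 1000).
#' @param adapt JAGS adaptation iterations (default 500).
#' @param vi_iterations optimisation steps for the variational fit
#'   (default 5000).
#' @param vi_samples Monte Carlo gradient samples per step (default 4).
#' @param vi_draws posterior draws sampled from the fitted variational
#'   approximation (default 2000).
#' @param seed integer seed for the sampler RNG.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(method = c("mcmc", "vi"), chains = 4, iter = 2000,
                       warmup = 1000, adapt = 500, vi_iterations = 5000,
                       vi_samples = 4, vi_draws = 2000, seed = 1) {
  stopifnot(
    chains >= 1, iter >= 2, warmup >= 0, adapt >= 100,
    vi_iterations >= 10, vi_samples >= 1, vi_draws >= 2
  )
  structure(
    list(
      method = match.arg(method), chains = as.integer(chains),
      iter = as.integer(iter), warmup = as.integer(warmup),
      adapt = as.integer(adapt), vi_iterations = as.integer(vi_iterations),
      vi_samples = as.integer(vi_samples), vi_draws = as.integer(vi_draws),
      seed = as.integer(seed)
    ),
    class = "fit_config"
  )
}
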