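#' Draw subject-level latent parameters
#'
#' For each subject: slope \eqn{\beta_j \sim N(\mu_\beta, \sigma_\beta^2)}
#' and intercept \eqn{\alpha_j = \theta \beta_j + \gamma +
#' N(0, \sigma_\alpha^2)}. With \eqn{\theta < 0}, subjects whose initial
#' error \eqn{\alpha_j} lies above the boundary \eqn{\gamma} have negative
#' slopes, i.e. improve after training.
#'
#' @param config a [generator_config()].
#' @return tibble with columns `subject` (character), `alpha`, `beta`.
#' @examples
#' draw_subject_latents(generator_config(n_subjects = 4, seed = 1))
#' @export
draw_subject_latents <- function(config) {
  validate_generator_config(config)
  run <- function() {
    n <- config$n_subjects
    beta <- rnorm(n, config$mu_beta, config$sigma_beta)
    alpha <- config$theta * beta + config$gamma + rnorm(n, 0, config$sigma_alpha)
    tibble::tibble(
      subject = sprintf("S%02d", seq_len(n)),
      alpha = alpha,
      beta = beta
    )
  }
  if (is.null(config$seed)) run() else
    withr::with_seed(stage_seed(config$seed, "latents"), run())
}

#' Generate a synthetic per-trial metric dataset
#'
#' Each evaluated trial contributes one observation
#' \eqn{y = \alpha_j + \beta_j x + N(0, \sigma_{obs}^2)} with session
#' \eqn{x \in \{0, 1\}}. Trials are independently flagged excluded with
#' probability `exclusion_rate`; excluded trials are emitted with
#' `excluded = TRUE` and `y = NA` (the movement left the safe area, so it
#' was not evaluated, but it still counts towards the per-session trial
#' total).
#'
#' @param config a [generator_config()].
#' @param latents optional tibble from [draw_subject_latents()]; drawn from
#'   `config` when `NULL`.
#' @return tibble with columns `subject`, `session` (0/1), `trial`, `y`,
#'   `excluded`; the generating latents are attached as attribute
#'   `"latents"` and the metric name as `"metric"`.
#' @examples
#' d <- generate_metric_dataset(generator_config(n_subjects = 3, seed = 1))
#' dplyr::count(d, session)
#' @export
generate_metric_dataset <- function(config, latents = NULL) {
  validate_generator_config(config)
  latents <- latents %||% draw_subject_latents(config)
  grid <- tidyr::expand_grid(
    subject = latents$subject,
    session = 0:1,
    trial = seq_len(config$trials_per_session)
  )
  run <- function() {
    i <- match(grid$subject, latents$subject)
    mu <- latents$alpha[i] + latents$beta[i] * grid$session
    y <- mu + rnorm(nrow(grid), 0, config$sigma_obs)
    excluded <- as.logical(rbinom(nrow(grid), 1, config$exclusion_rate))
    out <- dplyr::mutate(grid, y = ifelse(excluded, NA_real_, y),
                         excluded = excluded)
    out
  }
  out <- if (is.null(config$seed)) run() else
    withr::with_seed(stage_seed(config$seed, "metrics"), run())
  attr(out, "latents") <- latents
  attr(out, "metric") <- config$metric
  out
}

#' Generate one synthetic circle-drawing trajectory
#'
#' The hand moves on a circle of radius `radius_bias_factor` times the
#' target radius, with angular progression `speed_bias_factor` times the
#' target's, plus isotropic Gaussian kinematic noise. When
#' `radius_bias_factor` is `NULL` it is set to
#' \eqn{1 + (\alpha + \beta \cdot session) / r}, so a noise-free trajectory
#' yields \eqn{E_p = \alpha + \beta \cdot session} exactly.
#'
#' @param latents one-row tibble (or list) with `alpha` and `beta` (and
#'   optionally `subject`).
#' @param session session indicator, 0 or 1.
#' @param traj_config a [trajectory_config()].
#' @param target a [target_spec()].
#' @param seed integer seed, or `NULL`.
#' @param trial optional trial number carried into the output.
#' @return trajectory tibble with columns `subject`, `session`, `trial`,
#'   `t`, `x`, `y`.
#' @examples
#' tr <- generate_trajectory(list(alpha = 0.02, beta = 0), session = 0)
#' compute_position_error(tr, target_spec())
#' @export
generate_trajectory <- function(latents, session = 0,
                                traj_config = trajectory_config(),
                                target = target_spec(), seed = NULL,
                                trial = 1L) {
  stopifnot(session %in% c(0, 1))
  r <- target$radius
  bias <- traj_config$radius_bias_factor %||%
    (1 + (latents$alpha + latents$beta * session) / r)
  if (bias <= 0) {
    stop("derived radius bias is non-positive; latent error below -radius",
         call. = FALSE)
  }
  n <- floor(traj_config$duration * traj_config$sample_rate) + 1
  t <- (seq_len(n) - 1) / traj_config$sample_rate
  omega <- target$peripheral_speed / r # target angular rate
  t_full <- 2 * pi / omega
  phi <- target$start_angle +
    omega * traj_config$speed_bias_factor * pmin(t, t_full)
  run <- function() {
    nx <- if (traj_config$kinematic_noise_sd > 0)
      rnorm(n, 0, traj_config$kinematic_noise_sd) else 0
    ny <- if (traj_config$kinematic_noise_sd > 0)
      rnorm(n, 0, traj_config$kinematic_noise_sd) else 0
    tibble::tibble(
      subject = as.character(latents$subject %||% "S01"),
      session = as.integer(session),
      trial = as.integer(trial),
      t = t,
      x = target$center[1] + bias * r * cos(phi) + nx,
      y = target$center[2] + bias * r * sin(phi) + ny
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Generate a full set of trajectories for a synthetic study
#'
#' One trajectory per subject, session, and trial, with per-trial exclusion
#' flags, suitable for [metrics_table()].
#'
#' @param config a [generator_config()] (latent structure, counts,
#'   exclusions, seed).
#' @param traj_config a [trajectory_config()].
#' @param target a [target_spec()].
#' @return long tibble of samples: `subject`, `session`, `trial`, `t`, `x`,
#'   `y`, `excluded`; generating latents attached as attribute `"latents"`.
#' @export
generate_trajectories <- function(config, traj_config = trajectory_config(),
                                  target = target_spec()) {
  validate_generator_config(config)
  latents <- draw_subject_latents(config)
  grid <- tidyr::expand_grid(
    i = seq_len(nrow(latents)),
    session = 0:1,
    trial = seq_len(config$trials_per_session)
  )
  base_seed <- if (is.null(config$seed)) NULL else
    stage_seed(config$seed, "trajectories")
  excl <- if (is.null(config$seed)) {
    as.logical(rbinom(nrow(grid), 1, config$exclusion_rate))
  } else {
    withr::with_seed(
      stage_seed(config$seed, "exclusions"),
      as.logical(rbinom(nrow(grid), 1, config$exclusion_rate))
    )
  }
  out <- purrr::pmap(
    list(grid$i, grid$session, grid$trial, seq_len(nrow(grid))),
    function(i, session, trial, k) {
      tr <- generate_trajectory(
        latents[i, ], session, traj_config, target,
        seed = if (is.null(base_seed)) NULL else base_seed + k,
        trial = trial
      )
      tr$excluded <- excl[k]
      tr
    }
  ) |>
    dplyr::bind_rows()
  attr(out, "latents") <- latents
  out
}

#' Simulate a two-metric study (position and velocity errors)
#'
#' Generates independent position- and velocity-error datasets that share
#' subjects and exclusion flags, assembled into one per-trial metrics table
#' of the shape produced by [metrics_table()].
#'
#' @param position_config,velocity_config [generator_config()]s for the two
#'   metrics; the velocity config's subject count, trial count and
#'   exclusion flags are taken from the position config.
#' @param seed integer seed overriding both configs' seeds (optional).
#' @return tibble `subject`, `session`, `trial`, `e_p`, `e_v`, `excluded`;
#'   latents attached as attributes `"latents_position"` and
#'   `"latents_velocity"`.
#' @export
simulate_study <- function(position_config = generator_config(metric = "position"),
                           velocity_config = generator_config(metric = "velocity"),
                           seed = NULL) {
  if (!is.null(seed)) {
    position_config$seed <- seed
    velocity_config$seed <- seed + 1L
  }
  velocity_config$n_subjects <- position_config$n_subjects
  velocity_config$trials_per_session <- position_config$trials_per_session
  velocity_config$exclusion_rate <- 0 # exclusions come from the position draw
  dp <- generate_metric_dataset(position_config)
  dv <- generate_metric_dataset(velocity_config)
  out <- dp |>
    dplyr::rename(e_p = "y") |>
    dplyr::mutate(e_v = ifelse(dp$excluded, NA_real_, dv$y)) |>
    dplyr::select("subject", "session", "trial", "e_p", "e_v", "excluded")
  attr(out, "latents_position") <- attr(dp, "latents")
  attr(out, "latents_velocity") <- attr(dv, "latents")
  out
}

#' Convert a metrics table to a model-ready skill dataset
#'
#' Selects one metric as the response `y`, drops excluded trials, and
#' checks that every subject is observed in both sessions (needed to
#' identify per-subject slopes).
#'
#' @param metrics tibble with `subject`, `session`, `trial` and a metric
#'   column (`e_p`/`e_v`, or already `y`).
#' @param metric `"position"` (uses `e_p`) or `"velocity"` (uses `e_v`);
#'   ignored when `metrics` already has a `y` column.
#' @return tibble `subject`, `session`, `trial`, `y` with attribute
#'   `"metric"`.
#' @export
as_skill_data <- function(metrics, metric = c("position", "velocity")) {
  metric <- match.arg(metric)
  col <- if ("y" %in% names(metrics)) "y"
         else if (metric == "position") "e_p" else "e_v"
  if (!col %in% names(metrics)) {
    stop("metrics table has no column `", col, "`", call. = FALSE)
  }
  out <- metrics
  if ("excluded" %in% names(out)) out <- dplyr::filter(out, !.data$excluded)
  out <- out |>
    dplyr::transmute(
      subject = as.character(.data$subject),
      session = as.integer(.data$session),
      trial = .data$trial,
      y = .data[[col]]
    ) |>
    dplyr::filter(!is.na(.data$y))
  if (!all(out$session %in% 0:1)) {
    stop("session must be coded 0 (first) / 1 (second)", call. = FALSE)
  }
  attr(out, "metric") <- metric
  out
}
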