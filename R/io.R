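# CSV formats: UTF-8, header row, '.' decimal separator.
# trajectories: subject_id, session, trial, t_s, x_m, y_m, excluded
# metrics:      subject_id, session, trial, e_p, e_v, score, excluded

#' Read a trajectory CSV
#'
#' Validates columns and per-trial timestamp monotonicity; malformed trials
#' are reported by subject/session/trial.
#'
#' @param path CSV with columns `subject_id`, `session`, `trial`, `t_s`,
#'   `x_m`, `y_m` and optionally `excluded`.
#' @return long tibble `subject`, `session`, `trial`, `t`, `x`, `y`,
#'   `excluded`.
#' @export
read_trajectories <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "session", "trial", "t_s", "x_m", "y_m")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"excluded" %in% names(raw)) raw$excluded <- FALSE
  out <- tibble::tibble(
    subject = as.character(raw$subject_id),
    session = as.integer(raw$session),
    trial = as.integer(raw$trial),
    t = as.numeric(raw$t_s),
    x = as.numeric(raw$x_m),
    y = as.numeric(raw$y_m),
    excluded = as.logical(raw$excluded)
  )
  bad <- out |>
    dplyr::group_by(.data$subject, .data$session, .data$trial) |>
    dplyr::summarise(ok = all(diff(.data$t) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "%s: non-monotone timestamps in subject %s session %s trial %s",
      path, bad$subject[1], bad$session[1], bad$trial[1]
    ), call. = FALSE)
  }
  out
}

#' @rdname read_trajectories
#' @param trajectories long trajectory tibble (as returned by
#'   [read_trajectories()] or [generate_trajectories()]).
#' @export
write_trajectories <- function(trajectories, path) {
  if (!"excluded" %in% names(trajectories)) trajectories$excluded <- FALSE
  out <- tibble::tibble(
    subject_id = trajectories$subject,
    session = trajectories$session,
    trial = trajectories$trial,
    t_s = trajectories$t,
    x_m = trajectories$x,
    y_m = trajectories$y,
    excluded = trajectories$excluded
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a per-trial metrics CSV
#'
#' @param path CSV with columns `subject_id`, `session`, `trial`, `e_p`,
#'   `e_v` and optionally `score`, `excluded`.
#' @return tibble `subject`, `session`, `trial`, `e_p`, `e_v`, (`score`,)
#'   `excluded`.
#' @export
read_metrics <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "session", "trial", "e_p", "e_v")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(
    subject = as.character(raw$subject_id),
    session = as.integer(raw$session),
    trial = as.integer(raw$trial),
    e_p = as.numeric(raw$e_p),
    e_v = as.numeric(raw$e_v)
  )
  if ("score" %in% names(raw)) out$score <- as.numeric(raw$score)
  out$excluded <- if ("excluded" %in% names(raw)) as.logical(raw$excluded)
                  else FALSE
  out
}

#' @rdname read_metrics
#' @param metrics metrics tibble (e.g. from [metrics_table()] or
#'   [simulate_study()]).
#' @export
write_metrics <- function(metrics, path) {
  out <- tibble::tibble(
    subject_id = metrics$subject,
    session = metrics$session,
    trial = metrics$trial,
    e_p = metrics$e_p,
    e_v = if ("e_v" %in% names(metrics)) metrics$e_v else NA_real_,
    score = if ("score" %in% names(metrics)) metrics$score else NA_real_,
    excluded = if ("excluded" %in% names(metrics)) metrics$excluded else FALSE
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Serialize / restore posterior draws
#'
#' Draws go to a plain CSV (one column per parameter) with a JSON metadata
#' sidecar (model, method, seed, subjects), so cached fits survive in a
#' text-only workspace and can be reloaded without refitting.
#'
#' @param fit a `skill_fit`.
#' @param path CSV path; metadata is written to `<path>.json`.
#' @export
write_posterior <- function(fit, path) {
  readr::write_csv(tibble::as_tibble(fit$draws), path, progress = FALSE)
  meta <- list(
    model = fit$model, method = fit$method, seed = fit$seed,
    subjects = fit$subjects, metric = fit$metric,
    diagnostics = fit$diagnostics
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_posterior
#' @param data the skill dataset the posterior was fitted to (restores the
#'   log-likelihood matrix).
#' @export
read_posterior <- function(path, data) {
  draws <- as.matrix(readr::read_csv(path, show_col_types = FALSE,
                                     progress = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fit <- list(
    model = meta$model, method = meta$method, draws = draws, mcmc = NULL,
    diagnostics = tibble::as_tibble(meta$diagnostics),
    subjects = meta$subjects, data = data, priors = prior_config(),
    config = NULL, seed = meta$seed, theta_fixed = NULL,
    metric = meta$metric
  )
  class(fit) <- "skill_fit"
  fit$log_lik <- pointwise_loglik(fit, data)
  fit
}

#' Read a structured run configuration
#'
#' Flat YAML sections (`run`, `generator_position`, `generator_velocity`,
#' `priors`, `fit`) mirroring the programmatic sub-configs; every key is
#' optional and falls back to the package defaults.
#'
#' @param path YAML file.
#' @return a `run_config` list, see [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(
    cfg$run %||% list(),
    list(
      position_config = do.call(
        generator_config,
        c(cfg$generator_position %||% list(), list(metric = "position"))
      ),
      velocity_config = do.call(
        generator_config,
        c(cfg$generator_velocity %||% list(), list(metric = "velocity"))
      ),
      priors = do.call(prior_config, cfg$priors %||% list()),
      fit = do.call(fit_config, cfg$fit %||% list())
    )
  ))
}
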