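#' Detect the evaluation window of a trial
#'
#' The window starts at the first sample whose distance from the start
#' point (the target position at 12 o'clock) exceeds the start-zone radius
#' (half of `start_zone_diameter`), and lasts `window_length` seconds. A
#' trajectory whose first sample is already outside the start zone starts
#' its window at the first sample.
#'
#' @param traj a trajectory tibble with numeric columns `t`, `x`, `y`
#'   (seconds/metres), `t` strictly increasing, at least 2 samples.
#' @param target a [target_spec()].
#' @param start_zone_diameter start-zone diameter in metres (default 0.03).
#' @param window_length evaluation window length in seconds (default 1.46).
#' @return a list of class `eval_window` with elements `t_s`, `t_e`, and
#'   `idx` (row indices of the window samples, `t_s <= t <= t_e`).
#' @examples
#' tg <- target_spec()
#' traj <- target_position(tg, seq(0, 1.998, by = 1 / 500))
#' detect_window(traj, tg)
#' @export
detect_window <- function(traj, target, start_zone_diameter = 0.03,
                          window_length = 1.46) {
  check_trajectory(traj)
  stopifnot(inherits(target, "target_spec"),
            start_zone_diameter > 0, window_length > 0)
  start <- target_position(target, 0)
  d <- sqrt((traj$x - start$x)^2 + (traj$y - start$y)^2)
  out <- which(d > start_zone_diameter / 2)
  id <- trial_label(traj)
  if (length(out) == 0) {
    stop(sprintf("window detection failed for %s: hand never left the start zone", id),
         call. = FALSE)
  }
  t_s <- traj$t[out[1]]
  t_e <- t_s + window_length
  # allow the last sample to fall short of t_e by up to one sample period
  dt <- stats::median(diff(traj$t))
  if (max(traj$t) < t_e - dt - 1e-9) {
    stop(sprintf(
      "window detection failed for %s: trajectory ends %.3f s before the %.2f s window",
      id, t_e - max(traj$t), window_length
    ), call. = FALSE)
  }
  idx <- which(traj$t >= t_s - 1e-12 & traj$t <= t_e + 1e-12)
  structure(list(t_s = t_s, t_e = t_e, idx = idx), class = "eval_window")
}

check_trajectory <- function(traj) {
  need <- c("t", "x", "y")
  missing <- setdiff(need, names(traj))
  if (length(missing) > 0) {
    stop("trajectory is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(traj) < 2) stop("trajectory needs at least 2 samples", call. = FALSE)
  dt <- diff(traj$t)
  if (any(dt <= 0)) {
    stop(sprintf("trajectory timestamps must be strictly increasing (%s)",
                 trial_label(traj)), call. = FALSE)
  }
  invisible(traj)
}

trial_label <- function(traj) {
  if (all(c("subject", "session", "trial") %in% names(traj))) {
    sprintf("subject %s session %s trial %s",
            traj$subject[1], traj$session[1], traj$trial[1])
  } else {
    "trial"
  }
}

#' Instantaneous tracking error
#'
#' Euclidean distance between the hand position (linearly interpolated at
#' `t`) and the reference target position at the same elapsed time.
#'
#' @inheritParams detect_window
#' @param t times (s) at which to evaluate; must lie within the sampled
#'   range.
#' @return numeric vector of errors in metres.
#' @export
compute_err <- function(traj, target, t) {
  check_trajectory(traj)
  if (any(t < min(traj$t) - 1e-12 | t > max(traj$t) + 1e-12)) {
    stop("compute_err: t outside the sampled time range", call. = FALSE)
  }
  hx <- stats::approx(traj$t, traj$x, xout = t)$y
  hy <- stats::approx(traj$t, traj$y, xout = t)$y
  tp <- target_position(target, t)
  sqrt((hx - tp$x)^2 + (hy - tp$y)^2)
}

#' Per-trial score
#'
#' Time average over the evaluation window of
#' \eqn{100 (E_{max} - ERR(t)) / E_{max}} with \eqn{E_{max}} equal to the
#' target radius. A perfect trial scores 100; a hand held at the workspace
#' centre scores 0. Values are not clamped: errors beyond \eqn{E_{max}}
#' yield negative instantaneous scores (clamp for display only).
#'
#' @inheritParams detect_window
#' @param window an [detect_window()] result, or `NULL` to detect it.
#' @return scalar trial score (dimensionless).
#' @export
compute_trial_score <- function(traj, target, window = NULL) {
  window <- window %||% detect_window(traj, target)
  if (length(window$idx) == 0) stop("empty evaluation window", call. = FALSE)
  ts <- traj$t[window$idx]
  err <- compute_err(traj, target, ts)
  e_max <- target$radius
  mean(100 * (e_max - err) / e_max)
}

#' Per-trial position error
#'
#' Mean absolute deviation of the hand's distance from the workspace centre
#' from the target radius, over the evaluation window:
#' \eqn{E_p = mean(|r_h(t) - r|)}. Depends only on radial deviation, not on
#' angular position or timing.
#'
#' @inheritParams compute_trial_score
#' @return scalar \eqn{E_p} in metres (>= 0).
#' @export
compute_position_error <- function(traj, target, window = NULL) {
  window <- window %||% detect_window(traj, target)
  if (length(window$idx) == 0) stop("empty evaluation window", call. = FALSE)
  i <- window$idx
  r_h <- sqrt((traj$x[i] - target$center[1])^2 + (traj$y[i] - target$center[2])^2)
  mean(abs(r_h - target$radius))
}

#' Per-sample hand velocity
#'
#' Central finite differences on interior samples, one-sided differences at
#' the ends; no smoothing. Requires at least 3 samples with strictly
#' increasing, non-duplicated timestamps.
#'
#' @inheritParams detect_window
#' @return the trajectory tibble with `vx`, `vy` columns added (m/s).
#' @export
estimate_velocity <- function(traj) {
  check_trajectory(traj)
  n <- nrow(traj)
  if (n < 3) stop("estimate_velocity needs at least 3 samples", call. = FALSE)
  t <- traj$t
  fd <- function(p) {
    v <- numeric(n)
    v[1] <- (p[2] - p[1]) / (t[2] - t[1])
    v[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
    i <- 2:(n - 1)
    v[i] <- (p[i + 1] - p[i - 1]) / (t[i + 1] - t[i - 1])
    v
  }
  dplyr::mutate(traj, vx = fd(traj$x), vy = fd(traj$y))
}

#' Per-trial velocity error
#'
#' Mean Euclidean norm of the difference between the estimated hand
#' velocity and the target's tangential velocity at matched elapsed time,
#' over the evaluation window: \eqn{E_v = mean(\|v_h(t) - v(t)\|)}. For a
#' stationary hand this equals the target peripheral speed (0.3762 m/s at
#' the defaults).
#'
#' @inheritParams compute_trial_score
#' @return scalar \eqn{E_v} in m/s (>= 0).
#' @export
compute_velocity_error <- function(traj, target, window = NULL) {
  window <- window %||% detect_window(traj, target)
  if (length(window$idx) == 0) stop("empty evaluation window", call. = FALSE)
  vel <- estimate_velocity(traj)
  i <- window$idx
  tv <- target_velocity(target, vel$t[i])
  mean(sqrt((vel$vx[i] - tv$vx)^2 + (vel$vy[i] - tv$vy)^2))
}

#' Metrics for a single trial
#'
#' @inheritParams compute_trial_score
#' @return one-row tibble with `e_p`, `e_v`, `score` (plus `subject`,
#'   `session`, `trial` when present in `traj`).
#' @export
trial_metrics <- function(traj, target = target_spec(), window = NULL) {
  window <- window %||% detect_window(traj, target)
  ids <- intersect(c("subject", "session", "trial"), names(traj))
  out <- tibble::as_tibble(as.list(traj[1, ids, drop = FALSE]))
  dplyr::bind_cols(out, tibble::tibble(
    e_p = compute_position_error(traj, target, window),
    e_v = compute_velocity_error(traj, target, window),
    score = compute_trial_score(traj, target, window)
  ))
}

#' Per-trial metrics table for a set of trajectories
#'
#' Trials flagged `excluded` (movement left the safe area) are omitted from
#' the metric rows but still counted; the attached `"trial_counts"`
#' attribute (also available via [trial_counts()]) records per
#' subject-session how many trials were presented and how many evaluated.
#'
#' @param trajectories long tibble of samples with columns `subject`,
#'   `session`, `trial`, `t`, `x`, `y` and optionally `excluded`.
#' @param target a [target_spec()].
#' @param start_zone_diameter,window_length window parameters, see
#'   [detect_window()].
#' @return tibble with one row per evaluated trial: `subject`, `session`,
#'   `trial`, `e_p`, `e_v`, `score`.
#' @export
metrics_table <- function(trajectories, target = target_spec(),
                          start_zone_diameter = 0.03, window_length = 1.46) {
  need <- c("subject", "session", "trial", "t", "x", "y")
  missing <- setdiff(need, names(trajectories))
  if (length(missing) > 0) {
    stop("trajectories table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"excluded" %in% names(trajectories)) {
    trajectories$excluded <- FALSE
  }
  counts <- trajectories |>
    dplyr::distinct(.data$subject, .data$session, .data$trial, .data$excluded) |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_evaluated = sum(!.data$excluded),
      .groups = "drop"
    )
  evaluated <- dplyr::filter(trajectories, !.data$excluded)
  if (nrow(evaluated) == 0) {
    out <- tibble::tibble(
      subject = character(), session = integer(), trial = integer(),
      e_p = double(), e_v = double(), score = double()
    )
  } else {
    out <- evaluated |>
      dplyr::group_by(.data$subject, .data$session, .data$trial) |>
      dplyr::group_map(~ trial_metrics(
        dplyr::mutate(.x,
          subject = .y$subject, session = .y$session, trial = .y$trial
        ),
        target,
        detect_window(.x, target, start_zone_diameter, window_length)
      )) |>
      dplyr::bind_rows() |>
      dplyr::arrange(.data$subject, .data$session, .data$trial)
  }
  attr(out, "trial_counts") <- counts
  out
}

#' Trial bookkeeping for a metrics table or trajectory set
#'
#' @param x a [metrics_table()] result (counts attached) or a long
#'   trajectory tibble.
#' @return tibble with `subject`, `session`, `n_trials`, `n_evaluated`.
#' @export
trial_counts <- function(x) {
  tc <- attr(x, "trial_counts")
  if (!is.null(tc)) return(tc)
  metrics_table_counts_from_raw(x)
}

metrics_table_counts_from_raw <- function(trajectories) {
  if (!"excluded" %in% names(trajectories)) trajectories$excluded <- FALSE
  trajectories |>
    dplyr::distinct(.data$subject, .data$session, .data$trial, .data$excluded) |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_evaluated = sum(!.data$excluded),
      .groups = "drop"
    )
}
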