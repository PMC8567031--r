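#' Plot the skill-level change between sessions
#'
#' One thin line per subject connecting the session means, with the group
#' mean overlaid — the standard before/after view of a training study.
#'
#' @param data skill dataset (`subject`, `session`, `y`) or metrics table
#'   plus `metric` selection.
#' @param metric metric column to plot when `data` is a metrics table.
#' @return a ggplot object.
#' @export
plot_skill_change <- function(data, metric = c("position", "velocity")) {
  if (!"y" %in% names(data)) data <- as_skill_data(data, match.arg(metric))
  means <- data |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  grand <- means |>
    dplyr::group_by(.data$session) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(.data$session, .data$y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(data = grand, linewidth = 1.2, colour = "black") +
    ggplot2::geom_point(data = grand, size = 2) +
    ggplot2::scale_x_continuous(breaks = 0:1,
                                labels = c("first", "second")) +
    ggplot2::labs(x = "session", y = "skill metric (error)",
                  title = "Skill-level change between sessions") +
    ggplot2::theme_minimal()
}

#' @method autoplot skill_boundary
#' @export
autoplot.skill_boundary <- function(object, ...) {
  se <- object$subject_effects
  p <- ggplot2::ggplot()
  if (!is.null(se)) {
    p <- p + ggplot2::geom_point(
      data = se, ggplot2::aes(.data$beta_mean, .data$alpha_mean),
      colour = "steelblue", size = 2
    )
  }
  if (is.finite(object$theta_mean)) {
    p <- p + ggplot2::geom_abline(
      slope = object$theta_mean, intercept = object$gamma_mean,
      colour = "red"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = object$gamma_mean,
                        linetype = "dashed", colour = "red") +
    ggplot2::annotate(
      "rect", xmin = -Inf, xmax = Inf,
      ymin = object$ci_low, ymax = object$ci_high,
      alpha = 0.15, fill = "red"
    ) +
    ggplot2::labs(
      x = "slope (skill change)", y = "intercept (initial skill)",
      title = sprintf(
        "Initial-skill boundary: gamma = %.4g [%.4g, %.4g]",
        object$gamma_mean, object$ci_low, object$ci_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot loso_waic
#' @export
autoplot.loso_waic <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(factor(.data$model), .data$waic_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$waic_mean - .data$waic_sd,
      ymax = .data$waic_mean + .data$waic_sd
    )) +
    ggplot2::labs(x = "model", y = "WAIC (mean ± SD over LOSO folds)",
                  title = "Model comparison (smaller is better)") +
    ggplot2::theme_minimal()
}

#' @method autoplot skill_classification
#' @export
autoplot.skill_classification <- function(object, ...) {
  s <- object$subjects
  long <- tidyr::pivot_longer(
    s, c("initial_mean", "second_mean"),
    names_to = "session", values_to = "y"
  ) |>
    dplyr::mutate(session = ifelse(.data$session == "initial_mean", 0, 1))
  ggplot2::ggplot(long, ggplot2::aes(.data$session, .data$y,
                                     group = .data$subject,
                                     colour = .data$predicted)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 0:1,
                                labels = c("first", "second")) +
    ggplot2::labs(x = "session", y = "skill metric (error)",
                  colour = "predicted",
                  title = sprintf("LOSO prediction: accuracy %.2f, F %.2f",
                                  object$accuracy, object$f_measure)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
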