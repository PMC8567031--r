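#' Derive the initial-skill boundary from a model-4 posterior
#'
#' The boundary \eqn{\gamma} is the intercept of the coupling relation
#' \eqn{\alpha_j = \theta \beta_j + \gamma}: subjects with initial error
#' above \eqn{\gamma} are expected to improve (\eqn{\beta_j < 0} when
#' \eqn{\theta < 0}). Summarises the posterior of \eqn{\gamma} (mean and
#' credible interval, 94% highest-density by default) and flags whether the
#' \eqn{\theta} and \eqn{\gamma} intervals exclude zero — a non-zero
#' \eqn{\theta} is the evidence that skill change depends on initial skill.
#'
#' @param fit a `skill_fit` of model 4 (must carry `gamma` draws), or any
#'   object accepted by [boundary_from_draws()].
#' @param prob credible-interval mass (default from the fit's priors,
#'   0.94).
#' @param method `"hdi"` or `"eti"`.
#' @return object of class `skill_boundary`: `gamma_mean`, `ci_low`,
#'   `ci_high`, `theta_mean`, `theta_ci`, `gamma_excludes_zero`,
#'   `theta_excludes_zero`, `prob`, retained `draws` (tibble), and
#'   `subject_effects` (posterior-mean \eqn{\alpha_j}, \eqn{\beta_j}).
#' @examples
#' b <- boundary_from_draws(gamma = rnorm(1000, 0.019, 0.001),
#'                          theta = rnorm(1000, -1, 0.1))
#' b$gamma_mean
#' @export
derive_boundary <- function(fit, prob = NULL, method = NULL) {
  stopifnot(inherits(fit, "skill_fit"))
  if (!"gamma" %in% colnames(fit$draws)) {
    stop("derive_boundary needs a model-4 fit with gamma draws", call. = FALSE)
  }
  prob <- prob %||% fit$priors$interval_prob
  method <- method %||% fit$priors$interval_method
  theta <- if ("theta" %in% colnames(fit$draws)) fit$draws[, "theta"] else
    rep(fit$theta_fixed %||% NA_real_, nrow(fit$draws))
  b <- boundary_from_draws(fit$draws[, "gamma"], theta, prob, method)
  comp <- draws_components(fit)
  b$subject_effects <- tibble::tibble(
    subject = fit$subjects,
    alpha_mean = colMeans(comp$alpha),
    beta_mean = colMeans(comp$beta)
  )
  b$metric <- fit$metric
  b
}

#' @rdname derive_boundary
#' @param gamma,theta numeric vectors of posterior draws (theta may be
#'   `NULL`).
#' @export
boundary_from_draws <- function(gamma, theta = NULL, prob = 0.94,
                                method = c("hdi", "eti")) {
  method <- match.arg(method)
  ci <- credible_interval(gamma, prob, method)
  theta_ci <- if (is.null(theta) || all(is.na(theta))) c(NA_real_, NA_real_)
              else credible_interval(theta, prob, method)
  excl0 <- function(iv) all(is.finite(iv)) && (iv[1] > 0 || iv[2] < 0)
  structure(
    list(
      gamma_mean = mean(gamma),
      ci_low = ci[1], ci_high = ci[2],
      theta_mean = if (is.null(theta)) NA_real_ else mean(theta),
      theta_ci = theta_ci,
      gamma_excludes_zero = excl0(ci),
      theta_excludes_zero = excl0(theta_ci),
      prob = prob, method = method,
      draws = tibble::tibble(
        gamma = as.numeric(gamma),
        theta = if (is.null(theta)) NA_real_ else as.numeric(theta)
      ),
      subject_effects = NULL,
      metric = NA_character_
    ),
    class = "skill_boundary"
  )
}

#' @export
print.skill_boundary <- function(x, ...) {
  cat(sprintf(
    "<skill_boundary> gamma %.4f [%.4f, %.4f] (%d%% %s)\n  theta %.3f [%.3f, %.3f]; theta excludes zero: %s\n",
    x$gamma_mean, x$ci_low, x$ci_high, round(100 * x$prob),
    toupper(x$method), x$theta_mean, x$theta_ci[1], x$theta_ci[2],
    x$theta_excludes_zero
  ))
  invisible(x)
}

#' @describeIn derive_boundary two-row tibble summarising gamma and theta.
#' @param x a `skill_boundary`.
#' @param ... unused.
#' @method tidy skill_boundary
#' @export
tidy.skill_boundary <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "theta"),
    estimate = c(x$gamma_mean, x$theta_mean),
    conf.low = c(x$ci_low, x$theta_ci[1]),
    conf.high = c(x$ci_high, x$theta_ci[2]),
    excludes_zero = c(x$gamma_excludes_zero, x$theta_excludes_zero)
  )
}

#' Per-subject session means of the skill metric
#'
#' @param data skill dataset (`subject`, `session`, `y`), excluded trials
#'   already dropped.
#' @return tibble `subject`, `initial_mean` (session 0), `second_mean`
#'   (session 1, `NA` if absent).
#' @export
initial_skill <- function(data) {
  check_skill_data(data)
  wide <- data |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::summarise(m = mean(.data$y), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "session", values_from = "m",
                       names_prefix = "s")
  if (!"s1" %in% names(wide)) wide$s1 <- NA_real_
  wide |>
    dplyr::transmute(
      subject = as.character(.data$subject),
      initial_mean = .data$s0,
      second_mean = .data$s1
    ) |>
    dplyr::arrange(.data$subject)
}

#' Classify subjects against a derived boundary
#'
#' A subject whose first-session mean error lies strictly above the
#' boundary mean is predicted to improve under training (their expected
#' slope is negative); otherwise they are predicted to decline. Ties fall
#' on the decline side. The proximity flag marks initial means inside the
#' boundary's credible interval, where the posterior uncertainty should
#' temper the call.
#'
#' @param initial either a tibble with `subject` and `initial_mean`
#'   columns, or a skill dataset from which session-0 means are computed.
#' @param boundary a `skill_boundary`.
#' @return tibble `subject`, `initial_mean`, `predicted`
#'   (`"improve"`/`"decline"`), `near_boundary` (logical).
#' @export
classify_subjects <- function(initial, boundary) {
  stopifnot(inherits(boundary, "skill_boundary"))
  if (!"initial_mean" %in% names(initial)) {
    initial <- initial_skill(initial)
  }
  initial |>
    dplyr::transmute(
      subject = as.character(.data$subject),
      initial_mean = .data$initial_mean,
      predicted = ifelse(.data$initial_mean > boundary$gamma_mean,
                         "improve", "decline"),
      near_boundary = .data$initial_mean >= boundary$ci_low &
        .data$initial_mean <= boundary$ci_high
    )
}

#' Leave-one-subject-out responder prediction
#'
#' For every subject: model 4 is refitted on the remaining subjects, the
#' boundary derived, and the held-out subject predicted to improve iff
#' their first-session mean exceeds the fold's boundary. The actual label
#' is `"improve"` iff their second-session mean is strictly below the
#' first-session mean. Aggregates a confusion matrix, accuracy, and the
#' F-measure (F1 with `"improve"` as the positive class). Fold seeds are
#' keyed to the sorted subject labels, so results are invariant to row
#' order; a failed fold skips its subject with a warning.
#'
#' @inheritParams loso_waic
#' @return object of class `skill_classification`: `subjects` (per-subject
#'   tibble), `confusion` (2x2 table, predicted x actual), `accuracy`,
#'   `f_measure`, `n_classified`, `n_skipped`, `boundaries` (per-fold
#'   gamma summaries).
#' @export
loso_classification <- function(data, priors = prior_config(),
                                config = fit_config(), quiet = TRUE) {
  check_skill_data(data)
  subjects <- sort(unique(as.character(data$subject)))
  if (length(subjects) < 3) {
    stop("LOSO classification needs at least 3 subjects", call. = FALSE)
  }
  means <- initial_skill(data)
  rows <- purrr::map(seq_along(subjects), function(fi) {
    held <- subjects[fi]
    train <- dplyr::filter(data, .data$subject != held)
    fold_cfg <- config
    fold_cfg$seed <- stage_seed(config$seed, "classify") + fi
    tryCatch({
      fit <- fit_skill_model(train, model = 4, priors = priors,
                             config = fold_cfg, quiet = quiet)
      b <- derive_boundary(fit)
      mi <- means[means$subject == held, ]
      pred <- classify_subjects(mi, b)
      tibble::tibble(
        subject = held,
        initial_mean = mi$initial_mean,
        second_mean = mi$second_mean,
        predicted = pred$predicted,
        actual = ifelse(mi$second_mean < mi$initial_mean,
                        "improve", "decline"),
        near_boundary = pred$near_boundary,
        gamma = b$gamma_mean,
        gamma_low = b$ci_low,
        gamma_high = b$ci_high
      )
    }, error = function(e) {
      warning(sprintf("fold %s failed, subject skipped: %s", held,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  })
  per_subject <- dplyr::bind_rows(rows)
  lv <- c("improve", "decline")
  confusion <- table(
    predicted = factor(per_subject$predicted, levels = lv),
    actual = factor(per_subject$actual, levels = lv)
  )
  structure(
    list(
      subjects = per_subject,
      confusion = confusion,
      accuracy = sum(diag(confusion)) / sum(confusion),
      f_measure = f1_improve(confusion),
      n_classified = nrow(per_subject),
      n_skipped = length(subjects) - nrow(per_subject),
      boundaries = per_subject[, c("subject", "gamma", "gamma_low", "gamma_high")]
    ),
    class = "skill_classification"
  )
}

f1_improve <- function(confusion) {
  tp <- confusion["improve", "improve"]
  fp <- confusion["improve", "decline"]
  fn <- confusion["decline", "improve"]
  if (tp == 0) return(0)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

#' @export
print.skill_classification <- function(x, ...) {
  cat(sprintf(
    "<skill_classification> accuracy %.2f, F %.2f (%d classified, %d skipped)\n",
    x$accuracy, x$f_measure, x$n_classified, x$n_skipped
  ))
  print(x$confusion)
  invisible(x)
}

#' @describeIn loso_classification the per-subject prediction table.
#' @param x a `skill_classification`.
#' @param ... unused.
#' @method tidy skill_classification
#' @export
tidy.skill_classification <- function(x, ...) x$subjects

#' @describeIn loso_classification one-row tibble with accuracy, F-measure
#'   and counts.
#' @method glance skill_classification
#' @export
glance.skill_classification <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, f_measure = x$f_measure,
    n_classified = x$n_classified, n_skipped = x$n_skipped
  )
}

#' Allocate subjects to dual-boundary skill groups
#'
#' Partitions subjects by whether their initial position and velocity
#' errors lie above or below the respective boundaries. Above both: the
#' "red" group (initially low-skilled in both aspects, expected to benefit
#' most); above velocity only: "blue"; above position only: "green"; below
#' both: "none" (expected non-responders on both aspects).
#'
#' @param position_means,velocity_means tibbles with `subject` and
#'   `initial_mean` (from [initial_skill()] or [classify_subjects()]).
#' @param position_boundary,velocity_boundary `skill_boundary` objects.
#' @return tibble `subject`, `above_position`, `above_velocity`, `group`
#'   with a `"group_counts"` attribute (2x2 count table).
#' @export
assign_groups <- function(position_means, velocity_means,
                          position_boundary, velocity_boundary) {
  stopifnot(inherits(position_boundary, "skill_boundary"),
            inherits(velocity_boundary, "skill_boundary"))
  pm <- dplyr::select(position_means, "subject", pos_mean = "initial_mean")
  vm <- dplyr::select(velocity_means, "subject", vel_mean = "initial_mean")
  out <- dplyr::inner_join(pm, vm, by = "subject") |>
    dplyr::mutate(
      above_position = .data$pos_mean > position_boundary$gamma_mean,
      above_velocity = .data$vel_mean > velocity_boundary$gamma_mean,
      group = dplyr::case_when(
        .data$above_position & .data$above_velocity ~ "red",
        !.data$above_position & .data$above_velocity ~ "blue",
        .data$above_position & !.data$above_velocity ~ "green",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select("subject", "above_position", "above_velocity", "group")
  counts <- table(
    velocity = ifelse(out$above_velocity, "above", "below"),
    position = ifelse(out$above_position, "above", "below")
  )
  attr(out, "group_counts") <- counts
  out
}
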