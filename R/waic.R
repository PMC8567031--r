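#' Widely applicable information criterion (WAIC)
#'
#' Computed from a per-draw, per-observation log-likelihood matrix on the
#' deviance scale, so smaller is better:
#' \deqn{lppd = \sum_i \log(\frac{1}{S}\sum_s e^{\ell_{si}}), \quad
#'       p_{WAIC} = \sum_i Var_s(\ell_{si}), \quad
#'       WAIC = -2 (lppd - p_{WAIC}).}
#'
#' @param x a log-likelihood matrix (draws in rows, observations in
#'   columns), or a `skill_fit` whose `log_lik` is used.
#' @param ... unused.
#' @return object of class `skill_waic`: list with `waic`, `p_waic`,
#'   `lppd`, `pointwise` (tibble with per-observation `lppd` and `p_waic`),
#'   `n_obs`, `n_draws`.
#' @examples
#' ll <- matrix(c(-1, -1.2, -0.8, -1.1, -0.9, -1.3), nrow = 2)
#' compute_waic(ll)
#' @export
compute_waic <- function(x, ...) {
  ll <- if (inherits(x, "skill_fit")) x$log_lik else as.matrix(x)
  if (!is.numeric(ll)) stop("log-likelihood matrix must be numeric", call. = FALSE)
  if (nrow(ll) < 2) {
    stop("WAIC needs at least 2 posterior draws (variance over draws)",
         call. = FALSE)
  }
  lppd_i <- col_log_mean_exp(ll)
  p_i <- col_var(ll)
  structure(
    list(
      waic = -2 * (sum(lppd_i) - sum(p_i)),
      p_waic = sum(p_i),
      lppd = sum(lppd_i),
      pointwise = tibble::tibble(lppd = lppd_i, p_waic = p_i),
      n_obs = ncol(ll),
      n_draws = nrow(ll)
    ),
    class = "skill_waic"
  )
}

#' @export
print.skill_waic <- function(x, ...) {
  cat(sprintf("<skill_waic> WAIC %.2f (lppd %.2f, p_waic %.2f, %d obs, %d draws)\n",
              x$waic, x$lppd, x$p_waic, x$n_obs, x$n_draws))
  invisible(x)
}

#' @describeIn compute_waic one-row tibble with `waic`, `p_waic`, `lppd`.
#' @method glance skill_waic
#' @export
glance.skill_waic <- function(x, ...) {
  tibble::tibble(waic = x$waic, p_waic = x$p_waic, lppd = x$lppd,
                 n_obs = x$n_obs, n_draws = x$n_draws)
}

#' Leave-one-subject-out WAIC model comparison
#'
#' For every held-out subject, refits each candidate model on the remaining
#' subjects and computes WAIC on that training fold; reports the mean and
#' SD of WAIC across folds per model. The model with the smallest mean WAIC
#' wins. Fold seeds are derived from the subject label order, so the result
#' does not depend on row order. A fold whose fit fails is flagged and
#' dropped from that model's mean/SD with a warning.
#'
#' @param data skill dataset (see [fit_skill_model()]); needs >= 3
#'   subjects.
#' @param models integer vector of model numbers to compare (default 1:4).
#' @param priors a [prior_config()].
#' @param config a [fit_config()].
#' @param quiet suppress JAGS output.
#' @return object of class `loso_waic`: list with `summary` (tibble:
#'   `model`, `name`, `waic_mean`, `waic_sd`, `n_folds`), `folds` (tibble:
#'   `model`, `held_out`, `waic`, `p_waic`), and `best_model`.
#' @export
loso_waic <- function(data, models = 1:4, priors = prior_config(),
                      config = fit_config(), quiet = TRUE) {
  check_skill_data(data)
  subjects <- sort(unique(as.character(data$subject)))
  if (length(subjects) < 3) {
    stop("LOSO comparison needs at least 3 subjects", call. = FALSE)
  }
  folds <- purrr::map_dfr(seq_along(subjects), function(fi) {
    held <- subjects[fi]
    train <- dplyr::filter(data, .data$subject != held)
    fold_cfg <- config
    fold_cfg$seed <- stage_seed(config$seed, "loso") + fi
    purrr::map_dfr(models, function(m) {
      res <- tryCatch({
        fit <- fit_skill_model(train, model = m, priors = priors,
                               config = fold_cfg, quiet = quiet)
        w <- compute_waic(fit)
        tibble::tibble(model = m, held_out = held, waic = w$waic,
                       p_waic = w$p_waic, failed = FALSE)
      }, error = function(e) {
        warning(sprintf("fold %s, model %d failed: %s", held, m,
                        conditionMessage(e)), call. = FALSE)
        tibble::tibble(model = m, held_out = held, waic = NA_real_,
                       p_waic = NA_real_, failed = TRUE)
      })
      res
    })
  })
  summary <- folds |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      waic_mean = mean(.data$waic),
      waic_sd = sd(.data$waic),
      n_folds = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(skill_models()[, c("model", "name")], by = "model") |>
    dplyr::select("model", "name", "waic_mean", "waic_sd", "n_folds")
  best <- summary$model[which.min(summary$waic_mean)]
  structure(
    list(summary = summary, folds = folds, best_model = best,
         n_subjects = length(subjects)),
    class = "loso_waic"
  )
}

#' @export
print.loso_waic <- function(x, ...) {
  cat(sprintf("<loso_waic> %d folds, best model: %d\n",
              x$n_subjects, x$best_model))
  print(x$summary)
  invisible(x)
}

#' @describeIn loso_waic the per-model summary table (mean and SD of WAIC
#'   over folds).
#' @param x a `loso_waic`.
#' @param ... unused.
#' @method tidy loso_waic
#' @export
tidy.loso_waic <- function(x, ...) x$summary

#' @describeIn loso_waic one-row summary naming the winning model.
#' @method glance loso_waic
#' @export
glance.loso_waic <- function(x, ...) {
  tibble::tibble(
    best_model = x$best_model,
    best_name = skill_models()$name[x$best_model],
    n_folds = x$n_subjects,
    n_models = nrow(x$summary)
  )
}
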