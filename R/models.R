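# The four skill-change models. Likelihood for all:
#   y_k ~ Normal(alpha + beta * x_k, sigma^2), x = session (0/1)
# 1 pooled:                    scalar alpha, scalar beta
# 2 varying slope:             scalar alpha, beta_j ~ N(mu_beta, sigma_beta^2)
# 3 varying intercept:         alpha_j ~ N(mu_alpha, sigma_alpha^2), scalar beta
# 4 varying intercept + slope: beta_j ~ N(mu_beta, sigma_beta^2),
#                              alpha_j ~ N(theta * beta_j + gamma, sigma_alpha^2)

#' Model descriptions
#'
#' @return tibble describing the four skill-change model variants.
#' @export
skill_models <- function() {
  tibble::tibble(
    model = 1:4,
    name = c("pooled", "varying slope", "varying intercept",
             "varying intercept and slope"),
    initial_skill_dependent = c(FALSE, FALSE, TRUE, TRUE),
    individual_effect = c(FALSE, TRUE, FALSE, TRUE)
  )
}

jags_model_string <- function(model, priors, theta_fixed = NULL) {
  fe <- format(priors$fixed_effect_precision, scientific = TRUE)
  hc <- format(1 / priors$half_cauchy_scale^2, digits = 10)
  fb <- format(priors$flat_bound)
  lik <- switch(model,
    "y[i] ~ dnorm(alpha + beta * x[i], tau)",
    "y[i] ~ dnorm(alpha + beta[subj[i]] * x[i], tau)",
    "y[i] ~ dnorm(alpha[subj[i]] + beta * x[i], tau)",
    "y[i] ~ dnorm(alpha[subj[i]] + beta[subj[i]] * x[i], tau)"
  )
  hier <- switch(model,
    sprintf("alpha ~ dnorm(0, %s)\n  beta ~ dnorm(0, %s)", fe, fe),
    sprintf(paste0(
      "alpha ~ dnorm(0, %s)\n",
      "  for (j in 1:J) { beta[j] ~ dnorm(mu_beta, tau_beta) }\n",
      "  mu_beta ~ dnorm(0, %s)\n",
      "  sigma_beta ~ dt(0, %s, 1) T(0,)\n",
      "  tau_beta <- pow(sigma_beta, -2)"
    ), fe, fe, hc),
    sprintf(paste0(
      "for (j in 1:J) { alpha[j] ~ dnorm(mu_alpha, tau_alpha) }\n",
      "  mu_alpha ~ dnorm(0, %s)\n",
      "  sigma_alpha ~ dt(0, %s, 1) T(0,)\n",
      "  tau_alpha <- pow(sigma_alpha, -2)\n",
      "  beta ~ dnorm(0, %s)"
    ), fe, hc, fe),
    sprintf(paste0(
      "for (j in 1:J) {\n",
      "    beta[j] ~ dnorm(mu_beta, tau_beta)\n",
      "    alpha[j] ~ dnorm(theta * beta[j] + gamma, tau_alpha)\n",
      "  }\n",
      "  %s\n",
      "  gamma ~ dunif(-%s, %s)\n",
      "  mu_beta ~ dnorm(0, %s)\n",
      "  sigma_alpha ~ dt(0, %s, 1) T(0,)\n",
      "  sigma_beta ~ dt(0, %s, 1) T(0,)\n",
      "  tau_alpha <- pow(sigma_alpha, -2)\n",
      "  tau_beta <- pow(sigma_beta, -2)"
    ),
    if (is.null(theta_fixed)) sprintf("theta ~ dunif(-%s, %s)", fb, fb)
    else sprintf("theta <- %s", format(theta_fixed)),
    fb, fb, fe, hc, hc)
  )
  sprintf(paste0(
    "model {\n",
    "  for (i in 1:N) { %s }\n",
    "  %s\n",
    "  sigma ~ dt(0, %s, 1) T(0,)\n",
    "  tau <- pow(sigma, -2)\n",
    "}"
  ), lik, hier, hc)
}

model_monitors <- function(model, theta_fixed = NULL) {
  switch(model,
    c("alpha", "beta", "sigma"),
    c("alpha", "beta", "mu_beta", "sigma_beta", "sigma"),
    c("alpha", "mu_alpha", "sigma_alpha", "beta", "sigma"),
    c(
      "alpha", "beta",
      if (is.null(theta_fixed)) "theta", "gamma",
      "mu_beta", "sigma_alpha", "sigma_beta", "sigma"
    )
  )
}

check_skill_data <- function(data) {
  need <- c("subject", "session", "y")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("skill dataset is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(data$session %in% 0:1)) {
    stop("session must be coded 0 (first) / 1 (second)", call. = FALSE)
  }
  if (any(!is.finite(data$y))) {
    stop("skill dataset contains non-finite y", call. = FALSE)
  }
  invisible(data)
}

# data-derived starting values; shared by both backends
initial_values <- function(data) {
  by_subj <- data |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::summarise(m = mean(.data$y), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "session", values_from = "m",
                       names_prefix = "s")
  a <- by_subj$s0
  b <- if ("s1" %in% names(by_subj)) by_subj$s1 - by_subj$s0 else rep(0, nrow(by_subj))
  a[!is.finite(a)] <- mean(data$y)
  b[!is.finite(b)] <- 0
  list(subject = by_subj$subject, alpha = a, beta = b,
       sigma = max(sd(data$y), 1e-6))
}

#' Fit a hierarchical Bayesian skill-change model
#'
#' Fits one of the four model variants (see [skill_models()]) to a long
#' skill dataset by MCMC (JAGS) or by a mean-field variational
#' approximation. Returns posterior draws, per-observation log-likelihoods
#' (for WAIC), and convergence diagnostics.
#'
#' @param data tibble with columns `subject`, `session` (0/1), `y` (one row
#'   per evaluated trial), e.g. from [as_skill_data()].
#' @param model model number 1-4.
#' @param priors a [prior_config()].
#' @param config a [fit_config()]; `method`, chain/draw counts and the
#'   sampler seed live here.
#' @param theta_fixed optionally fix the coupling coefficient of model 4
#'   (e.g. `0`, which reduces model 4 to model 3 with \eqn{\mu_\alpha}
#'   renamed \eqn{\gamma}).
#' @param quiet suppress JAGS progress output (default TRUE).
#' @return an object of class `skill_fit`: list with `draws` (matrix, one
#'   column per parameter), `log_lik` (draws x observations matrix),
#'   `diagnostics` (tibble with R-hat and effective sample size), `model`,
#'   `method`, `subjects`, `data`, `metric`, `seed`.
#' @examples
#' \donttest{
#' d <- generate_metric_dataset(generator_config(n_subjects = 5, seed = 1))
#' fit <- fit_skill_model(as_skill_data(d), model = 1,
#'                        config = fit_config(chains = 2, iter = 500,
#'                                            warmup = 250, seed = 1))
#' tidy(fit)
#' }
#' @export
fit_skill_model <- function(data, model = 4, priors = prior_config(),
                            config = fit_config(), theta_fixed = NULL,
                            quiet = TRUE) {
  stopifnot(model %in% 1:4)
  model <- as.integer(model)
  check_skill_data(data)
  data <- dplyr::mutate(data, subject = as.character(.data$subject))
  subjects <- sort(unique(data$subject))
  if (model %in% c(2L, 4L)) {
    per_session <- table(data$subject, data$session)
    if (any(per_session == 0)) {
      warning("some subjects lack trials in one session; ",
              "per-subject slopes are identified only through the prior",
              call. = FALSE)
    }
  }
  fit <- if (config$method == "vi") {
    fit_vi(data, model, priors, config, theta_fixed)
  } else {
    fit_jags(data, model, priors, config, theta_fixed, quiet)
  }
  fit$log_lik <- pointwise_loglik(fit, data)
  fit$metric <- attr(data, "metric") %||% NA_character_
  class(fit) <- "skill_fit"
  # convergence is reported, not enforced
  bad <- fit$diagnostics$rhat[is.finite(fit$diagnostics$rhat)] > 1.01
  if (config$method == "mcmc" && any(bad)) {
    warning(sprintf("model %d: %d parameter(s) with R-hat > 1.01", model,
                    sum(bad)), call. = FALSE)
  }
  fit
}

fit_jags <- function(data, model, priors, config, theta_fixed, quiet) {
  subjects <- sort(unique(data$subject))
  jd <- list(
    y = data$y, x = as.numeric(data$session),
    N = nrow(data)
  )
  if (model >= 2) {
    jd$subj <- match(data$subject, subjects)
    jd$J <- length(subjects)
  }
  iv <- initial_values(data)
  ord <- match(subjects, iv$subject)
  inits <- lapply(seq_len(config$chains), function(ch) {
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = config$seed * 100 + ch,
      sigma = iv$sigma
    )
    if (model == 1) {
      ini$alpha <- mean(iv$alpha)
      ini$beta <- mean(iv$beta)
    } else if (model == 2) {
      ini$alpha <- mean(iv$alpha)
      ini$beta <- iv$beta[ord]
      ini$mu_beta <- mean(iv$beta)
      ini$sigma_beta <- max(sd(iv$beta), 1e-6)
    } else if (model == 3) {
      ini$alpha <- iv$alpha[ord]
      ini$mu_alpha <- mean(iv$alpha)
      ini$sigma_alpha <- max(sd(iv$alpha), 1e-6)
      ini$beta <- mean(iv$beta)
    } else {
      ini$alpha <- iv$alpha[ord]
      ini$beta <- iv$beta[ord]
      if (is.null(theta_fixed)) ini$theta <- 0
      ini$gamma <- mean(iv$alpha)
      ini$mu_beta <- mean(iv$beta)
      ini$sigma_alpha <- max(sd(iv$alpha), 1e-6)
      ini$sigma_beta <- max(sd(iv$beta), 1e-6)
    }
    ini
  })
  ms <- jags_model_string(model, priors, theta_fixed)
  jm <- rjags::jags.model(
    textConnection(ms), data = jd, inits = inits,
    n.chains = config$chains, n.adapt = config$adapt, quiet = quiet
  )
  if (config$warmup > 0) {
    update(jm, config$warmup, progress.bar = if (quiet) "none" else "text")
  }
  samp <- rjags::coda.samples(
    jm, variable.names = model_monitors(model, theta_fixed),
    n.iter = config$iter, progress.bar = if (quiet) "none" else "text"
  )
  draws <- as.matrix(samp)
  diagnostics <- jags_diagnostics(samp)
  list(
    model = model, method = "mcmc", draws = draws, mcmc = samp,
    diagnostics = diagnostics, subjects = subjects, data = data,
    priors = priors, config = config, seed = config$seed,
    theta_fixed = theta_fixed
  )
}

jags_diagnostics <- function(samp) {
  pars <- colnames(samp[[1]])
  ess <- tryCatch(coda::effectiveSize(samp), error = function(e) NULL)
  rhat <- if (length(samp) >= 2) {
    tryCatch(
      coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1],
      error = function(e) rep(NA_real_, length(pars))
    )
  } else {
    rep(NA_real_, length(pars))
  }
  tibble::tibble(
    parameter = pars,
    rhat = unname(rhat[pars]),
    ess = if (is.null(ess)) NA_real_ else unname(ess[pars])
  )
}

# split a draws matrix into per-subject alpha/beta matrices + sigma vector
draws_components <- function(fit) {
  draws <- fit$draws
  cn <- colnames(draws)
  pick <- function(stem) {
    per <- grep(sprintf("^%s\\[", stem), cn, value = TRUE)
    if (length(per) > 0) {
      j <- as.integer(sub(sprintf("^%s\\[(\\d+)\\]$", stem), "\\1", per))
      draws[, per[order(j)], drop = FALSE]
    } else if (stem %in% cn) {
      draws[, stem, drop = FALSE]
    } else {
      NULL
    }
  }
  list(alpha = pick("alpha"), beta = pick("beta"), sigma = draws[, "sigma"])
}

#' Per-draw, per-observation log-likelihood
#'
#' The log normal density of every observation under every posterior
#' draw's \eqn{(\alpha_j + \beta_j x, \sigma)} — the input WAIC needs.
#'
#' @param fit a [fit_skill_model()] result (or a list with a compatible
#'   `draws` matrix plus `model` and `subjects`).
#' @param data dataset to evaluate; defaults to the fit's own data.
#' @return numeric matrix, draws in rows, observations in columns.
#' @export
pointwise_loglik <- function(fit, data = NULL) {
  data <- data %||% fit$data
  check_skill_data(data)
  comp <- draws_components(fit)
  S <- nrow(comp$alpha)
  N <- nrow(data)
  subj_of_col <- function(m) {
    if (ncol(m) == 1) rep(1L, N) else {
      idx <- match(as.character(data$subject), fit$subjects)
      if (any(is.na(idx))) {
        stop("dataset contains subjects absent from the fit", call. = FALSE)
      }
      idx
    }
  }
  A <- comp$alpha[, subj_of_col(comp$alpha), drop = FALSE]
  B <- comp$beta[, subj_of_col(comp$beta), drop = FALSE]
  X <- matrix(as.numeric(data$session), S, N, byrow = TRUE)
  Y <- matrix(data$y, S, N, byrow = TRUE)
  SD <- matrix(comp$sigma, S, N)
  ll <- dnorm(Y, A + B * X, SD, log = TRUE)
  dimnames(ll) <- NULL
  ll
}

#' @export
print.skill_fit <- function(x, ...) {
  nm <- skill_models()$name[x$model]
  cat(sprintf(
    "<skill_fit> model %d (%s), method %s\n  %d draws x %d parameters, %d observations, %d subjects\n",
    x$model, nm, x$method, nrow(x$draws), ncol(x$draws),
    nrow(x$data), length(x$subjects)
  ))
  if (x$method == "mcmc") {
    rh <- x$diagnostics$rhat
    if (any(is.finite(rh))) {
      cat(sprintf("  max R-hat %.3f, min ESS %.0f\n",
                  max(rh, na.rm = TRUE),
                  min(x$diagnostics$ess, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' @describeIn fit_skill_model posterior summary: one row per parameter with
#'   mean, SD, credible interval, R-hat and effective sample size.
#' @param x,object a `skill_fit`.
#' @param prob credible-interval mass (default from the fit's priors).
#' @param ... unused.
#' @method tidy skill_fit
#' @export
tidy.skill_fit <- function(x, prob = NULL, ...) {
  prob <- prob %||% x$priors$interval_prob
  method <- x$priors$interval_method
  purrr::map_dfr(colnames(x$draws), function(p) {
    d <- x$draws[, p]
    ci <- credible_interval(d, prob, method)
    tibble::tibble(
      term = p, estimate = mean(d), std.error = sd(d),
      conf.low = ci[1], conf.high = ci[2]
    )
  }) |>
    dplyr::left_join(x$diagnostics, by = c(term = "parameter"))
}

#' @describeIn fit_skill_model one-row fit summary (model, method, draws,
#'   observations, subjects, max R-hat).
#' @method glance skill_fit
#' @export
glance.skill_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    method = x$method,
    n_draws = nrow(x$draws),
    n_parameters = ncol(x$draws),
    n_obs = nrow(x$data),
    n_subjects = length(x$subjects),
    max_rhat = if (any(is.finite(x$diagnostics$rhat)))
      max(x$diagnostics$rhat, na.rm = TRUE) else NA_real_
  )
}
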