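# Mean-field Gaussian variational approximation (ADVI-style).
#
# Positive scale parameters are log-transformed; the variational family is
# an independent normal per unconstrained parameter. The ELBO gradient is
# estimated with reparameterised Monte Carlo samples using the analytic
# gradient of the log joint density, and optimised with Adam. theta and
# gamma keep genuinely flat priors here (no bounding needed).

# parameter layout per model: named index list into the unconstrained vector
vi_layout <- function(model, J, theta_fixed = NULL) {
  if (model == 1) {
    list(alpha = 1L, beta = 2L, ls = 3L, n = 3L)
  } else if (model == 2) {
    list(alpha = 1L, beta = 1L + seq_len(J), mu_beta = J + 2L,
         lsb = J + 3L, ls = J + 4L, n = J + 4L)
  } else if (model == 3) {
    list(alpha = seq_len(J), mu_alpha = J + 1L, beta = J + 2L,
         lsa = J + 3L, ls = J + 4L, n = J + 4L)
  } else {
    k <- 2L * J
    if (is.null(theta_fixed)) {
      list(alpha = seq_len(J), beta = J + seq_len(J), theta = k + 1L,
           gamma = k + 2L, mu_beta = k + 3L, lsa = k + 4L, lsb = k + 5L,
           ls = k + 6L, n = k + 6L)
    } else {
      list(alpha = seq_len(J), beta = J + seq_len(J),
           gamma = k + 1L, mu_beta = k + 2L, lsa = k + 3L, lsb = k + 4L,
           ls = k + 5L, n = k + 5L)
    }
  }
}

# log joint density and its gradient at unconstrained z
vi_log_post <- function(z, lay, model, y, x, subj, J, priors, theta_fixed) {
  fe_prec <- priors$fixed_effect_precision
  hs <- priors$half_cauchy_scale
  g <- numeric(lay$n)
  lp <- 0

  # half-Cauchy prior on sigma = exp(ls), including the log Jacobian
  hc_term <- function(ls_idx) {
    s <- exp(z[ls_idx])
    lp <<- lp + log(2 / (pi * hs)) - log1p((s / hs)^2) + z[ls_idx]
    g[ls_idx] <<- g[ls_idx] + 1 - 2 * s^2 / (hs^2 + s^2)
  }
  vague_term <- function(idx) {
    lp <<- lp - 0.5 * fe_prec * sum(z[idx]^2)
    g[idx] <<- g[idx] - fe_prec * z[idx]
  }

  sigma <- exp(z[lay$ls])
  a_obs <- if (length(lay$alpha) > 1) z[lay$alpha][subj] else z[lay$alpha]
  b_obs <- if (length(lay$beta) > 1) z[lay$beta][subj] else z[lay$beta]
  r <- y - (a_obs + b_obs * x)
  N <- length(y)
  lp <- lp - N * (0.5 * log(2 * pi) + z[lay$ls]) - sum(r^2) / (2 * sigma^2)
  g[lay$ls] <- g[lay$ls] + sum(r^2) / sigma^2 - N
  ra <- r / sigma^2
  if (length(lay$alpha) > 1) {
    g[lay$alpha] <- g[lay$alpha] +
      as.numeric(rowsum(ra, subj, reorder = TRUE))
  } else {
    g[lay$alpha] <- g[lay$alpha] + sum(ra)
  }
  if (length(lay$beta) > 1) {
    g[lay$beta] <- g[lay$beta] +
      as.numeric(rowsum(ra * x, subj, reorder = TRUE))
  } else {
    g[lay$beta] <- g[lay$beta] + sum(ra * x)
  }

  if (model == 1) {
    vague_term(c(lay$alpha, lay$beta))
  } else if (model == 2) {
    vague_term(c(lay$alpha, lay$mu_beta))
    sb <- exp(z[lay$lsb])
    rb <- z[lay$beta] - z[lay$mu_beta]
    lp <- lp - J * (0.5 * log(2 * pi) + z[lay$lsb]) - sum(rb^2) / (2 * sb^2)
    g[lay$beta] <- g[lay$beta] - rb / sb^2
    g[lay$mu_beta] <- g[lay$mu_beta] + sum(rb) / sb^2
    g[lay$lsb] <- g[lay$lsb] + sum(rb^2) / sb^2 - J
    hc_term(lay$lsb)
  } else if (model == 3) {
    vague_term(c(lay$mu_alpha, lay$beta))
    sa <- exp(z[lay$lsa])
    ra2 <- z[lay$alpha] - z[lay$mu_alpha]
    lp <- lp - J * (0.5 * log(2 * pi) + z[lay$lsa]) - sum(ra2^2) / (2 * sa^2)
    g[lay$alpha] <- g[lay$alpha] - ra2 / sa^2
    g[lay$mu_alpha] <- g[lay$mu_alpha] + sum(ra2) / sa^2
    g[lay$lsa] <- g[lay$lsa] + sum(ra2^2) / sa^2 - J
    hc_term(lay$lsa)
  } else {
    vague_term(lay$mu_beta)
    theta <- if (is.null(theta_fixed)) z[lay$theta] else theta_fixed
    sa <- exp(z[lay$lsa])
    sb <- exp(z[lay$lsb])
    m_a <- theta * z[lay$beta] + z[lay$gamma]
    ra2 <- z[lay$alpha] - m_a
    lp <- lp - J * (0.5 * log(2 * pi) + z[lay$lsa]) - sum(ra2^2) / (2 * sa^2)
    g[lay$alpha] <- g[lay$alpha] - ra2 / sa^2
    g[lay$beta] <- g[lay$beta] + theta * ra2 / sa^2
    if (is.null(theta_fixed)) {
      g[lay$theta] <- g[lay$theta] + sum(z[lay$beta] * ra2) / sa^2
    }
    g[lay$gamma] <- g[lay$gamma] + sum(ra2) / sa^2
    g[lay$lsa] <- g[lay$lsa] + sum(ra2^2) / sa^2 - J
    rb <- z[lay$beta] - z[lay$mu_beta]
    lp <- lp - J * (0.5 * log(2 * pi) + z[lay$lsb]) - sum(rb^2) / (2 * sb^2)
    g[lay$beta] <- g[lay$beta] - rb / sb^2
    g[lay$mu_beta] <- g[lay$mu_beta] + sum(rb) / sb^2
    g[lay$lsb] <- g[lay$lsb] + sum(rb^2) / sb^2 - J
    hc_term(lay$lsa)
    hc_term(lay$lsb)
  }
  hc_term(lay$ls)
  list(lp = lp, grad = g)
}

vi_init <- function(lay, model, iv, subjects, theta_fixed) {
  ord <- match(subjects, iv$subject)
  z <- numeric(lay$n)
  a <- iv$alpha[ord]
  b <- iv$beta[ord]
  z[lay$alpha] <- if (length(lay$alpha) > 1) a else mean(a)
  z[lay$beta] <- if (length(lay$beta) > 1) b else mean(b)
  z[lay$ls] <- log(iv$sigma)
  if (model == 2) {
    z[lay$mu_beta] <- mean(b)
    z[lay$lsb] <- log(max(sd(b), iv$sigma / 10))
  } else if (model == 3) {
    z[lay$mu_alpha] <- mean(a)
    z[lay$lsa] <- log(max(sd(a), iv$sigma / 10))
  } else if (model == 4) {
    if (is.null(theta_fixed)) z[lay$theta] <- 0
    z[lay$gamma] <- mean(a)
    z[lay$mu_beta] <- mean(b)
    z[lay$lsa] <- log(max(sd(a), iv$sigma / 10))
    z[lay$lsb] <- log(max(sd(b), iv$sigma / 10))
  }
  z
}

fit_vi <- function(data, model, priors, config, theta_fixed = NULL) {
  subjects <- sort(unique(data$subject))
  J <- length(subjects)
  subj <- match(data$subject, subjects)
  y <- data$y
  x <- as.numeric(data$session)
  lay <- vi_layout(model, J, theta_fixed)
  iv <- initial_values(data)

  m <- vi_init(lay, model, iv, subjects, theta_fixed)
  omega <- rep(log(max(sd(y), 1e-6) / 10), lay$n)

  # Adam state
  lr <- 0.05
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  mm <- vv <- numeric(2 * lay$n)
  n_mc <- config$vi_samples

  withr::with_seed(stage_seed(config$seed, "vi"), {
    for (it in seq_len(config$vi_iterations)) {
      gm <- numeric(lay$n)
      go <- numeric(lay$n)
      for (s in seq_len(n_mc)) {
        epsv <- rnorm(lay$n)
        zs <- m + exp(omega) * epsv
        lpg <- vi_log_post(zs, lay, model, y, x, subj, J, priors, theta_fixed)
        gm <- gm + lpg$grad
        go <- go + lpg$grad * epsv * exp(omega)
      }
      gm <- gm / n_mc
      go <- go / n_mc + 1 # + d/domega of the entropy term
      grad <- c(gm, go)
      mm <- b1 * mm + (1 - b1) * grad
      vv <- b2 * vv + (1 - b2) * grad^2
      mhat <- mm / (1 - b1^it)
      vhat <- vv / (1 - b2^it)
      step <- lr * mhat / (sqrt(vhat) + eps)
      m <- m + step[seq_len(lay$n)]
      omega <- omega + step[lay$n + seq_len(lay$n)]
      omega <- pmin(pmax(omega, -20), 5)
    }
    # sample the fitted approximation
    S <- config$vi_draws
    Z <- matrix(rnorm(S * lay$n), S, lay$n)
    Z <- sweep(sweep(Z, 2, exp(omega), "*"), 2, m, "+")
    draws <- vi_draws_matrix(Z, lay, model, J, theta_fixed)
  })

  diagnostics <- tibble::tibble(
    parameter = colnames(draws), rhat = NA_real_, ess = NA_real_
  )
  list(
    model = model, method = "vi", draws = draws, mcmc = NULL,
    diagnostics = diagnostics, subjects = subjects, data = data,
    priors = priors, config = config, seed = config$seed,
    theta_fixed = theta_fixed,
    vi = list(mean = m, log_sd = omega, layout = lay)
  )
}

# name the columns like the JAGS output so downstream code is agnostic
vi_draws_matrix <- function(Z, lay, model, J, theta_fixed) {
  cols <- list()
  grab <- function(idx, stem) {
    m <- Z[, idx, drop = FALSE]
    colnames(m) <- if (length(idx) > 1) {
      sprintf("%s[%d]", stem, seq_along(idx))
    } else {
      stem
    }
    m
  }
  cols$alpha <- grab(lay$alpha, "alpha")
  cols$beta <- grab(lay$beta, "beta")
  if (model == 2) {
    cols$mu_beta <- grab(lay$mu_beta, "mu_beta")
    cols$sigma_beta <- exp(grab(lay$lsb, "lsb")); colnames(cols$sigma_beta) <- "sigma_beta"
  } else if (model == 3) {
    cols$mu_alpha <- grab(lay$mu_alpha, "mu_alpha")
    cols$sigma_alpha <- exp(grab(lay$lsa, "lsa")); colnames(cols$sigma_alpha) <- "sigma_alpha"
  } else if (model == 4) {
    if (is.null(theta_fixed)) cols$theta <- grab(lay$theta, "theta")
    cols$gamma <- grab(lay$gamma, "gamma")
    cols$mu_beta <- grab(lay$mu_beta, "mu_beta")
    cols$sigma_alpha <- exp(grab(lay$lsa, "lsa")); colnames(cols$sigma_alpha) <- "sigma_alpha"
    cols$sigma_beta <- exp(grab(lay$lsb, "lsb")); colnames(cols$sigma_beta) <- "sigma_beta"
  }
  sigma <- exp(Z[, lay$ls, drop = FALSE])
  colnames(sigma) <- "sigma"
  cols$sigma <- sigma
  do.call(cbind, unname(cols))
}
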