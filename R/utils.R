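# internal numerical helpers

# log(mean(exp(x))) per column, stable against underflow
col_log_mean_exp <- function(m) {
  mx <- apply(m, 2, max)
  log(colMeans(exp(sweep(m, 2, mx, "-")))) + mx
}

# sample variance per column (denominator S - 1)
col_var <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("variance over draws needs at least 2 draws", call. = FALSE)
  mu <- colMeans(m)
  colSums(sweep(m, 2, mu, "-")^2) / (n - 1)
}

#' Posterior credible interval of a vector of draws
#'
#' Highest-density interval (shortest interval containing `prob` of the
#' draws, via [coda::HPDinterval()]) or the equal-tailed quantile interval.
#'
#' @param draws numeric vector of posterior draws.
#' @param prob interval probability mass (default 0.94).
#' @param method `"hdi"` (default) or `"eti"` (equal-tailed).
#' @return length-2 numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, prob = 0.94, method = c("hdi", "eti")) {
  method <- match.arg(method)
  stopifnot(is.numeric(draws), length(draws) >= 1, prob > 0, prob < 1)
  if (length(unique(draws)) == 1L) {
    return(c(draws[1], draws[1]))
  }
  if (method == "hdi") {
    iv <- coda::HPDinterval(coda::as.mcmc(as.numeric(draws)), prob = prob)
    c(iv[1, "lower"], iv[1, "upper"])
  } else {
    unname(quantile(draws, c((1 - prob) / 2, 1 - (1 - prob) / 2)))
  }
}

# per-stage seeds derived from one run seed; stage indices keep stages
# independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    latents = 11L, metrics = 29L, trajectories = 47L, exclusions = 61L,
    fit = 101L, vi = 131L, loso = 151L, classify = 179L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
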