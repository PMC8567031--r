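#' Configure an end-to-end pipeline run
#'
#' @param seed run seed; every stage derives its own sub-seed from it.
#' @param out_dir output directory (created if missing).
#' @param metrics which metrics to analyse (`"position"`, `"velocity"`).
#' @param models model numbers compared by LOSO WAIC (default 1:4).
#' @param level `"metrics"` simulates per-trial metrics directly;
#'   `"trajectories"` simulates full circle drawings and runs the metric
#'   stage on them.
#' @param input_metrics,input_trajectories optional CSV paths; when given,
#'   the simulation stage is skipped and data are read instead.
#' @param stages stages to run, a subset of
#'   `c("compare", "boundary", "classify", "groups")` (the data/metrics/fit
#'   stages always run).
#' @param position_config,velocity_config [generator_config()]s used when
#'   simulating.
#' @param traj_config [trajectory_config()] used at
#'   `level = "trajectories"`.
#' @param target [target_spec()].
#' @param priors [prior_config()].
#' @param fit [fit_config()].
#' @param use_cache reuse posterior CSVs found in `out_dir` when the config
#'   hash matches (default TRUE).
#' @param verbose log stage progress to stderr.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("skillbound-run-"),
                       metrics = c("position", "velocity"), models = 1:4,
                       level = c("metrics", "trajectories"),
                       input_metrics = NULL, input_trajectories = NULL,
                       stages = c("compare", "boundary", "classify", "groups"),
                       position_config = generator_config(metric = "position"),
                       velocity_config = generator_config(metric = "velocity"),
                       traj_config = trajectory_config(),
                       target = target_spec(),
                       priors = prior_config(),
                       fit = fit_config(),
                       use_cache = TRUE,
                       verbose = TRUE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(input_metrics, input_trajectories)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), out_dir = out_dir, metrics = metrics,
      models = models, level = match.arg(level),
      input_metrics = input_metrics,
      input_trajectories = input_trajectories, stages = stages,
      position_config = position_config, velocity_config = velocity_config,
      traj_config = traj_config, target = target, priors = priors,
      fit = fit, use_cache = use_cache, verbose = verbose
    ),
    class = "run_config"
  )
}

pipeline_log <- function(config, stage, ...) {
  if (isTRUE(config$verbose)) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
}

config_hash <- function(config) {
  keep <- config[c("seed", "metrics", "models", "level", "position_config",
                   "velocity_config", "priors", "fit")]
  digest::digest(keep, algo = "md5")
}

#' Run the full analysis pipeline
#'
#' simulate (or read) → metrics → fit the four models per metric → LOSO
#' WAIC comparison → boundary → LOSO classification → dual-metric groups,
#' writing one CSV per stage plus a provenance record (seed, config hash,
#' package version, per-stage warnings) into `config$out_dir`. Reruns with
#' the same config reuse cached posterior draws.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of every stage
#'   (`metrics`, `fits`, `comparison`, `boundaries`, `classification`,
#'   `groups`, `provenance`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, w)

  # --- data stage ---------------------------------------------------------
  metrics_tbl <- withCallingHandlers(
    pipeline_data_stage(config),
    warning = function(w) {
      note(paste("data:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  write_metrics(metrics_tbl, file.path(config$out_dir, "metrics.csv"))
  pipeline_log(config, "metrics", "wrote %d metric rows", nrow(metrics_tbl))

  results <- list(metrics = metrics_tbl, fits = list(), comparison = list(),
                  boundaries = list(), classification = list())

  for (metric in config$metrics) {
    data <- as_skill_data(metrics_tbl, metric = metric)

    # --- fit stage (cached) ----------------------------------------------
    fits <- purrr::map(config$models, function(m) {
      cache <- file.path(config$out_dir,
                         sprintf("posterior_%s_model%d.csv", metric, m))
      if (config$use_cache && file.exists(cache) &&
          file.exists(paste0(cache, ".json")) &&
          identical(cached_config_hash(config$out_dir), hash)) {
        pipeline_log(config, "fit", "%s model %d: cached", metric, m)
        return(read_posterior(cache, data))
      }
      fcfg <- config$fit
      fcfg$seed <- stage_seed(config$seed, "fit") + 10L * m +
        (metric == "velocity")
      fit <- withCallingHandlers(
        fit_skill_model(data, model = m, priors = config$priors, config = fcfg),
        warning = function(w) {
          note(sprintf("fit %s model %d: %s", metric, m, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      write_posterior(fit, cache)
      pipeline_log(config, "fit", "%s model %d: %d draws", metric, m,
                   nrow(fit$draws))
      fit
    })
    names(fits) <- paste0("model", config$models)
    results$fits[[metric]] <- fits

    # --- comparison stage --------------------------------------------------
    if ("compare" %in% config$stages) {
      cmp <- withCallingHandlers(
        loso_waic(data, models = config$models, priors = config$priors,
                  config = config$fit),
        warning = function(w) {
          note(sprintf("compare %s: %s", metric, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      readr::write_csv(tidy(cmp),
                       file.path(config$out_dir,
                                 sprintf("waic_%s.csv", metric)),
                       progress = FALSE)
      pipeline_log(config, "compare", "%s: best model %d", metric,
                   cmp$best_model)
      results$comparison[[metric]] <- cmp
    }

    # --- boundary stage -----------------------------------------------------
    if ("boundary" %in% config$stages && "model4" %in% names(fits)) {
      b <- derive_boundary(fits$model4)
      readr::write_csv(tidy(b),
                       file.path(config$out_dir,
                                 sprintf("boundary_%s.csv", metric)),
                       progress = FALSE)
      pipeline_log(config, "boundary", "%s: gamma %.4f [%.4f, %.4f]",
                   metric, b$gamma_mean, b$ci_low, b$ci_high)
      results$boundaries[[metric]] <- b
    }

    # --- classification stage ----------------------------------------------
    if ("classify" %in% config$stages) {
      cls <- withCallingHandlers(
        loso_classification(data, priors = config$priors, config = config$fit),
        warning = function(w) {
          note(sprintf("classify %s: %s", metric, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      readr::write_csv(tidy(cls),
                       file.path(config$out_dir,
                                 sprintf("classification_%s.csv", metric)),
                       progress = FALSE)
      readr::write_csv(
        tibble::as_tibble(cls$confusion),
        file.path(config$out_dir, sprintf("confusion_%s.csv", metric)),
        progress = FALSE
      )
      pipeline_log(config, "classify", "%s: accuracy %.2f, F %.2f", metric,
                   cls$accuracy, cls$f_measure)
      results$classification[[metric]] <- cls
    }
  }

  # --- groups stage ---------------------------------------------------------
  if ("groups" %in% config$stages &&
      all(c("position", "velocity") %in% names(results$boundaries))) {
    pos_means <- initial_skill(as_skill_data(metrics_tbl, "position"))
    vel_means <- initial_skill(as_skill_data(metrics_tbl, "velocity"))
    groups <- assign_groups(pos_means, vel_means,
                            results$boundaries$position,
                            results$boundaries$velocity)
    readr::write_csv(groups, file.path(config$out_dir, "groups.csv"),
                     progress = FALSE)
    readr::write_csv(
      tibble::as_tibble(attr(groups, "group_counts")),
      file.path(config$out_dir, "group_counts.csv"), progress = FALSE
    )
    pipeline_log(config, "groups", "%s",
                 paste(capture_counts(groups), collapse = ", "))
    results$groups <- groups
  }

  provenance <- list(
    config_hash = hash,
    seed = config$seed,
    package = "skillbound",
    version = as.character(packageVersion("skillbound")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    metrics = config$metrics,
    models = config$models,
    warnings = warnings_log
  )
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(hash, file.path(config$out_dir, "config_hash.txt"))
  results$provenance <- provenance
  invisible(results)
}

capture_counts <- function(groups) {
  tb <- table(groups$group)
  sprintf("%s=%d", names(tb), as.integer(tb))
}

cached_config_hash <- function(out_dir) {
  f <- file.path(out_dir, "config_hash.txt")
  if (file.exists(f)) readLines(f, n = 1) else NA_character_
}

pipeline_data_stage <- function(config) {
  if (!is.null(config$input_metrics)) {
    pipeline_log(config, "data", "reading metrics from %s",
                 config$input_metrics)
    return(read_metrics(config$input_metrics))
  }
  if (!is.null(config$input_trajectories)) {
    pipeline_log(config, "data", "reading trajectories from %s",
                 config$input_trajectories)
    traj <- read_trajectories(config$input_trajectories)
    mt <- metrics_table(traj, config$target)
    mt$excluded <- FALSE
    return(mt)
  }
  pcfg <- config$position_config
  pcfg$seed <- config$seed
  if (config$level == "trajectories") {
    pipeline_log(config, "data", "simulating trajectories (%d subjects)",
                 pcfg$n_subjects)
    traj <- generate_trajectories(pcfg, config$traj_config, config$target)
    write_trajectories(traj, file.path(config$out_dir, "trajectories.csv"))
    mt <- metrics_table(traj, config$target)
    counts <- trial_counts(mt)
    excl <- traj |>
      dplyr::distinct(.data$subject, .data$session, .data$trial,
                      .data$excluded)
    mt <- dplyr::left_join(
      mt, excl, by = c("subject", "session", "trial")
    )
    return(mt)
  }
  pipeline_log(config, "data", "simulating metrics (%d subjects)",
               pcfg$n_subjects)
  vcfg <- config$velocity_config
  simulate_study(pcfg, vcfg, seed = config$seed)
}
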