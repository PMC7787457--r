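# Configuration handling and end-to-end orchestration:
# simulate -> split -> train -> thresholds -> rollout -> evaluate.

run_config_sections <- function() {
  list(
    seed = NULL,
    out_dir = NULL,
    sim = names(formals(sim_config)),
    model = names(formals(model_spec)),
    loss = names(formals(loss_config)),
    train = names(formals(train_config)),
    rollout = c("observed_years", "horizon_years", "min_age",
                "advance_age", "binarize_feedback"),
    evaluation = c("threshold", "years", "cumulative")
  )
}

#' Build a pipeline run configuration
#'
#' A nested key-value configuration with sections `sim`, `model`, `loss`,
#' `train`, `rollout` and `evaluation`; every random stage derives its seed
#' deterministically from the global `seed`. Unknown keys are rejected by
#' name.
#'
#' @param seed Global seed.
#' @param out_dir Directory for the artifact bundle.
#' @param sim,model,loss,train,rollout,evaluation Named lists of overrides
#'   for the corresponding stage defaults.
#' @return A `run_config` list with all defaults resolved.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("hftraj_run_"),
                       sim = list(), model = list(), loss = list(),
                       train = list(), rollout = list(),
                       evaluation = list()) {
  sections <- run_config_sections()
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0) {
      stop_hftraj(sprintf("unknown configuration key '%s' in section '%s'",
                          bad[1], where), "config_error")
    }
  }
  check_keys(sim, setdiff(sections$sim, "seed"), "sim")
  check_keys(model, sections$model, "model")
  check_keys(loss, sections$loss, "loss")
  check_keys(train, setdiff(sections$train, "seed"), "train")
  check_keys(rollout, sections$rollout, "rollout")
  check_keys(evaluation, sections$evaluation, "evaluation")
  rollout_defaults <- list(observed_years = 15, horizon_years = 10,
                           min_age = 40, advance_age = FALSE,
                           binarize_feedback = NA)
  eval_defaults <- list(threshold = "conservative", years = 10,
                        cumulative = FALSE)
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    sim = utils::modifyList(list(), sim),
    model = utils::modifyList(list(), model),
    loss = utils::modifyList(list(), loss),
    train = utils::modifyList(list(), train),
    rollout = utils::modifyList(rollout_defaults, rollout),
    evaluation = utils::modifyList(eval_defaults, evaluation)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round trips are lossless: `read_run_config(write_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return The configuration (read) or `path` invisibly (write).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(run_config_sections()))
  if (length(bad) > 0) {
    stop_hftraj(sprintf("unknown configuration key '%s'", bad[1]),
                "config_error")
  }
  do.call(run_config, raw)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint holds the architecture specification, all named parameter
#' arrays and the encoding contract; the loader validates parameter shape
#' consistency against the specification.
#'
#' @param model An `hf_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `hf_model` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hf_model")) {
    stop_hftraj("checkpoint does not contain an hf_model", "io_error")
  }
  ref <- init_model_params(model$spec, seed = 1L)
  check <- function(a, b, where) {
    if (is.list(a)) {
      if (!setequal(names(a), names(b))) {
        stop_hftraj(paste0("checkpoint parameter mismatch at ", where), "io_error")
      }
      for (nm in names(a)) check(a[[nm]], b[[nm]], paste0(where, "$", nm))
    } else if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
      stop_hftraj(paste0("checkpoint shape mismatch at ", where), "io_error")
    }
  }
  check(ref, model$params, "params")
  model
}

#' Run the full pipeline
#'
#' Simulates (or loads) a cohort, assigns patient-level splits, trains the
#' configured model, computes the four decision thresholds, rolls out test
#' trajectories and evaluates both tasks, writing every artifact (cohort
#' CSV, model checkpoint, training log, forecasts CSV, evaluation report
#' JSON, resolved-configuration log) under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built cohort; when supplied the simulation
#'   stage is skipped.
#' @return Invisibly, a list with the in-memory artifacts and their paths.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_hftraj(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)), "pipeline_error")
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    model = file.path(config$out_dir, "model.rds"),
    training_log = file.path(config$out_dir, "training_log.csv"),
    forecasts = file.path(config$out_dir, "forecasts.csv"),
    report = file.path(config$out_dir, "report.json"),
    config = file.path(config$out_dir, "config.yaml")
  )
  write_run_config(config, paths$config)

  cohort <- stage("simulate", {
    if (is.null(cohort)) {
      sim_args <- utils::modifyList(
        config$sim, list(seed = derive_seed(config$seed, "simulate")))
      cohort <- simulate_cohort(do.call(sim_config, sim_args))
    }
    cohort
  })
  cohort <- stage("split", {
    tc <- do.call(train_config,
                  utils::modifyList(config$train,
                                    list(seed = derive_seed(config$seed, "split"))))
    split_cohort(cohort, fractions = tc$fractions, seed = config$seed)
  })
  write_cohort(cohort, paths$cohort)

  model <- stage("train", {
    spec <- do.call(model_spec, config$model)
    loss <- do.call(loss_config, config$loss)
    tc <- do.call(train_config,
                  utils::modifyList(config$train, list(seed = config$seed)))
    train_model(cohort, spec, loss, tc)
  })
  save_model(model, paths$model)
  readr::write_csv(model$history, paths$training_log, progress = FALSE)

  thresholds <- stage("thresholds", {
    compute_thresholds(
      predict_next_step(model, cohort, split = "train"),
      predict_next_step(model, cohort, split = "validation")
    )
  })

  ro <- config$rollout
  bf <- ro$binarize_feedback
  if (!is.null(bf) && is.na(bf)) bf <- NULL
  roll <- stage("rollout", {
    batch_rollout(model, cohort, observed_years = ro$observed_years,
                  horizon_years = ro$horizon_years, min_age = ro$min_age,
                  split = "test", advance_age = ro$advance_age,
                  binarize_feedback = bf)
  })
  readr::write_csv(as_tibble(roll$forecasts), paths$forecasts,
                   progress = FALSE)

  report <- stage("evaluate", {
    next_step <- evaluate_next_step(model, cohort, split = "test")
    trajectory <- if (nrow(roll$forecasts) > 0) {
      evaluate_trajectory(roll$forecasts, cohort, thresholds,
                          kind = config$evaluation$threshold,
                          years = config$evaluation$years,
                          cumulative = config$evaluation$cumulative,
                          min_age = ro$min_age, split = "test")
    } else NULL
    list(
      next_step = as.list(next_step),
      thresholds = thresholds[c("frequency", "conservative", "balanced",
                                "optimized")],
      trajectory = if (!is.null(trajectory)) {
        lapply(split(trajectory, trajectory$year), as.list)
      },
      n_skipped_rollout = length(roll$skipped),
      # out_dir is machine-specific; the report records only the scientific
      # configuration
      resolved_config = unclass(config)[setdiff(names(config), "out_dir")]
    )
  })
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             paths$report)
  invisible(list(cohort = cohort, model = model, thresholds = thresholds,
                 forecasts = roll$forecasts, skipped = roll$skipped,
                 report = report, paths = paths))
}
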