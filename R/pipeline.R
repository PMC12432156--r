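# End-to-end pipeline: configuration, staged execution, run manifest.

CONFIG_KEYS <- c(
  "data_path", "outdir", "data_types", "target_variables",
  "surv_time_var", "surv_event_var", "covariates",
  "model_class", "fusion", "hpo_iter",
  "features_top_pct", "min_features", "variance_quantile", "log_transform",
  "finetune_fraction", "hyperparameters", "seed"
)

#' Default pipeline configuration
#'
#' @return Named list of every configuration key with its default value.
#' @export
default_config <- function() {
  list(
    data_path = NULL,
    outdir = "omicfuse_run",
    data_types = NULL,
    target_variables = character(),
    surv_time_var = NULL,
    surv_event_var = NULL,
    covariates = character(),
    model_class = "DirectPred",
    fusion = "intermediate",
    hpo_iter = 5,
    features_top_pct = 1,
    min_features = 20,
    variance_quantile = 0.01,
    log_transform = FALSE,
    finetune_fraction = NULL,
    hyperparameters = list(),
    seed = 42
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration file, overlays it on the defaults, then
#' overlays `overrides` (command-line flags) on top. Unknown keys are an
#' error — nothing is silently ignored. Fixed hyperparameter values are
#' checked against the documented search-space bounds unless
#' `allow_override = TRUE`.
#'
#' @param path YAML file path, or `NULL` for pure defaults/overrides.
#' @param overrides Named list of values taking precedence over the file.
#' @param allow_override Permit hyperparameter values outside the standard
#'   search-space bounds.
#' @return A validated `pipeline_config` list; attributes `file_values` and
#'   `overrides` record the two layers for the run manifest.
#' @export
load_config <- function(path = NULL, overrides = list(), allow_override = FALSE) {
  cfg <- default_config()
  file_values <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) of_abort(sprintf("config file not found: %s", path))
    file_values <- yaml::read_yaml(path) %||% list()
    if (!is.list(file_values)) of_abort("config file must be a YAML mapping.")
  }
  for (layer in list(file_values, overrides)) {
    unknown <- setdiff(names(layer), CONFIG_KEYS)
    if (length(unknown)) {
      of_abort(sprintf("unknown configuration key(s): %s (valid: %s)",
                       paste(unknown, collapse = ", "),
                       paste(CONFIG_KEYS, collapse = ", ")))
    }
    for (nm in names(layer)) cfg[[nm]] <- layer[[nm]]
  }
  if (!cfg$model_class %in% ARCHITECTURES) {
    of_abort(sprintf("unknown model_class '%s'; valid architectures: %s",
                     cfg$model_class, paste(ARCHITECTURES, collapse = ", ")),
             class = "omicfuse_usage_error")
  }
  if (!cfg$fusion %in% c("early", "intermediate")) {
    of_abort("`fusion` must be 'early' or 'intermediate'.",
             class = "omicfuse_usage_error")
  }
  if (!is_count(cfg$hpo_iter + 1)) of_abort("`hpo_iter` must be >= 0.")
  if (!is.null(cfg$finetune_fraction) &&
      !(is.numeric(cfg$finetune_fraction) && cfg$finetune_fraction > 0 &&
        cfg$finetune_fraction < 1)) {
    of_abort("`finetune_fraction` must be in (0, 1).")
  }
  hp <- cfg$hyperparameters
  bad_hp <- setdiff(names(hp), names(formals(hyper_config)))
  if (length(bad_hp)) {
    of_abort(sprintf("unknown hyperparameter(s): %s", paste(bad_hp, collapse = ", ")))
  }
  if (length(hp)) {
    # full config with fixed values substituted; bounds enforced unless
    # explicitly overridden
    do.call(hyper_config, c(hp, list(validate = !allow_override)))
  }
  structure(cfg, class = "pipeline_config",
            file_values = file_values, overrides = overrides)
}

infer_task_kinds <- function(metadata, target_variables) {
  kinds <- vapply(target_variables, function(v) {
    if (!v %in% names(metadata)) {
      of_abort(sprintf("target variable '%s' not found in the metadata.", v))
    }
    if (is.numeric(metadata[[v]])) "regression" else "classification"
  }, "")
  names(kinds) <- target_variables
  kinds
}

#' Run the full analysis pipeline
#'
#' Executes import, cleaning/harmonization (with optional unsupervised
#' feature selection), hyperparameter optimization, final training, held-out
#' test evaluation, feature attribution, and (optionally) fine-tuning on a
#' fraction of the test split. Every artifact is written under
#' `config$outdir` and recorded — with a checksum — in `manifest.json`.
#'
#' @param config A validated [load_config()] result (or a bare named list of
#'   the same keys, which will be validated first).
#' @return Invisibly, a list with `model`, `bundle`, `metrics`, `markers`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- load_config(NULL, overrides = config)
  }
  if (is.null(config$data_path)) of_abort("`data_path` is required.")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  timings <- list()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    of_log("%s", line)
  }
  stage <- function(name, expr) {
    say("stage '%s' started", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      say("stage '%s' FAILED: %s", name, conditionMessage(e))
      writeLines(log_lines, file.path(outdir, "run.log"))
      of_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say("stage '%s' finished (%.2fs)", name, timings[[name]])
    out
  }
  seed <- config$seed
  stage_seeds <- list(split = derive_seed(seed, 1), hpo = derive_seed(seed, 2),
                      final = derive_seed(seed, 3), attribution = derive_seed(seed, 4),
                      finetune = derive_seed(seed, 5))

  train_dir <- file.path(config$data_path, "train")
  test_dir <- file.path(config$data_path, "test")
  input_files <- c(list.files(train_dir, full.names = TRUE),
                   list.files(test_dir, full.names = TRUE))
  input_checksums <- as.list(tools::md5sum(input_files))

  dataset <- stage("import", {
    read_omics_dataset(train_dir, test_dir, modality_names = config$data_types)
  })

  bundle <- stage("harmonize", {
    kinds <- infer_task_kinds(dataset$train$metadata, config$target_variables)
    surv_cols <- NULL
    if (!is.null(config$surv_time_var) && !is.null(config$surv_event_var)) {
      kinds <- c(kinds, surv = "survival")
      surv_cols <- list(surv = c(time = config$surv_time_var,
                                 event = config$surv_event_var))
    }
    if (length(kinds) == 0) of_abort("no prediction target declared.")
    ts <- task_spec(kinds, survival_cols = surv_cols,
                    covariates = config$covariates)
    harmonize(dataset, ts,
              variance_quantile = config$variance_quantile,
              feature_top_fraction = config$features_top_pct,
              min_features = config$min_features,
              log_transform = config$log_transform)
  })

  template <- model_spec(config$model_class, config$fusion,
                         hyper = do.call(hyper_config,
                                         c(config$hyperparameters,
                                           list(validate = FALSE))))
  policy <- training_policy(seed = stage_seeds$split)

  best_spec <- template
  hpo_trials <- NULL
  if (config$hpo_iter > 0) {
    hpo <- stage("hpo", {
      # fixed hyperparameters are pinned: drop them from the search space
      space <- default_search_space(config$model_class)
      space <- Filter(function(p) !p$name %in% names(config$hyperparameters), space)
      hpo_search(template, bundle, space = space, n_iter = config$hpo_iter,
                 policy = training_policy(seed = stage_seeds$hpo),
                 n_init = min(5, config$hpo_iter))
    })
    best_spec <- hpo$best_spec
    hpo_trials <- hpo$trials
  }

  model <- stage("final_train", {
    train_once(best_spec, bundle, training_policy(seed = stage_seeds$final))
  })

  metrics <- stage("evaluate", evaluate_model(model, bundle, "test"))

  markers <- stage("attribution", {
    compute_markers(model, bundle, "integrated_gradients", top_n = 25,
                    steps = 32, seed = stage_seeds$attribution)
  })

  finetuned <- NULL
  if (!is.null(config$finetune_fraction)) {
    finetuned <- stage("finetune", {
      ft <- finetune(model, bundle,
                     finetune_policy(holdin_fraction = config$finetune_fraction,
                                     seed = stage_seeds$finetune))
      ft$metrics <- evaluate_model(ft$model, bundle, "test", idx = ft$heldout_idx)
      ft
    })
  }

  outputs <- stage("write_artifacts", {
    paths <- c(
      checkpoint = file.path(outdir, "model.rds"),
      embeddings_train = file.path(outdir, "embeddings_train.csv"),
      embeddings_test = file.path(outdir, "embeddings_test.csv"),
      metrics = file.path(outdir, "metrics.json"),
      attribution = file.path(outdir, "attribution.csv")
    )
    saveRDS(model, paths[["checkpoint"]])
    write_embeddings <- function(x, ids, path) {
      emb <- model_forward(model, x, train = FALSE)$embedding
      df <- data.frame(sample_id = ids, emb, check.names = FALSE)
      names(df) <- c("sample_id", paste0("dim_", seq_len(ncol(emb))))
      utils::write.csv(df, path, row.names = FALSE)
    }
    write_embeddings(bundle$x_train, bundle$train_sample_ids, paths[["embeddings_train"]])
    write_embeddings(bundle$x_test, bundle$test_sample_ids, paths[["embeddings_test"]])
    metrics_out <- list(test = metrics)
    if (!is.null(finetuned)) metrics_out$finetuned_heldout <- finetuned$metrics
    jsonlite::write_json(metrics_out, paths[["metrics"]],
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(markers, paths[["attribution"]], row.names = FALSE)
    if (!is.null(hpo_trials)) {
      paths[["hpo_trials"]] <- file.path(outdir, "hpo_trials.csv")
      utils::write.csv(hpo_trials, paths[["hpo_trials"]], row.names = FALSE)
    }
    if (!is.null(finetuned)) {
      paths[["finetuned_checkpoint"]] <- file.path(outdir, "model_finetuned.rds")
      saveRDS(finetuned$model, paths[["finetuned_checkpoint"]])
    }
    paths
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("omicfuse")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[CONFIG_KEYS],
    config_file_values = attr(config, "file_values") %||% list(),
    config_overrides = attr(config, "overrides") %||% list(),
    seed = seed,
    stage_seeds = stage_seeds,
    input_checksums = input_checksums,
    timings = timings,
    outputs = lapply(as.list(outputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  say("wrote manifest %s", manifest_path)
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(list(model = model, bundle = bundle, metrics = metrics,
                 markers = markers, finetuned = finetuned, manifest = manifest))
}
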