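# Experiment orchestration: presets, YAML configs, end-to-end runs.

.preset_table <- list(
  model1  = list(w = 1000, p1 = 1, p2 = 1, dropout = c(0.3, 0.3, 0.3, 0.3), loss = "MSE"),
  model2  = list(w = 1,    p1 = 1, p2 = 1, dropout = c(0.3, 0.3, 0.3, 0.3), loss = "MSE"),
  model3  = list(w = 1,    p1 = 1, p2 = 1, dropout = c(0.4, 0.4, 0.1, 0.1), loss = "MSE"),
  model4  = list(w = 1,    p1 = 0, p2 = 1, dropout = c(0,   0,   0.3, 0.3), loss = "MSE"),
  model5  = list(w = 1,    p1 = 0, p2 = 1, dropout = c(0,   0,   0.1, 0.1), loss = "MSE"),
  model6  = list(w = 1,    p1 = 1, p2 = 0, dropout = c(0.3, 0.3, 0,   0),   loss = "MSE"),
  model7  = list(w = 1,    p1 = 1, p2 = 0, dropout = c(0.4, 0.4, 0,   0),   loss = "MSE"),
  model8  = list(w = 100,  p1 = 1, p2 = 1, dropout = c(0.3, 0.3, 0.3, 0.3), loss = "MAE"),
  model9  = list(w = 100,  p1 = 1, p2 = 1, dropout = c(0.4, 0.4, 0.1, 0.1), loss = "MAE"),
  model10 = list(w = 1,    p1 = 1, p2 = 1, dropout = c(0.3, 0.3, 0.3, 0.3), loss = "MAE"),
  model11 = list(w = 1,    p1 = 1, p2 = 1, dropout = c(0.4, 0.4, 0.1, 0.1), loss = "MAE"),
  model12 = list(w = 1,    p1 = 0, p2 = 1, dropout = c(0,   0,   0.1, 0.1), loss = "MAE"),
  model13 = list(w = 10,   p1 = 0, p2 = 1, dropout = c(0,   0,   0.3, 0.3), loss = "MAE"),
  model14 = list(w = 10,   p1 = 0, p2 = 1, dropout = c(0,   0,   0.1, 0.1), loss = "MAE")
)

#' Named hyperparameter presets
#'
#' The fourteen studied hyperparameter combinations (`model1` ... `model14`):
#' loss weight `w`, branch switches `p1`/`p2`, dropout rates `D1`-`D4`, and
#' loss kind (MAE or MSE). Dropout entries of disabled branches are 0.
#'
#' @param name preset name, e.g. `"model9"` (both branches, dropout
#'   0.4/0.4/0.1/0.1, MAE, w = 100).
#' @return A list with `w`, `p1`, `p2`, `dropout`, `loss` (`"MAE"`/`"MSE"`),
#'   and `alpha` (1 or 2).
#' @export
model_preset <- function(name) {
  p <- .preset_table[[name]]
  if (is.null(p)) stop("unknown preset: ", name, " (model1 ... model14)")
  p$alpha <- if (p$loss == "MAE") 1 else 2
  p
}

.default_config <- function() {
  list(
    grid = list(L = 100L, D = 1, gamma = 1 / 400),
    sampling = list(radius = 5, n_disks = 2L, n_samples = 20000L,
                    split_fraction = 0.8),
    surrogate = list(preset = "model9", grid_size = 100L,
                     base_channels = NULL),
    loss = list(alpha = NULL, w = NULL),
    training = list(epochs = 800L, learning_rate = 1e-3, batch_size = 32L,
                    rollback_C = 5, rollback_m = 20L, rollback_s = 5L,
                    max_rollbacks = 200L),
    evaluation = list(n_slices = 10L, n_bins = 100L, rel_floor = 1e-3),
    seed = 1L
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment file, applies defaults (the 100x100 study preset:
#' `D = 1`, `gamma = 1/400`, radius-5 disks, preset `model9`), rejects unknown
#' keys, and enforces internal consistency (the surrogate grid size must equal
#' the sampling grid size). An empty file yields the full default
#' configuration. Loss settings default to the preset's `alpha`/`w` and can be
#' overridden explicitly.
#'
#' @param path YAML file path (missing/empty file = defaults).
#' @return A validated `experiment_config` list.
#' @export
load_experiment_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path) %||% list()
  }
  cfg <- .default_config()
  for (section in names(user)) {
    if (!section %in% c(names(cfg)))
      stop("unknown config section: ", section)
    if (section == "seed") { cfg$seed <- user$seed; next }
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop(sprintf("unknown key '%s' in section '%s'", key, section))
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  if (!is.null(user$surrogate$grid_size) || !is.null(user$grid$L)) {
    if (is.null(user$surrogate$grid_size)) cfg$surrogate$grid_size <- cfg$grid$L
    if (cfg$surrogate$grid_size != cfg$grid$L)
      stop(sprintf("grid sizes disagree: grid.L = %d, surrogate.grid_size = %d",
                   cfg$grid$L, cfg$surrogate$grid_size))
  }
  preset <- model_preset(cfg$surrogate$preset)
  cfg$loss$alpha <- cfg$loss$alpha %||% preset$alpha
  cfg$loss$w <- cfg$loss$w %||% preset$w
  structure(cfg, class = "experiment_config")
}

# Stable content hash of the data-generation settings (dataset reuse key).
config_dataset_hash <- function(cfg) {
  key <- list(grid = cfg$grid, sampling = cfg$sampling, seed = cfg$seed)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(key, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run a full experiment: generate, train, evaluate, report
#'
#' Executes the pipeline described by an [load_experiment_config()] object:
#' generates the paired dataset (or reuses a cached one with the same
#' grid/sampling settings and seed), builds and trains the surrogate, and
#' evaluates it on the test split. Artifacts written under `out_dir`:
#' `dataset-<hash>.rds`, `checkpoint.rds` (+ YAML sidecar),
#' `training_log.csv`, `report.json`, and `manifest.yml` tying them to the
#' configuration hash and seed.
#'
#' @param config an `experiment_config` (or path to a YAML file).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `model`, `report`, `training`, `manifest`.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- load_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  grid <- grid_spec(config$grid$L, config$grid$D, config$grid$gamma)
  hash <- config_dataset_hash(config)
  ds_path <- file.path(out_dir, paste0("dataset-", hash, ".rds"))
  reused <- file.exists(ds_path)
  dataset <- if (reused) dataset_load(ds_path) else {
    ds <- generate_dataset(config$sampling$n_samples,
                           seed = config$seed, grid = grid,
                           radius = config$sampling$radius,
                           n_disks = config$sampling$n_disks,
                           split_fraction = config$sampling$split_fraction)
    dataset_save(ds, ds_path)
    ds
  }

  preset <- model_preset(config$surrogate$preset)
  spec_args <- list(grid_size = config$surrogate$grid_size,
                    p1 = preset$p1, p2 = preset$p2, dropout = preset$dropout)
  if (!is.null(config$surrogate$base_channels))
    spec_args$base_channels <- config$surrogate$base_channels
  spec <- do.call(surrogate_spec, spec_args)
  model <- build_surrogate(spec, seed = derive_seed(config$seed, "init"))

  tcfg <- train_config(epochs = config$training$epochs,
                       learning_rate = config$training$learning_rate,
                       batch_size = config$training$batch_size,
                       rollback_C = config$training$rollback_C,
                       rollback_m = config$training$rollback_m,
                       rollback_s = config$training$rollback_s,
                       max_rollbacks = config$training$max_rollbacks,
                       seed = config$seed,
                       loss = loss_config(config$loss$alpha, config$loss$w))
  training <- tryCatch(train_surrogate(model, dataset, tcfg),
                       error = function(e) stop("train stage failed: ",
                                                conditionMessage(e)))
  utils::write.csv(training$log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)
  save_model(training$model, file.path(out_dir, "checkpoint.rds"),
             provenance = list(seed = config$seed,
                               epochs = config$training$epochs,
                               preset = config$surrogate$preset,
                               loss = unclass(tcfg$loss),
                               dataset_hash = hash))

  report <- tryCatch(
    residual_report(training$model, dataset, split = "test",
                    n_slices = config$evaluation$n_slices,
                    n_bins = config$evaluation$n_bins,
                    rel_floor = config$evaluation$rel_floor),
    error = function(e) stop("evaluate stage failed: ", conditionMessage(e)))
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(dataset_hash = hash, dataset_reused = reused,
                   seed = config$seed, preset = config$surrogate$preset,
                   best_epoch = training$best_epoch,
                   best_loss = training$best_loss,
                   rollback_count = training$rollback_count,
                   format_version = 1L)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(list(model = training$model, report = report, training = training,
                 manifest = manifest))
}
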