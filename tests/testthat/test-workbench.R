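test_that("presets reproduce the studied hyperparameter rows", {
  p9 <- model_preset("model9")
  expect_identical(p9$w, 100)
  expect_identical(p9$p1, 1)
  expect_identical(p9$p2, 1)
  expect_identical(p9$dropout, c(0.4, 0.4, 0.1, 0.1))
  expect_identical(p9$loss, "MAE")
  expect_identical(p9$alpha, 1)

  p5 <- model_preset("model5")
  expect_identical(p5$p1, 0)
  expect_identical(p5$loss, "MSE")
  expect_identical(p5$dropout, c(0, 0, 0.1, 0.1))
  p1 <- model_preset("model1")
  expect_identical(p1$w, 1000)
  expect_error(model_preset("model99"), "unknown preset")
})

test_that("an empty configuration resolves to the full-scale study defaults", {
  f <- tempfile(fileext = ".yml")
  writeLines("", f)
  cfg <- load_experiment_config(f)
  expect_identical(cfg$grid$L, 100L)
  expect_identical(cfg$grid$D, 1)
  expect_equal(cfg$grid$gamma, 1 / 400)
  expect_identical(cfg$sampling$radius, 5)
  expect_identical(cfg$training$epochs, 800L)
  expect_identical(cfg$surrogate$preset, "model9")
  expect_identical(cfg$loss$alpha, 1)   # inherited from the preset
  expect_identical(cfg$loss$w, 100)
  unlink(f)
})

test_that("unknown keys and inconsistent grids are rejected with field-level messages", {
  f <- tempfile(fileext = ".yml")
  writeLines("grid:\n  L: 32\n  bogus_key: 1\n", f)
  expect_error(load_experiment_config(f), "unknown key 'bogus_key'")
  writeLines("nonsense:\n  a: 1\n", f)
  expect_error(load_experiment_config(f), "unknown config section")
  writeLines("grid:\n  L: 32\nsurrogate:\n  grid_size: 64\n", f)
  expect_error(load_experiment_config(f), "grid sizes disagree")
  unlink(f)
  expect_error(load_experiment_config("/nonexistent/x.yml"), "not found")
})

test_that("a smoke-scale experiment runs end to end and reuses its dataset", {
  f <- tempfile(fileext = ".yml")
  writeLines(
"grid:
  L: 16
sampling:
  radius: 2
  n_samples: 24
surrogate:
  preset: model9
  grid_size: 16
  base_channels: 2
training:
  epochs: 3
  batch_size: 8
seed: 42
", f)
  out_dir <- tempfile()
  res <- run_experiment(f, out_dir)
  expect_true(file.exists(file.path(out_dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(out_dir, "training_log.csv")))
  expect_true(file.exists(file.path(out_dir, "report.json")))
  expect_true(file.exists(file.path(out_dir, "manifest.yml")))
  expect_false(res$manifest$dataset_reused)
  expect_s3_class(res$report, "residual_report")

  res2 <- run_experiment(f, out_dir)
  expect_true(res2$manifest$dataset_reused)
  expect_identical(res2$manifest$dataset_hash, res$manifest$dataset_hash)
  # same seed and config: identical training trajectory
  expect_identical(res2$training$history, res$training$history)

  log <- utils::read.csv(file.path(out_dir, "training_log.csv"))
  expect_identical(names(log), c("epoch", "loss", "rolled_back", "rollback_count"))
  rep <- jsonlite::read_json(file.path(out_dir, "report.json"))
  expect_identical(rep$split, "test")
  unlink(out_dir, recursive = TRUE)
  unlink(f)
})
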