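test_that("the roll-back threshold is C times the trailing-window mean", {
  cfg_m <- 20L
  expect_equal(rollback_threshold(rep(0.3, 50), C = 5, m = cfg_m), 1.5)
  expect_identical(rollback_threshold(1:20, C = 5, m = 20L), 52.5)
  # shorter history than the window: partial-window mean
  expect_identical(rollback_threshold(c(1, 2, 3), C = 5, m = 20L), 10)
  expect_error(rollback_threshold(numeric(0), 5, 20), "empty")
})

test_that("roll-back triggers only after warm-up and only above C times the trend", {
  cfg <- train_config(epochs = 100, rollback_C = 5, rollback_m = 20L,
                      rollback_s = 5L)
  hist <- rep(0.01, 20)
  expect_false(should_rollback(0.01, hist, cfg))       # equal to trend
  expect_false(should_rollback(0.049, hist, cfg))      # below threshold
  expect_true(should_rollback(0.06, hist, cfg))        # 6x the trend
  expect_false(should_rollback(100, rep(0.01, 19), cfg))  # warm-up
  off <- train_config(epochs = 100, rollback_C = Inf)
  expect_false(should_rollback(1e9, rep(1e-9, 50), off))
})

test_that("a scripted loss spike triggers exactly one roll-back with bit-identical restore", {
  cfg <- train_config(epochs = 30, rollback_C = 5, rollback_m = 5L,
                      rollback_s = 3L, max_rollbacks = 10L)
  attempt <- 0L
  seen_payloads <- list()
  run_epoch <- function(payload, epoch) {
    attempt <<- attempt + 1L
    seen_payloads[[attempt]] <<- payload
    loss <- if (attempt == 10L) 50 else 1 / attempt
    list(payload = list(stamp = attempt, blob = runif(5)), loss = loss)
  }
  out <- train_loop(list(stamp = 0L, blob = numeric(5)), run_epoch, cfg)

  expect_identical(out$rollback_count, 1L)
  expect_identical(sum(out$log$rolled_back), 1L)
  expect_length(out$history, 30L)
  # spike at attempt 10 (epoch 10 candidate): revert to the epoch-6 snapshot,
  # i.e. the payload produced by attempt 6, restored without modification
  expect_identical(seen_payloads[[11L]]$stamp, 6L)
  expect_identical(seen_payloads[[11L]],
                   list(stamp = 6L, blob = seen_payloads[[7L]]$blob))
  # the spike epoch consumed budget but was not accepted
  expect_identical(out$epochs_run, 34L)
  expect_false(50 %in% out$history)
  # best checkpoint is the minimum accepted loss
  expect_identical(out$best_loss, min(out$history))
  expect_identical(out$payload$stamp, attempt)
})

test_that("exceeding max_rollbacks and non-finite losses abort with diagnostics", {
  cfg <- train_config(epochs = 50, rollback_C = 2, rollback_m = 3L,
                      rollback_s = 2L, max_rollbacks = 2L)
  run_spiky <- function(payload, epoch) {
    list(payload = payload, loss = if (epoch >= 4) 100 else 1)
  }
  expect_error(train_loop(list(), run_spiky, cfg), "max_rollbacks")

  cfg2 <- train_config(epochs = 5)
  expect_error(train_loop(list(), function(p, e) list(payload = p, loss = NaN),
                          cfg2), "non-finite")
})

test_that("training a real model is deterministic under a fixed seed and reduces the loss", {
  g <- grid_spec(16)
  ds <- generate_dataset(24, seed = 4, grid = g, radius = 2)
  spec <- surrogate_spec(16L, dropout = c(0.2, 0.2, 0.1, 0.1),
                         base_channels = 2L)
  cfg <- train_config(epochs = 6, batch_size = 8, seed = 13,
                      loss = loss_config(1, 100))
  r1 <- train_surrogate(build_surrogate(spec, seed = 21), ds, cfg)
  r2 <- train_surrogate(build_surrogate(spec, seed = 21), ds, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(diffsurr:::model_params(r1$model),
                   diffsurr:::model_params(r2$model))
  expect_lt(r1$history[length(r1$history)], r1$history[1])
  expect_identical(r1$best_loss, min(r1$history))
  expect_identical(r1$rollback_count, 0L)
  expect_s3_class(r1$log, "data.frame")
  expect_identical(nrow(r1$log), r1$epochs_run)
})

test_that("validation-based checkpoint selection picks the best test-split loss", {
  g <- grid_spec(16)
  ds <- generate_dataset(20, seed = 8, grid = g, radius = 2)
  spec <- surrogate_spec(16L, dropout = c(0, 0, 0, 0), base_channels = 2L)
  cfg <- train_config(epochs = 5, batch_size = 8, seed = 31,
                      loss = loss_config(1, 100), select_on = "validation")
  tr <- train_surrogate(build_surrogate(spec, seed = 3), ds, cfg)
  # recompute the validation loss of the returned checkpoint: it must equal
  # the reported best and be the minimum over the per-epoch series
  vt <- diffsurr:::dataset_tensors(ds, "test")
  vp <- diffsurr:::model_forward(tr$model, vt$x, training = FALSE)$y
  expect_equal(weighted_loss(vp, vt$y, cfg$loss), tr$best_loss,
               tolerance = 1e-12)
  # training-loss history is still what roll-back monitors
  expect_length(tr$history, 5L)
})
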