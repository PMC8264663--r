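# Shape and contract tests for the two surrogate branches.

trace_shapes <- function(layers, x) {
  dims <- list()
  for (i in seq_along(layers)) {
    x <- diffsurr:::layer_forward(layers[[i]], x, training = FALSE)$y
    dims[[i]] <- dim(x)
  }
  list(dims = dims, out = x)
}

test_that("the full-scale autoencoder collapses to a 2048x1x1 bottleneck and expands through 1-3-7-13-25-51-100", {
  spec <- surrogate_spec(100L, p1 = 0, p2 = 1, dropout = c(0, 0, 0.1, 0.1))
  expect_identical(spec$nn2_encoder_sizes, c(100L, 50L, 25L, 12L, 6L, 3L))
  expect_identical(spec$nn2_encoder_channels, c(64L, 128L, 256L, 512L, 1024L))
  expect_identical(spec$nn2_bottleneck, 2048L)
  expect_identical(spec$nn2_decoder_sizes, c(1L, 3L, 7L, 13L, 25L, 51L, 100L))

  nn2 <- build_surrogate(spec, seed = 1)$nn2
  tr <- trace_shapes(nn2, array(0, c(100, 100, 1, 1)))
  types <- vapply(nn2, `[[`, "", "type")
  pool_dims <- tr$dims[types == "pool"]
  expect_identical(vapply(pool_dims, `[`, 0L, 1L), c(50L, 25L, 12L, 6L, 3L))
  # bottleneck: output of the last encoder (valid) convolution
  conv_dims <- tr$dims[types == "conv"]
  expect_identical(conv_dims[[length(conv_dims)]], c(1L, 1L, 2048L, 1L))
  tconv_dims <- tr$dims[types == "tconv"]
  expect_identical(vapply(tconv_dims, `[`, 0L, 1L),
                   c(3L, 7L, 13L, 25L, 51L, 100L))
  expect_identical(vapply(tconv_dims, `[`, 0L, 3L),
                   c(1024L, 512L, 256L, 128L, 64L, 1L))
  expect_identical(dim(tr$out), c(100L, 100L, 1L, 1L))
  expect_true(all(is.finite(tr$out)))
  expect_true(all(tr$out >= 0))
})

test_that("the deep CNN branch preserves spatial size through its 1-4-8-16-8-4-1 channel sequence", {
  for (L in c(32L, 100L)) {
    spec <- surrogate_spec(L, p1 = 1, p2 = 0, dropout = c(0.4, 0.4, 0, 0))
    nn1 <- build_surrogate(spec, seed = 2)$nn1
    tr <- trace_shapes(nn1, array(0, c(L, L, 1, 1)))
    types <- vapply(nn1, `[[`, "", "type")
    conv_dims <- tr$dims[types == "conv"]
    expect_identical(vapply(conv_dims, `[`, 0L, 3L), c(4L, 8L, 16L, 8L, 4L, 1L))
    expect_true(all(vapply(conv_dims, `[`, 0L, 1L) == L))
    expect_identical(dim(tr$out), c(L, L, 1L, 1L))
  }
})

test_that("scaled presets mirror the encoder size sequence back up to the grid", {
  spec <- surrogate_spec(32L, base_channels = 8L)
  expect_identical(spec$nn2_encoder_sizes, c(32L, 16L, 8L, 4L))
  expect_identical(spec$nn2_bottleneck, 64L)
  expect_identical(spec$nn2_decoder_sizes, c(1L, 4L, 8L, 16L, 32L))
  x <- matrix(runif(32 * 32), 32, 32)
  m <- build_surrogate(spec, seed = 3)
  expect_identical(dim(predict(m, x)), c(32L, 32L))
})

test_that("prediction is the p-weighted sum of the branch outputs", {
  spec <- surrogate_spec(16L, p1 = 1, p2 = 1, dropout = c(0, 0, 0, 0),
                         base_channels = 2L)
  m <- build_surrogate(spec, seed = 4)
  x4 <- array(runif(16 * 16), c(16, 16, 1, 1))
  y1 <- diffsurr:::net_forward(m$nn1, x4, training = FALSE)$y
  y2 <- diffsurr:::net_forward(m$nn2, x4, training = FALSE)$y
  both <- predict(m, x4[, , 1, 1])
  expect_equal(both, (y1 + y2)[, , 1, 1], tolerance = 1e-14)

  # p1 = 0 builds and uses only the autoencoder branch
  m2 <- build_surrogate(surrogate_spec(16L, p1 = 0, p2 = 1,
                                       dropout = c(0, 0, 0, 0),
                                       base_channels = 2L), seed = 4)
  expect_null(m2$nn1)
  expect_identical(dim(predict(m2, x4[, , 1, 1])), c(16L, 16L))
})

test_that("inference is deterministic, non-negative, and dropout-free", {
  m <- tiny_surrogate(seed = 8, dropout = c(0.5, 0.5, 0.5, 0.5))
  x <- matrix(runif(16 * 16), 16, 16)
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
})

test_that("parameter counts are a pure function of the spec", {
  expect_identical(model_parameter_count(
    build_surrogate(surrogate_spec(32L), seed = 1)), 85006L)
  expect_identical(model_parameter_count(
    build_surrogate(surrogate_spec(32L), seed = 99)), 85006L)
})

test_that("models round-trip through serialization with identical predictions", {
  m <- tiny_surrogate(seed = 11)
  x <- matrix(runif(16 * 16), 16, 16)
  f <- tempfile(fileext = ".rds")
  save_model(m, f, provenance = list(seed = 11))
  m2 <- load_model(f)
  expect_identical(predict(m2, x), predict(m, x))
  expect_true(file.exists(paste0(f, ".yml")))
  unlink(c(f, paste0(f, ".yml")))
})
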