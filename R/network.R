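#' Architecture specification of the dual-branch surrogate
#'
#' The surrogate maps the source-layout image to the steady-state field as a
#' weighted sum of two branches, \eqn{\hat y = p_1 \hat y_1 + p_2 \hat y_2}:
#'
#' * **NN 1** — a size-preserving deep CNN: six 3x3 stride-1 padded
#'   convolutions with channel sequence 1-4-8-16-8-4-1, leaky-ReLU activations
#'   on layers 1-5 and a final ReLU, batch normalization per layer, dropout
#'   `D1` after layer 1 and `D2` in the final stage. This branch resolves the
#'   sources sharply but cannot propagate information across the domain.
#' * **NN 2** — a convolutional autoencoder: repeated
#'   \[3x3 padded convolution + leaky-ReLU, 2x2 mean-pool (floor)\] stages that
#'   halve the spatial size while doubling channels, a final unpadded
#'   convolution collapsing the last feature map to a 1x1 bottleneck, then
#'   transpose convolutions expanding back to the full grid. Batch norm and
#'   dropout `D3` follow the first encoder convolution; dropout `D4` precedes
#'   the final transpose convolution. The bottleneck forces this branch to
#'   learn the global structure of the field.
#'
#' For `grid_size = 100` the exact full-scale reference schedule is used: encoder sizes
#' 100-50-25-12-6-3 with channels 64-128-256-512-1024 and a 2048-channel 1x1
#' bottleneck; decoder spatial trace 1-3-7-13-25-51-100 with channels
#' 2048-1024-512-256-128-64-1. For other grid sizes the encoder pools (floor
#' halving) until the spatial size is at most 4, collapses to 1x1, and the
#' decoder mirrors the encoder size sequence; `base_channels` scales the
#' channel widths (default 8 for scaled presets).
#'
#' @param grid_size lattice linear size in pixels.
#' @param p1,p2 branch mixing weights; the study presets use 0/1 values and at
#'   least one branch must be active.
#' @param dropout numeric length-4 vector `(D1, D2, D3, D4)`, each in `[0, 1)`.
#' @param base_channels first encoder channel width of NN 2 (64 for the
#'   100x100 preset).
#' @param leaky_slope negative slope of the leaky-ReLU activations.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(grid_size = 100L, p1 = 1, p2 = 1,
                           dropout = c(0.4, 0.4, 0.1, 0.1),
                           base_channels = if (grid_size == 100L) 64L else 8L,
                           leaky_slope = 0.01) {
  grid_size <- as.integer(grid_size)
  stopifnot(grid_size >= 8L, length(dropout) == 4L,
            all(dropout >= 0), all(dropout < 1),
            p1 >= 0, p2 >= 0, p1 > 0 || p2 > 0)

  # encoder spatial sizes: floor halving until <= 4, then collapse to 1x1
  enc_sizes <- grid_size
  while (enc_sizes[length(enc_sizes)] > 4L)
    enc_sizes <- c(enc_sizes, enc_sizes[length(enc_sizes)] %/% 2L)
  n_stages <- length(enc_sizes) - 1L
  enc_channels <- as.integer(base_channels * 2^(seq_len(n_stages) - 1L))
  bottleneck <- 2L * enc_channels[n_stages]

  if (grid_size == 100L) {
    # reference decoder schedule: sizes 1 -> 3 -> 7 -> 13 -> 25 -> 51 -> 100
    dec_sizes <- c(1L, 3L, 7L, 13L, 25L, 51L, 100L)
    dec_steps <- list(c(3L, 1L, 0L), c(3L, 2L, 0L), c(3L, 2L, 1L),
                      c(3L, 2L, 1L), c(3L, 2L, 0L), c(4L, 2L, 2L))
  } else {
    # mirror the encoder size sequence back up
    up <- rev(enc_sizes)
    dec_sizes <- c(1L, up)
    dec_steps <- list(c(up[1L], 1L, 0L))  # 1 -> e_m via valid transpose conv
    if (n_stages >= 1L) {
      for (i in seq_len(n_stages)) {
        s <- up[i]; t <- up[i + 1L]
        if (t == 2L * s) dec_steps <- c(dec_steps, list(c(4L, 2L, 1L)))
        else if (t == 2L * s + 1L) dec_steps <- c(dec_steps, list(c(3L, 2L, 0L)))
        else stop("decoder cannot mirror encoder size step ", s, " -> ", t)
      }
    }
  }
  dec_channels <- c(rev(enc_channels), 1L)

  structure(list(
    grid_size = grid_size, p1 = p1, p2 = p2,
    dropout = as.numeric(dropout), leaky_slope = leaky_slope,
    nn1_channels = c(4L, 8L, 16L, 8L, 4L, 1L),
    nn2_encoder_sizes = enc_sizes,
    nn2_encoder_channels = enc_channels,
    nn2_bottleneck = bottleneck,
    nn2_decoder_sizes = dec_sizes,
    nn2_decoder_steps = dec_steps,
    nn2_decoder_channels = dec_channels
  ), class = "surrogate_spec")
}

#' @export
print.surrogate_spec <- function(x, ...) {
  cat(sprintf("<surrogate_spec> grid %d, p1 = %g, p2 = %g, dropout = (%s)\n",
              x$grid_size, x$p1, x$p2, paste(x$dropout, collapse = ", ")))
  cat("  NN1 channels:", paste(c(1L, x$nn1_channels), collapse = "-"), "\n")
  cat("  NN2 encoder sizes:", paste(x$nn2_encoder_sizes, collapse = "-"),
      " channels:", paste(c(1L, x$nn2_encoder_channels), collapse = "-"),
      " bottleneck:", x$nn2_bottleneck, "\n")
  cat("  NN2 decoder sizes:", paste(x$nn2_decoder_sizes, collapse = "-"), "\n")
  invisible(x)
}

#' Build the size-preserving deep CNN branch (NN 1)
#'
#' @param spec a [surrogate_spec()].
#' @return A list of layers (internal network representation).
#' @export
build_nn1 <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  ch <- c(1L, spec$nn1_channels)
  d1 <- spec$dropout[1L]; d2 <- spec$dropout[2L]
  layers <- list()
  for (i in 1:5) {
    layers <- c(layers, list(layer_conv(ch[i], ch[i + 1L])))
    layers <- c(layers, list(layer_act("lrelu", spec$leaky_slope)))
    if (i == 1L && d1 > 0) layers <- c(layers, list(layer_dropout(d1)))
    layers <- c(layers, list(layer_bn(ch[i + 1L])))
  }
  # final stage: conv -> (dropout) -> batchnorm -> ReLU (output stays >= 0)
  layers <- c(layers, list(layer_conv(ch[6L], ch[7L])))
  if (d2 > 0) layers <- c(layers, list(layer_dropout(d2)))
  layers <- c(layers, list(layer_bn(ch[7L]), layer_act("relu")))
  layers
}

#' Build the convolutional autoencoder branch (NN 2)
#'
#' @param spec a [surrogate_spec()].
#' @return A list of layers (internal network representation).
#' @export
build_nn2 <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  enc_ch <- c(1L, spec$nn2_encoder_channels)
  n_stages <- length(spec$nn2_encoder_channels)
  d3 <- spec$dropout[3L]; d4 <- spec$dropout[4L]
  layers <- list()
  for (i in seq_len(n_stages)) {
    layers <- c(layers, list(layer_conv(enc_ch[i], enc_ch[i + 1L]),
                             layer_act("lrelu", spec$leaky_slope)))
    if (i == 1L) {
      layers <- c(layers, list(layer_bn(enc_ch[2L])))
      if (d3 > 0) layers <- c(layers, list(layer_dropout(d3)))
    }
    layers <- c(layers, list(layer_pool()))
  }
  # collapse the last feature map to the 1x1 bottleneck via an unpadded conv
  k_last <- spec$nn2_encoder_sizes[length(spec$nn2_encoder_sizes)]
  layers <- c(layers, list(
    layer_conv(enc_ch[n_stages + 1L], spec$nn2_bottleneck, k = k_last, pad = 0L),
    layer_act("lrelu", spec$leaky_slope)))

  dec_in <- c(spec$nn2_bottleneck, spec$nn2_decoder_channels)
  n_dec <- length(spec$nn2_decoder_steps)
  for (i in seq_len(n_dec)) {
    st <- spec$nn2_decoder_steps[[i]]
    if (i == n_dec) {
      # final stage: (dropout) -> tconv -> batchnorm -> ReLU
      if (d4 > 0) layers <- c(layers, list(layer_dropout(d4)))
      layers <- c(layers, list(
        layer_tconv(dec_in[i], dec_in[i + 1L], st[1L], st[2L], st[3L]),
        layer_bn(dec_in[i + 1L]), layer_act("relu")))
    } else {
      layers <- c(layers, list(
        layer_tconv(dec_in[i], dec_in[i + 1L], st[1L], st[2L], st[3L]),
        layer_act("lrelu", spec$leaky_slope)))
    }
  }
  layers
}

#' Construct a surrogate model
#'
#' Builds the branches selected by the spec's mixing weights (`p1`, `p2`) with
#' freshly initialized parameters (Glorot-uniform convolution weights, zero
#' biases, unit-scale batch norm).
#'
#' @param spec a [surrogate_spec()].
#' @param seed optional integer seed for the initialization draw.
#' @return An object of class `surrogate_model`.
#' @export
build_surrogate <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "surrogate_spec"))
  with_seed(seed, {
    structure(list(
      spec = spec,
      nn1 = if (spec$p1 != 0) build_nn1(spec) else NULL,
      nn2 = if (spec$p2 != 0) build_nn2(spec) else NULL
    ), class = "surrogate_model")
  })
}

# Forward pass through both branches; returns prediction tensor + caches.
model_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  y <- 0
  c1 <- c2 <- NULL
  if (!is.null(model$nn1)) {
    f1 <- net_forward(model$nn1, x, training)
    model$nn1 <- f1$layers
    c1 <- f1$caches
    y <- y + spec$p1 * f1$y
  }
  if (!is.null(model$nn2)) {
    f2 <- net_forward(model$nn2, x, training)
    model$nn2 <- f2$layers
    c2 <- f2$caches
    y <- y + spec$p2 * f2$y
  }
  list(y = y, caches = list(nn1 = c1, nn2 = c2), model = model)
}

# Backward pass; returns flat named gradients ("nn1.lNN.W", ...).
model_backward <- function(model, caches, dy) {
  spec <- model$spec
  grads <- list()
  if (!is.null(model$nn1)) {
    b1 <- net_backward(model$nn1, caches$nn1, spec$p1 * dy)
    g1 <- net_grads_flat(b1$grads)
    names(g1) <- paste0("nn1.", names(g1))
    grads <- c(grads, g1)
  }
  if (!is.null(model$nn2)) {
    b2 <- net_backward(model$nn2, caches$nn2, spec$p2 * dy)
    g2 <- net_grads_flat(b2$grads)
    names(g2) <- paste0("nn2.", names(g2))
    grads <- c(grads, g2)
  }
  grads
}

model_params <- function(model) {
  out <- list()
  if (!is.null(model$nn1)) {
    p <- net_params(model$nn1)
    names(p) <- paste0("nn1.", names(p))
    out <- c(out, p)
  }
  if (!is.null(model$nn2)) {
    p <- net_params(model$nn2)
    names(p) <- paste0("nn2.", names(p))
    out <- c(out, p)
  }
  out
}

model_set_params <- function(model, params) {
  pick <- function(branch) {
    sel <- grepl(paste0("^", branch, "\\."), names(params))
    p <- params[sel]
    names(p) <- sub(paste0("^", branch, "\\."), "", names(p))
    p
  }
  if (!is.null(model$nn1)) model$nn1 <- net_set_params(model$nn1, pick("nn1"))
  if (!is.null(model$nn2)) model$nn2 <- net_set_params(model$nn2, pick("nn2"))
  model
}

#' Number of trainable parameters of a surrogate model
#'
#' @param model a `surrogate_model`.
#' @return Integer count of scalar trainable parameters (convolution weights
#'   and biases, batch-norm scales and shifts) over the active branches.
#' @export
model_parameter_count <- function(model) {
  stopifnot(inherits(model, "surrogate_model"))
  sum(vapply(model_params(model), length, integer(1)))
}

#' Predict the steady-state field with a surrogate
#'
#' Runs the model in inference mode (dropout disabled, batch norm using its
#' running statistics): the output is a deterministic function of the input
#' and the parameters, non-negative because both branches end in a ReLU, and
#' has the same spatial shape as the input.
#'
#' @param object a `surrogate_model`.
#' @param x an `L` x `L` matrix or an `L x L x n` array of source layouts.
#' @param ... unused.
#' @return Prediction with the same shape as `x`.
#' @export
predict.surrogate_model <- function(object, x, ...) {
  L <- object$spec$grid_size
  was_matrix <- is.matrix(x)
  if (was_matrix) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L, dim(x)[1L] == L, dim(x)[2L] == L)
  n <- dim(x)[3L]
  x4 <- x
  dim(x4) <- c(L, L, 1L, n)
  y <- model_forward(object, x4, training = FALSE)$y
  dim(y) <- c(L, L, n)
  if (was_matrix) y <- y[, , 1L]
  y
}

#' Save / load a surrogate model
#'
#' Serializes parameters and spec to `path`, with a YAML sidecar
#' (`<path>.yml`) describing the architecture and training provenance.
#'
#' @param model a `surrogate_model`.
#' @param path checkpoint file path.
#' @param provenance optional named list recorded in the sidecar (seed,
#'   epochs, loss configuration, ...).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "surrogate_model"))
  saveRDS(model, path)
  spec <- model$spec
  side <- list(
    spec = list(grid_size = spec$grid_size, p1 = spec$p1, p2 = spec$p2,
                dropout = spec$dropout, leaky_slope = spec$leaky_slope),
    parameter_count = model_parameter_count(model),
    provenance = provenance
  )
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "surrogate_model")) stop("file does not contain a surrogate_model")
  m
}
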