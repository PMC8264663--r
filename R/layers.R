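# Neural-network layer primitives.
#
# Tensors are numeric arrays in (H, W, C, N) layout. Each layer is a plain
# list with a `type` field plus parameters/buffers. `layer_forward` returns
# the output, a cache for backprop, and the (possibly updated) layer —
# batch-norm updates its running statistics in training mode.
# `layer_backward` returns the input gradient and a named list of parameter
# gradients matching `layer_params`.

glorot_init <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

layer_conv <- function(in_ch, out_ch, k = 3L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", k = as.integer(k), pad = as.integer(pad),
       in_ch = in_ch, out_ch = out_ch,
       W = matrix(glorot_init(k * k * in_ch, k * k * out_ch,
                              c(out_ch, k * k * in_ch)),
                  out_ch, k * k * in_ch),
       b = numeric(out_ch))
}

layer_tconv <- function(in_ch, out_ch, k, stride, pad) {
  list(type = "tconv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), in_ch = in_ch, out_ch = out_ch,
       W = glorot_init(k * k * in_ch, k * k * out_ch,
                       c(out_ch, in_ch, k, k)),
       b = numeric(out_ch))
}

layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", ch = ch, momentum = momentum, eps = eps,
       gamma = rep(1, ch), beta = numeric(ch),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

layer_dropout <- function(rate) list(type = "dropout", rate = rate)

layer_act <- function(fun = c("lrelu", "relu"), slope = 0.01) {
  list(type = "act", fun = match.arg(fun), slope = slope)
}

layer_pool <- function() list(type = "pool")

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      y <- conv2d_fw(x, layer$W, layer$b, layer$k, layer$pad)
      list(y = y, cache = list(x = x), layer = layer)
    },
    tconv = {
      y <- tconv2d_fw(x, layer$W, layer$b, layer$stride, layer$pad)
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      out <- bn_fw(x, layer$gamma, layer$beta, layer$running_mean,
                   layer$running_var, layer$momentum, layer$eps, training)
      if (training) {
        layer$running_mean <- out$running_mean
        layer$running_var <- out$running_var
      }
      list(y = out$y,
           cache = list(x = x, mu = out$mu, inv_sd = out$inv_sd,
                        training = training),
           layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- (stats::runif(length(x)) < keep) / keep
        dim(mask) <- dim(x)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(y = x, cache = list(mask = NULL), layer = layer)
      }
    },
    act = {
      slope <- if (layer$fun == "relu") 0 else layer$slope
      list(y = act_fw(x, slope), cache = list(x = x), layer = layer)
    },
    pool = {
      d <- dim(x)
      Ho <- d[1L] %/% 2L; Wo <- d[2L] %/% 2L
      r1 <- seq(1L, 2L * Ho, by = 2L); r2 <- r1 + 1L
      c1 <- seq(1L, 2L * Wo, by = 2L); c2 <- c1 + 1L
      y <- (x[r1, c1, , , drop = FALSE] + x[r2, c1, , , drop = FALSE] +
            x[r1, c2, , , drop = FALSE] + x[r2, c2, , , drop = FALSE]) / 4
      list(y = y, cache = list(d = d), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      g <- conv2d_bw(cache$x, layer$W, dy, layer$k, layer$pad, need_dx)
      list(dx = g$dx, grads = list(W = g$dW, b = as.numeric(g$db)))
    },
    tconv = {
      g <- tconv2d_bw(cache$x, layer$W, dy, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(W = g$dW, b = as.numeric(g$db)))
    },
    bn = {
      g <- bn_bw(cache$x, dy, layer$gamma, cache$mu, cache$inv_sd,
                 cache$training)
      list(dx = g$dx, grads = list(gamma = as.numeric(g$dgamma),
                                   beta = as.numeric(g$dbeta)))
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    act = {
      slope <- if (layer$fun == "relu") 0 else layer$slope
      list(dx = act_bw(cache$x, dy, slope), grads = NULL)
    },
    pool = {
      d <- cache$d
      Ho <- dim(dy)[1L]; Wo <- dim(dy)[2L]
      r1 <- seq(1L, 2L * Ho, by = 2L); r2 <- r1 + 1L
      c1 <- seq(1L, 2L * Wo, by = 2L); c2 <- c1 + 1L
      dx <- array(0, dim = d)
      q <- dy / 4
      dx[r1, c1, , ] <- q; dx[r2, c1, , ] <- q
      dx[r1, c2, , ] <- q; dx[r2, c2, , ] <- q
      list(dx = dx, grads = NULL)
    },
    stop("unknown layer type: ", layer$type)
  )
}

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- layer_forward(layers[[i]], x, training)
    x <- step$y
    caches[[i]] <- step$cache
    layers[[i]] <- step$layer
  }
  list(y = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    step <- layer_backward(layers[[i]], caches[[i]], dy, need_dx = i > 1L)
    dy <- step$dx
    grads[i] <- list(step$grads)   # keep NULL placeholders (no [[<- deletion)
  }
  list(dx = dy, grads = grads)
}

# Flatten / restore trainable parameters as a named list of arrays.
net_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    nm <- switch(l$type, conv = , tconv = c("W", "b"),
                 bn = c("gamma", "beta"), NULL)
    for (p in nm) out[[sprintf("l%02d.%s", i, p)]] <- l[[p]]
  }
  out
}

net_set_params <- function(layers, params) {
  for (nm in names(params)) {
    i <- as.integer(sub("^l([0-9]+)\\..*$", "\\1", nm))
    p <- sub("^l[0-9]+\\.", "", nm)
    layers[[i]][[p]] <- params[[nm]]
  }
  layers
}

net_grads_flat <- function(grads) {
  out <- list()
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    for (p in names(g)) out[[sprintf("l%02d.%s", i, p)]] <- g[[p]]
  }
  out
}
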