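# ADAM optimizer over a flat named list of parameter arrays.

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  # moments mirror each parameter's exact shape (vector stays vector)
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    v <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] -
      state$lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
  }
  list(params = params, state = state)
}
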