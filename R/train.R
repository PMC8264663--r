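#' Training configuration
#'
#' Fixed-budget minibatch ADAM training of a surrogate with roll-back:
#' stochastic optimization occasionally jumps to an unfavorable branch where
#' the epoch loss stays one or two orders of magnitude above its trend; when
#' the freshly computed epoch loss exceeds `rollback_C` times the mean loss of
#' the previous `rollback_m` epochs, the trainer reverts model parameters,
#' optimizer state and batch-norm buffers to the snapshot from `rollback_s`
#' epochs earlier and tries again with freshly advanced RNG draws. Independent
#' of roll-back, the checkpoint with the lowest recorded epoch loss is
#' retained and returned as the final model.
#'
#' @param epochs training epochs (study value: 800).
#' @param learning_rate ADAM learning rate.
#' @param batch_size minibatch size.
#' @param rollback_C spike threshold multiplier `C` (study value: 5);
#'   `Inf` disables roll-back.
#' @param rollback_m trailing-mean window `m` in epochs (study value: 20);
#'   roll-back is inactive during the first `m` epochs (warm-up).
#' @param rollback_s revert depth `s` in epochs (study value: 5).
#' @param max_rollbacks abort bound on the number of roll-backs.
#' @param seed integer seed; expanded into per-stage substreams (shuffling and
#'   dropout share the training stream).
#' @param loss a [loss_config()].
#' @param select_on checkpoint-selection metric: `"train"` (default; the
#'   per-epoch training loss, the same quantity the roll-back thresholds
#'   monitor) or `"validation"` (the loss on the dataset's test split,
#'   evaluated in inference mode after each epoch).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 800L, learning_rate = 1e-3, batch_size = 32L,
                         rollback_C = 5, rollback_m = 20L, rollback_s = 5L,
                         max_rollbacks = 200L, seed = 1L,
                         loss = loss_config(alpha = 1, w = 100),
                         select_on = c("train", "validation")) {
  stopifnot(epochs >= 1, rollback_m >= 1, rollback_s >= 1, max_rollbacks >= 0,
            batch_size >= 1, learning_rate > 0, inherits(loss, "loss_config"))
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), rollback_C = rollback_C,
                 rollback_m = as.integer(rollback_m),
                 rollback_s = as.integer(rollback_s),
                 max_rollbacks = as.integer(max_rollbacks),
                 seed = as.integer(seed), loss = loss,
                 select_on = match.arg(select_on)),
            class = "train_config")
}

#' Roll-back threshold over a loss history
#'
#' `C` times the mean of the last `min(m, length(history))` epoch losses.
#'
#' @param loss_history numeric vector of per-epoch losses (nonempty).
#' @param C threshold multiplier.
#' @param m trailing window length in epochs.
#' @return The threshold (a scalar).
#' @export
rollback_threshold <- function(loss_history, C, m) {
  if (length(loss_history) == 0L) stop("empty loss history")
  C * mean(utils::tail(loss_history, m))
}

#' Roll-back decision
#'
#' TRUE iff at least `rollback_m` epochs have completed (warm-up) and the
#' candidate epoch loss exceeds [rollback_threshold()] — equivalently, iff the
#' ratio of the candidate to the trailing mean exceeds `C`.
#'
#' @param candidate_loss the freshly computed epoch loss.
#' @param loss_history accepted per-epoch losses so far.
#' @param cfg a [train_config()].
#' @return Logical scalar.
#' @export
should_rollback <- function(candidate_loss, loss_history, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (!is.finite(cfg$rollback_C)) return(FALSE)
  if (length(loss_history) < cfg$rollback_m) return(FALSE)
  candidate_loss > rollback_threshold(loss_history, cfg$rollback_C,
                                      cfg$rollback_m)
}

#' Generic training engine with roll-back and best-checkpoint retention
#'
#' Runs `run_epoch` repeatedly on an opaque payload (model + optimizer state,
#' or anything else), recording per-epoch losses, triggering roll-backs per
#' [should_rollback()], and retaining the payload with the lowest accepted
#' epoch loss. This engine is separated from the real epoch runner so that
#' the roll-back bookkeeping can be exercised with scripted loss sequences.
#'
#' A roll-back restores the payload snapshot from `rollback_s` epochs before
#' the spike (bit-identical) and truncates the accepted history to that epoch;
#' the total number of executed epochs is capped at
#' `epochs + max_rollbacks * rollback_s`.
#'
#' @param payload initial opaque state passed to `run_epoch`.
#' @param run_epoch `function(payload, epoch)` returning
#'   `list(payload = <updated>, loss = <scalar>)`, optionally with a
#'   `select_loss` element (defaults to `loss`) used for best-checkpoint
#'   selection instead of the training loss.
#' @param cfg a [train_config()].
#' @return A list: `payload` (best checkpoint), `best_epoch`, `best_loss`,
#'   `history` (accepted epoch losses), `log` (data frame of every executed
#'   epoch incl. rolled-back attempts), `rollback_count`, `epochs_run`.
#' @export
train_loop <- function(payload, run_epoch, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  history <- numeric(0)
  ring <- list()               # payload snapshots keyed by epoch index
  best <- NULL
  rollbacks <- 0L
  epochs_run <- 0L
  cap <- cfg$epochs + cfg$max_rollbacks * cfg$rollback_s
  log_rows <- list()

  while (length(history) < cfg$epochs) {
    if (epochs_run >= cap) {
      warning("epoch budget cap reached before completing the schedule")
      break
    }
    epoch <- length(history) + 1L
    res <- run_epoch(payload, epoch)
    epochs_run <- epochs_run + 1L
    cand <- res$loss
    if (!is.finite(cand))
      stop(sprintf("non-finite loss (%g) at epoch %d", cand, epoch))
    roll <- should_rollback(cand, history, cfg)
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(epoch = epoch, loss = cand, rolled_back = roll,
                 rollback_count = rollbacks + as.integer(roll))
    if (roll) {
      rollbacks <- rollbacks + 1L
      if (rollbacks > cfg$max_rollbacks)
        stop(sprintf("max_rollbacks (%d) exceeded", cfg$max_rollbacks))
      target <- max(1L, length(history) - cfg$rollback_s)
      payload <- ring[[as.character(target)]]
      if (is.null(payload)) stop("snapshot ring does not hold epoch ", target)
      history <- history[seq_len(target)]
      ring <- ring[as.integer(names(ring)) <= target]
    } else {
      payload <- res$payload
      history <- c(history, cand)
      ring[[as.character(length(history))]] <- payload
      keep <- as.integer(names(ring)) > length(history) - (cfg$rollback_s + 1L)
      ring <- ring[keep]
      sel <- res$select_loss %||% cand
      if (is.null(best) || sel < best$loss)
        best <- list(epoch = length(history), loss = sel, payload = payload)
    }
  }
  list(payload = best$payload, best_epoch = best$epoch, best_loss = best$loss,
       history = history, log = do.call(rbind, log_rows),
       rollback_count = rollbacks, epochs_run = epochs_run)
}

#' Train a surrogate model
#'
#' Minibatch ADAM on the configured weighted loss over the training split,
#' with per-epoch reshuffling, roll-back on loss spikes, and best-checkpoint
#' retention. The epoch loss is the pixel-count-weighted mean of minibatch
#' losses. With a fixed `cfg$seed` and roll-back disabled the run is
#' deterministic.
#'
#' @param model a freshly built (or partially trained) `surrogate_model`.
#' @param dataset a `diff_dataset` whose grid matches the model.
#' @param cfg a [train_config()].
#' @return A list: `model` (best checkpoint), `best_epoch`, `best_loss`,
#'   `history`, `log`, `rollback_count`, `epochs_run`.
#' @export
train_surrogate <- function(model, dataset, cfg) {
  stopifnot(inherits(model, "surrogate_model"),
            inherits(dataset, "diff_dataset"),
            inherits(cfg, "train_config"))
  if (dataset$meta$L != model$spec$grid_size)
    stop("dataset grid size does not match the model")
  if (length(dataset$train_idx) == 0L) stop("empty training split")

  tens <- dataset_tensors(dataset, "train")
  n <- dim(tens$x)[4L]
  L <- dataset$meta$L

  validate <- cfg$select_on == "validation" && length(dataset$test_idx) > 0L
  if (validate) vtens <- dataset_tensors(dataset, "test")

  run_epoch <- function(payload, epoch) {
    model <- payload$model
    opt <- payload$opt
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    tot_loss <- 0
    tot_px <- 0
    for (b in batches) {
      xb <- tens$x[, , , b, drop = FALSE]
      yb <- tens$y[, , , b, drop = FALSE]
      fw <- model_forward(model, xb, training = TRUE)
      model <- fw$model
      l <- weighted_loss(fw$y, yb, cfg$loss)
      dy <- weighted_loss_grad(fw$y, yb, cfg$loss)
      dim(dy) <- dim(yb)
      grads <- model_backward(model, fw$caches, dy)
      st <- adam_step(opt, model_params(model), grads)
      opt <- st$state
      model <- model_set_params(model, st$params)
      tot_loss <- tot_loss + l * length(yb)
      tot_px <- tot_px + length(yb)
    }
    out <- list(payload = list(model = model, opt = opt),
                loss = tot_loss / tot_px)
    if (validate) {
      vp <- model_forward(model, vtens$x, training = FALSE)$y
      out$select_loss <- weighted_loss(vp, vtens$y, cfg$loss)
    }
    out
  }

  set.seed(derive_seed(cfg$seed, "shuffle"))
  payload <- list(model = model,
                  opt = adam_init(model_params(model), lr = cfg$learning_rate))
  out <- train_loop(payload, run_epoch, cfg)
  list(model = out$payload$model, best_epoch = out$best_epoch,
       best_loss = out$best_loss, history = out$history, log = out$log,
       rollback_count = out$rollback_count, epochs_run = out$epochs_run)
}
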