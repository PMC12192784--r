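#' Training configuration
#'
#' Defaults are the published settings: Adam with learning rate 1e-4,
#' beta1 = 0.9, beta2 = 0.999; batch size 64; plateau schedule that
#' multiplies the learning rate by 0.1 after 5 consecutive epochs
#' without validation improvement, floored at 1e-6; at most 200 epochs;
#' L2 weight decay lambda = 0.001.
#'
#' @param batch_size,lr0,beta1,beta2,epsilon,plateau_patience,plateau_factor,min_lr,max_epochs,weight_decay
#'   Optimization constants.
#' @param seed Integer seed controlling shuffling, dropout and
#'   initialization downstream.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64L, lr0 = 1e-4, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-8,
                         plateau_patience = 5L, plateau_factor = 0.1,
                         min_lr = 1e-6, max_epochs = 200L,
                         weight_decay = 0.001, seed = 1L,
                         verbose = FALSE) {
  stopifnot(plateau_factor > 0, plateau_factor < 1, plateau_patience >= 1,
            min_lr < lr0, batch_size >= 1, max_epochs >= 1,
            weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, min_lr = min_lr,
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_config")
}

#' Stratified random split of windows into train/validation/test
#'
#' Default fractions 0.70 / 0.10 / 0.20. `unit = "recording"` (default)
#' assigns whole recordings to one split so no three-cycle window shares
#' cycles across splits; `unit = "window"` splits windows directly
#' (higher fidelity to cycle-level splitting, but adjacent-window
#' leakage is possible).
#'
#' @param meta Tibble with columns `window`, `recording`, `activity`
#'   (as from [build_feature_dataset()]).
#' @param fractions Length-3 numeric summing to 1.
#' @param unit `"recording"` or `"window"`.
#' @param seed Integer seed.
#' @return `meta` with an added factor column `split`
#'   (train/val/test); a seeded, reproducible partition.
#' @export
split_windows <- function(meta, fractions = c(0.70, 0.10, 0.20),
                          unit = c("recording", "window"), seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  meta$split <- NA_character_
  for (act in unique(meta$activity)) {
    rows <- which(meta$activity == act)
    if (unit == "recording") {
      units <- unique(meta$recording[rows])
    } else {
      units <- meta$window[rows]
    }
    n <- length(units)
    if (n < 3) stop("stratum '", act, "' has fewer than 3 ", unit, "s")
    perm <- sample(units)
    n_val <- max(1L, round(fractions[2] * n))
    n_test <- max(1L, round(fractions[3] * n))
    n_train <- n - n_val - n_test
    lab <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    key <- if (unit == "recording") meta$recording[rows] else
      meta$window[rows]
    meta$split[rows] <- lab[match(key, perm)]
  }
  meta$split <- factor(meta$split, levels = c("train", "val", "test"))
  meta
}

#' One Adam update for a single parameter array
#'
#' `m_t = b1*m + (1-b1)*g`; `v_t = b2*v + (1-b2)*g^2`; bias-corrected
#' `m^ = m_t/(1-b1^t)`, `v^ = v_t/(1-b2^t)`;
#' `theta <- theta - lr * m^ / (sqrt(v^) + eps)`. Weight decay, when
#' used by the trainer, is added to `g` beforehand (L2-in-gradient).
#'
#' @param param Numeric array.
#' @param grad Gradient array (same shape).
#' @param state List `(m, v, t)`; pass `NULL` to initialize.
#' @param lr Learning rate.
#' @param beta1,beta2,epsilon Adam constants.
#' @return List with updated `param` and `state`.
#' @export
adam_step <- function(param, grad, state = NULL, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(length(param) == length(grad))
  if (is.null(state)) state <- list(m = param * 0, v = param * 0, t = 0L)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  param <- param - lr * mhat / (sqrt(vhat) + epsilon)
  list(param = param, state = state)
}

#' Plateau learning-rate schedule over a validation-loss history
#'
#' Replays the rule over the whole history: the learning rate is
#' multiplied by `factor` whenever `patience` consecutive epochs pass
#' without a strict improvement of the best validation loss, never
#' dropping below `min_lr`; the stagnation counter resets after each
#' reduction.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param lr0 Initial learning rate.
#' @param patience,factor,min_lr Schedule constants.
#' @return Numeric vector of the learning rate in effect after each
#'   epoch.
#' @export
lr_schedule <- function(val_losses, lr0 = 1e-4, patience = 5L,
                        factor = 0.1, min_lr = 1e-6) {
  if (length(val_losses) == 0) stop("empty history")
  lr <- lr0
  best <- Inf
  bad <- 0L
  out <- numeric(length(val_losses))
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        lr <- max(lr * factor, min_lr)
        bad <- 0L
      }
    }
    out[e] <- lr
  }
  out
}

mse_loss <- function(pred, y) mean((pred - y)^2)

#' Train a torque network with Adam, MSE loss and the plateau schedule
#'
#' Mini-batches are reshuffled each epoch (seeded); the validation loss
#' is computed in inference mode (dropout off, batch-norm running
#' statistics) after every epoch and drives the plateau schedule.
#' Weight decay (L2) is added to the gradients of all weight matrices
#' (not biases or normalization affines). The model's layer
#' environments are updated in place and also returned.
#'
#' @param model A `torque_net` (hybrid or baseline).
#' @param x_train,y_train Arrays `[C x L x N]` and `[J x P x N]`.
#' @param x_val,y_val Validation arrays (optional; without them the
#'   schedule follows the training loss).
#' @param config A [train_config()].
#' @return List: `model`, `history` (tibble: epoch, train_loss,
#'   val_loss, lr, reduced).
#' @export
train_model <- function(model, x_train, y_train, x_val = NULL,
                        y_val = NULL, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  N <- dim(x_train)[3]
  if (N < 1) stop("empty training split")
  cfg <- model$config
  out_dim <- cfg$n_joints * cfg$out_points
  plys <- collect_param_layers(model$layers)
  states <- lapply(plys, function(ly) lapply(ly$params, function(p) NULL))

  set.seed(config$seed)
  lr <- config$lr0
  best <- Inf
  bad <- 0L
  hist <- vector("list", config$max_epochs)

  eval_loss <- function(x, y) {
    pred <- predict_torque_batched(model, x, config$batch_size)
    mse_loss(pred, y)
  }

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(N)
    batch_losses <- numeric(0)
    for (s in seq(1L, N, by = config$batch_size)) {
      idx <- perm[s:min(s + config$batch_size - 1L, N)]
      xb <- x_train[, , idx, drop = FALSE]
      yb <- matrix(y_train[, , idx], out_dim, length(idx))
      pred <- seq_forward(model$layers, xb, training = TRUE)
      loss <- mse_loss(pred, yb)
      if (!is.finite(loss)) {
        stop("training aborted: non-finite loss at epoch ", epoch)
      }
      batch_losses <- c(batch_losses, loss)
      dpred <- 2 * (pred - yb) / length(yb)
      seq_backward(model$layers, dpred)
      for (i in seq_along(plys)) {
        ly <- plys[[i]]
        for (nm in names(ly$params)) {
          g <- ly$grads[[nm]]
          if (config$weight_decay > 0 && startsWith(nm, "W")) {
            g <- g + config$weight_decay * ly$params[[nm]]
          }
          st <- adam_step(ly$params[[nm]], g, states[[i]][[nm]], lr,
                          config$beta1, config$beta2, config$epsilon)
          ly$params[[nm]] <- st$param
          states[[i]][[nm]] <- st$state
        }
      }
    }
    train_loss <- mean(batch_losses)
    val_loss <- if (!is.null(x_val) && dim(x_val)[3] > 0) {
      eval_loss(x_val, y_val)
    } else {
      train_loss
    }
    reduced <- FALSE
    if (val_loss < best) {
      best <- val_loss
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$plateau_patience) {
        new_lr <- max(lr * config$plateau_factor, config$min_lr)
        reduced <- new_lr < lr
        lr <- new_lr
        bad <- 0L
      }
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = train_loss,
                                    val_loss = val_loss, lr = lr,
                                    reduced = reduced)
    if (config$verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, train_loss, val_loss, lr))
    }
  }
  for (ly in model$layers) ly$reset()
  list(model = model, history = dplyr::bind_rows(hist))
}
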