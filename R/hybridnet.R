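#' Hybrid torque-estimation network configuration
#'
#' Architecture: 1-D convolutional stem (32 then 64 filters, kernel 3,
#' batch norm + ReLU + 2x max-pooling after each conv), two residual
#' blocks (32 and 64 filters, dropout 0.3 after each), 4-head
#' local-window self-attention (window 15) with residual + layer norm,
#' 64-unit bidirectional LSTM, and a fully connected head
#' (1024 -> 512 -> n_joints x 101) with ReLU and dropout 0.3.
#'
#' @param in_channels Input channel count (`k*m` for the
#'   `"channels_time"` layout, 1 for the literal `"flat"` layout).
#' @param in_length Input sequence length (`n = 303` for
#'   `"channels_time"`, `k*m*n` for `"flat"`).
#' @param input_layout `"flat"` (the literal one-dimensional expansion
#'   of the scalogram stack; default for fidelity) or `"channels_time"`
#'   (`k*m` channels over `n` time points; much shorter sequences).
#' @param stem_filters,kernel,pool,res_filters,dropout_rate,attn_heads,attn_window,lstm_hidden,fc_sizes
#'   Architecture constants (defaults are the published configuration).
#' @param n_joints Number of output joints.
#' @param out_points Phase points per joint trajectory.
#' @param variant Ablation variant: `"full"`, `"no_cwt"` (expects raw
#'   standardized windows as input), `"no_resnet"`, `"no_mhsa"`,
#'   `"lstm_only"` (unidirectional LSTM), `"no_bilstm"` (no recurrent
#'   layer; temporal mean pooling feeds the head).
#' @return A `model_config` list.
#' @export
model_config <- function(in_channels, in_length,
                         input_layout = c("flat", "channels_time"),
                         stem_filters = c(32L, 64L), kernel = 3L,
                         pool = 2L, res_filters = c(32L, 64L),
                         dropout_rate = 0.3, attn_heads = 4L,
                         attn_window = 15L, lstm_hidden = 64L,
                         fc_sizes = c(1024L, 512L), n_joints = 3L,
                         out_points = 101L,
                         variant = c("full", "no_cwt", "no_resnet",
                                     "no_mhsa", "lstm_only",
                                     "no_bilstm")) {
  input_layout <- match.arg(input_layout)
  variant <- match.arg(variant)
  stopifnot(attn_window %% 2 == 1, dropout_rate >= 0, dropout_rate < 1,
            in_channels >= 1, in_length >= kernel)
  structure(
    list(in_channels = as.integer(in_channels),
         in_length = as.integer(in_length), input_layout = input_layout,
         stem_filters = as.integer(stem_filters), kernel = as.integer(kernel),
         pool = as.integer(pool), res_filters = as.integer(res_filters),
         dropout_rate = dropout_rate, attn_heads = as.integer(attn_heads),
         attn_window = as.integer(attn_window),
         lstm_hidden = as.integer(lstm_hidden),
         fc_sizes = as.integer(fc_sizes), n_joints = as.integer(n_joints),
         out_points = as.integer(out_points), variant = variant),
    class = "model_config"
  )
}

#' Build the hybrid torque-estimation network
#'
#' Weight initialization: He-uniform for convolutional and fully
#' connected weights, orthogonal for recurrent kernels; call
#' `set.seed()` first for reproducible builds.
#'
#' @param config A [model_config()].
#' @return A `torque_net` object.
#' @export
build_hybrid <- function(config) {
  stopifnot(inherits(config, "model_config"))
  v <- config$variant
  layers <- list()
  add <- function(ly) layers[[length(layers) + 1L]] <<- ly

  # conv stem
  add(layer_conv1d(config$in_channels, config$stem_filters[1],
                   config$kernel))
  add(layer_batchnorm(config$stem_filters[1]))
  add(layer_relu())
  add(layer_maxpool1d(config$pool))
  add(layer_conv1d(config$stem_filters[1], config$stem_filters[2],
                   config$kernel))
  add(layer_batchnorm(config$stem_filters[2]))
  add(layer_relu())
  add(layer_maxpool1d(config$pool))
  d <- config$stem_filters[2]

  if (v != "no_resnet") {
    add(layer_resblock(d, config$res_filters[1], config$dropout_rate))
    add(layer_resblock(config$res_filters[1], config$res_filters[2],
                       config$dropout_rate))
    d <- config$res_filters[2]
  }

  if (v != "no_mhsa") {
    add(layer_mhsa_local(d, config$attn_heads, config$attn_window))
  }

  H <- config$lstm_hidden
  head_in <- if (v == "no_bilstm") {
    add(layer_meanpool_time())
    d
  } else if (v == "lstm_only") {
    add(layer_lstm_summary(d, H))
    2L * H
  } else {
    add(layer_bilstm(d, H, output = "summary"))
    4L * H
  }

  add(layer_dense(head_in, config$fc_sizes[1]))
  add(layer_relu())
  add(layer_dropout(config$dropout_rate))
  add(layer_dense(config$fc_sizes[1], config$fc_sizes[2]))
  add(layer_relu())
  add(layer_dropout(config$dropout_rate))
  add(layer_dense(config$fc_sizes[2], config$n_joints * config$out_points,
                  init = "output"))

  structure(list(layers = layers, config = config), class = "torque_net")
}

#' Temporal mean-pooling layer `[D x T x B] -> [D x B]`
#' @keywords internal
layer_meanpool_time <- function() {
  ly <- new_layer("meanpool_time")
  ly$fwd <- function(x, training = FALSE) {
    ly$in_dim <- dim(x)
    apply(x, c(1, 3), mean)
  }
  ly$bwd <- function(dy) {
    d <- ly$in_dim
    dx <- array(0, dim = d)
    for (t in seq_len(d[2])) dx[, t, ] <- dy / d[2]
    dx
  }
  ly
}

#' Unidirectional LSTM with the mean-pool + last-state summary interface
#' @keywords internal
layer_lstm_summary <- function(in_dim, hidden) {
  ly <- new_layer("bilstm")  # reuses the bilstm walker for parameters
  ly$H <- as.integer(hidden)
  ly$fw <- layer_lstm(in_dim, hidden, output = "seq")
  ly$bw <- NULL
  ly$params <- list()
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x); ly$in_dim <- d
    s <- ly$fw$fwd(x, training)
    mean_pool <- apply(s, c(1, 3), mean)
    rbind(mean_pool, ly$fw$h_last)
  }
  ly$bwd <- function(dy) {
    d <- ly$in_dim; T <- d[2]; B <- d[3]; H <- ly$H
    dmean <- dy[1:H, , drop = FALSE] / T
    dlast <- dy[(H + 1):(2 * H), , drop = FALSE]
    dseq <- array(0, dim = c(H, T, B))
    for (t in seq_len(T)) dseq[, t, ] <- dmean
    dseq[, T, ] <- dseq[, T, ] + dlast
    ly$fw$bwd(dseq)
  }
  ly$reset <- function() ly$fw$reset()
  ly
}

# collect_param_layers treats type "bilstm" via fw/bw; tolerate bw = NULL
# (handled in collect_param_layers through add(NULL) no-op).

#' Forward pass of a torque network
#'
#' @param model A `torque_net`.
#' @param x Input array `[C x L x B]` (a single `[C x L]` matrix is
#'   treated as batch size 1).
#' @param training Training mode (dropout active, batch statistics).
#' @return Array `[n_joints x out_points x B]`.
#' @export
predict_torque <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  cfg <- model$config
  if (dim(x)[1] != cfg$in_channels) {
    stop("input has ", dim(x)[1], " channels; model expects ",
         cfg$in_channels)
  }
  out <- seq_forward(model$layers, x, training)
  array(out, dim = c(cfg$n_joints, cfg$out_points, ncol(out)))
}

#' Batched inference for large window sets
#' @param model A `torque_net`.
#' @param x Array `[C x L x N]`.
#' @param batch_size Batch size.
#' @return Array `[n_joints x out_points x N]`.
#' @export
predict_torque_batched <- function(model, x, batch_size = 64L) {
  N <- dim(x)[3]
  cfg <- model$config
  out <- array(0, dim = c(cfg$n_joints, cfg$out_points, N))
  for (s in seq(1L, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, N)
    out[, , idx] <- predict_torque(model, x[, , idx, drop = FALSE])
  }
  out
}

#' Save a model checkpoint (weights + JSON architecture manifest)
#' @param model A `torque_net`.
#' @param path Checkpoint path (`.rds`); a `.json` manifest is written
#'   alongside.
#' @export
save_checkpoint <- function(model, path) {
  plys <- collect_param_layers(model$layers)
  state <- lapply(plys, function(ly) ly$params)
  bn <- lapply(plys, function(ly) {
    if (identical(ly$type, "batchnorm")) {
      list(mean = ly$running_mean, var = ly$running_var)
    } else NULL
  })
  saveRDS(list(config = model$config, state = state, bn = bn), path)
  jsonlite::write_json(
    c(unclass(model$config), list(n_parameters = n_parameters(model))),
    paste0(sub("\\.rds$", "", path), "_manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#' @param path Checkpoint path.
#' @return A `torque_net` with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_hybrid(ck$config)
  plys <- collect_param_layers(model$layers)
  stopifnot(length(plys) == length(ck$state))
  for (i in seq_along(plys)) {
    plys[[i]]$params <- ck$state[[i]]
    if (!is.null(ck$bn[[i]])) {
      plys[[i]]$running_mean <- ck$bn[[i]]$mean
      plys[[i]]$running_var <- ck$bn[[i]]$var
    }
  }
  model
}

#' @export
print.torque_net <- function(x, ...) {
  cat("<torque_net> variant '", x$config$variant, "', ",
      x$config$in_channels, "x", x$config$in_length, " input, ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}
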