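# Comparison architectures sharing the layer kit, training loop and
# prediction contract of the hybrid model. Input is the same featurized
# window array [C x L x B]; every model ends in a linear output layer of
# n_joints x 101 values.

#' Reshape `[C x L x B]` into a 1-channel image `[1 x C x L x B]`
#' @keywords internal
layer_to_image <- function() {
  ly <- new_layer("to_image")
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    ly$in_dim <- d
    array(x, dim = c(1L, d[1], d[2], d[3]))
  }
  ly$bwd <- function(dy) array(dy, dim = ly$in_dim)
  ly
}

#' 2-D convolution layer (3x3, same padding), input `[C x H x W x B]`
#' @keywords internal
layer_conv2d <- function(in_ch, out_ch, kernel = 3L) {
  stopifnot(kernel %% 2 == 1)
  ly <- new_layer("conv2d")
  ly$in_ch <- in_ch; ly$out_ch <- out_ch; ly$kernel <- as.integer(kernel)
  ly$pad <- (kernel - 1L) %/% 2L
  K2 <- kernel * kernel
  ly$params$W <- he_uniform(out_ch, in_ch * K2, fan_in = in_ch * K2)
  ly$params$b <- numeric(out_ch)
  ly$grads$W <- ly$params$W * 0
  ly$grads$b <- numeric(out_ch)

  im2col2 <- function(x) {
    d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
    p <- ly$pad; K <- ly$kernel
    xp <- array(0, dim = c(C, H + 2 * p, W + 2 * p, B))
    xp[, (p + 1):(p + H), (p + 1):(p + W), ] <- x
    Xc <- matrix(0, C * K * K, H * W * B)
    r <- 0L
    for (kw in seq_len(K)) for (kh in seq_len(K)) {
      sl <- xp[, kh:(kh + H - 1L), kw:(kw + W - 1L), , drop = FALSE]
      dim(sl) <- c(C, H * W * B)
      Xc[(r * C + 1):((r + 1) * C), ] <- sl
      r <- r + 1L
    }
    Xc
  }

  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    ly$in_dim <- d
    Xc <- im2col2(x)
    ly$Xc <- Xc
    Y <- ly$params$W %*% Xc + ly$params$b
    array(Y, dim = c(ly$out_ch, d[2], d[3], d[4]))
  }
  ly$bwd <- function(dy) {
    d <- ly$in_dim; C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
    dY <- matrix(dy, ly$out_ch, H * W * B)
    ly$grads$b <- rowSums(dY)
    ly$grads$W <- dY %*% t(ly$Xc)
    dXc <- crossprod(ly$params$W, dY)
    p <- ly$pad; K <- ly$kernel
    dxp <- array(0, dim = c(C, H + 2 * p, W + 2 * p, B))
    r <- 0L
    for (kw in seq_len(K)) for (kh in seq_len(K)) {
      block <- array(dXc[(r * C + 1):((r + 1) * C), ], dim = c(C, H, W, B))
      old <- dxp[, kh:(kh + H - 1L), kw:(kw + W - 1L), , drop = FALSE]
      dxp[, kh:(kh + H - 1L), kw:(kw + W - 1L), ] <- old + block
      r <- r + 1L
    }
    ly$Xc <- NULL
    dxp[, (p + 1):(p + H), (p + 1):(p + W), , drop = FALSE]
  }
  ly$reset <- function() ly$Xc <- NULL
  ly
}

#' 2x2 max pooling for `[C x H x W x B]`
#' @keywords internal
layer_maxpool2d <- function() {
  ly <- new_layer("maxpool2d")
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
    ly$in_dim <- d; ly$H2 <- H2; ly$W2 <- W2
    ih <- seq(1L, by = 2L, length.out = H2)
    iw <- seq(1L, by = 2L, length.out = W2)
    cand <- list(x[, ih, iw, , drop = FALSE], x[, ih + 1L, iw, , drop = FALSE],
                 x[, ih, iw + 1L, , drop = FALSE],
                 x[, ih + 1L, iw + 1L, , drop = FALSE])
    y <- cand[[1]]; which_max <- array(1L, dim = dim(y))
    for (k in 2:4) {
      upd <- cand[[k]] > y
      y[upd] <- cand[[k]][upd]
      which_max[upd] <- k
    }
    ly$which_max <- which_max
    y
  }
  ly$bwd <- function(dy) {
    d <- ly$in_dim
    dx <- array(0, dim = d)
    ih <- seq(1L, by = 2L, length.out = ly$H2)
    iw <- seq(1L, by = 2L, length.out = ly$W2)
    offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (k in 1:4) {
      sel <- ly$which_max == k
      blk <- array(0, dim = dim(dy))
      blk[sel] <- dy[sel]
      dx[, ih + offs[[k]][1], iw + offs[[k]][2], ] <-
        dx[, ih + offs[[k]][1], iw + offs[[k]][2], ] + blk
    }
    ly$which_max <- NULL
    dx
  }
  ly$reset <- function() ly$which_max <- NULL
  ly
}

#' Flatten `[C x H x W x B] -> [CHW x B]`
#' @keywords internal
layer_flatten2d <- function() {
  ly <- new_layer("flatten2d")
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    ly$in_dim <- d
    matrix(x, prod(d[1:3]), d[4])
  }
  ly$bwd <- function(dy) array(dy, dim = ly$in_dim)
  ly
}

#' Recognized baseline architecture names
#' @export
BASELINE_NAMES <- c("ANN", "CNN1D", "Conv2D", "GRU", "LSTM", "TCN",
                    "TimeTransformer", "TCN_LSTM")

#' Build a baseline comparison model
#'
#' Published layer configurations:
#' \describe{
#'   \item{ANN}{two FC layers of 128 and 64 neurons, ReLU, linear out.}
#'   \item{CNN1D}{conv (16 filters, size 3), 2x max-pool, two FC layers
#'     (128, 64), linear out.}
#'   \item{Conv2D}{input reshaped to a 2-D map; conv layers with 32 and
#'     64 filters, 2x2 pooling after each, FC 128, linear out.}
#'   \item{GRU}{GRU 64 (sequences) -> GRU 32 -> FC 128 -> linear out.}
#'   \item{LSTM}{LSTM 64 (sequences) -> dropout 0.2 -> LSTM 32 ->
#'     FC 128 -> linear out.}
#'   \item{TCN}{dilated convolutions, 32 filters, kernel 3, dilation
#'     rates 1, 2, 4; FC 128; linear out.}
#'   \item{TimeTransformer}{4-head self-attention, batch norm,
#'     LSTM 64/32, FC 128, linear out.}
#'   \item{TCN_LSTM}{TCN stack (32 filters, k3, dilations 1/2/4) ->
#'     LSTM 64/32 -> FC 128 -> linear out.}
#' }
#' Pooling sizes and FC activations not printed in the source
#' description default to 2x max-pooling and ReLU. Convolutional
#' baselines reduce time by global average pooling before the FC head.
#'
#' @param name One of [BASELINE_NAMES] (case-insensitive).
#' @param in_channels,in_length Input dimensions.
#' @param n_joints,out_points Output dimensions.
#' @return A `torque_net`.
#' @export
build_baseline <- function(name, in_channels, in_length, n_joints = 3L,
                           out_points = 101L) {
  key <- BASELINE_NAMES[match(tolower(name), tolower(BASELINE_NAMES))]
  if (is.na(key)) stop("unknown baseline model: ", name)
  out_dim <- n_joints * out_points
  C <- as.integer(in_channels); L <- as.integer(in_length)
  layers <- switch(key,
    ANN = list(
      layer_flatten_any(),
      layer_dense(C * L, 128L), layer_relu(),
      layer_dense(128L, 64L), layer_relu(),
      layer_dense(64L, out_dim, init = "output")
    ),
    CNN1D = list(
      layer_conv1d(C, 16L), layer_relu(), layer_maxpool1d(2L),
      layer_meanpool_time(),
      layer_dense(16L, 128L), layer_relu(),
      layer_dense(128L, 64L), layer_relu(),
      layer_dense(64L, out_dim, init = "output")
    ),
    Conv2D = list(
      layer_to_image(),
      layer_conv2d(1L, 32L), layer_relu(), layer_maxpool2d(),
      layer_conv2d(32L, 64L), layer_relu(), layer_maxpool2d(),
      layer_meanpool_image(),
      layer_dense(64L, 128L), layer_relu(),
      layer_dense(128L, out_dim, init = "output")
    ),
    GRU = list(
      layer_gru(C, 64L, output = "seq"),
      layer_gru(64L, 32L, output = "last"),
      layer_dense(32L, 128L), layer_relu(),
      layer_dense(128L, out_dim, init = "output")
    ),
    LSTM = list(
      layer_lstm(C, 64L, output = "seq"),
      layer_dropout(0.2),
      layer_lstm(64L, 32L, output = "last"),
      layer_dense(32L, 128L), layer_relu(),
      layer_dense(128L, out_dim, init = "output")
    ),
    TCN = list(
      layer_conv1d(C, 32L, dilation = 1L), layer_relu(),
      layer_conv1d(32L, 32L, dilation = 2L), layer_relu(),
      layer_conv1d(32L, 32L, dilation = 4L), layer_relu(),
      layer_meanpool_time(),
      layer_dense(32L, 128L), layer_relu(),
      layer_dense(128L, out_dim, init = "output")
    ),
    TimeTransformer = {
      heads <- 4L
      d_attn <- C
      if (d_attn %% heads != 0) {
        stop("TimeTransformer needs in_channels divisible by 4, got ", C)
      }
      list(
        layer_mhsa_local(d_attn, heads, window = 2L * L + 1L),
        layer_batchnorm(d_attn),
        layer_lstm(d_attn, 64L, output = "seq"),
        layer_lstm(64L, 32L, output = "last"),
        layer_dense(32L, 128L), layer_relu(),
        layer_dense(128L, out_dim, init = "output")
      )
    },
    TCN_LSTM = list(
      layer_conv1d(C, 32L, dilation = 1L), layer_relu(),
      layer_conv1d(32L, 32L, dilation = 2L), layer_relu(),
      layer_conv1d(32L, 32L, dilation = 4L), layer_relu(),
      layer_lstm(32L, 64L, output = "seq"),
      layer_lstm(64L, 32L, output = "last"),
      layer_dense(32L, 128L), layer_relu(),
      layer_dense(128L, out_dim, init = "output")
    )
  )
  cfg <- structure(
    list(in_channels = C, in_length = L, n_joints = as.integer(n_joints),
         out_points = as.integer(out_points), variant = key,
         input_layout = "channels_time"),
    class = "model_config"
  )
  structure(list(layers = layers, config = cfg, baseline = key),
            class = "torque_net")
}

#' Flatten `[C x L x B] -> [CL x B]` (any conv-path input)
#' @keywords internal
layer_flatten_any <- function() layer_flatten()

#' Global average pooling for images `[C x H x W x B] -> [C x B]`
#' @keywords internal
layer_meanpool_image <- function() {
  ly <- new_layer("meanpool_image")
  ly$fwd <- function(x, training = FALSE) {
    ly$in_dim <- dim(x)
    apply(x, c(1, 4), mean)
  }
  ly$bwd <- function(dy) {
    d <- ly$in_dim
    dx <- array(0, dim = d)
    per <- dy / (d[2] * d[3])
    for (h in seq_len(d[2])) for (w in seq_len(d[3])) dx[, h, w, ] <- per
    dx
  }
  ly
}
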