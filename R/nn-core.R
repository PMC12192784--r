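# Minimal array-based neural-network kit with manual backpropagation.
#
# Layout conventions:
#   conv / sequence path : array [features x time x batch]
#   dense path           : matrix [features x batch]
# Each layer is an environment with fields `params`, `grads`, closures
# `fwd(x, training)` and `bwd(dy)`, and a `reset()` that drops caches.
# All randomness (init, dropout) draws from R's RNG so callers control
# determinism with set.seed().

new_layer <- function(type) {
  env <- new.env(parent = emptyenv())
  env$type <- type
  env$params <- list()
  env$grads <- list()
  env$reset <- function() NULL
  env
}

he_uniform <- function(nrow, ncol, fan_in = ncol) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

orthogonal_init <- function(nrow, ncol) {
  a <- matrix(stats::rnorm(max(nrow, ncol)^2), max(nrow, ncol))
  q <- qr.Q(qr(a))
  q[seq_len(nrow), seq_len(ncol), drop = FALSE]
}

# ---- conv1d ---------------------------------------------------------------

#' 1-D convolution layer (same padding, odd kernel, optional dilation)
#'
#' Input `[C_in x L x B]`, output `[C_out x L x B]`. Implemented as
#' im2col + GEMM with exact gradient accumulation.
#'
#' @param in_ch,out_ch Channel counts.
#' @param kernel Odd kernel length.
#' @param dilation Dilation rate.
#' @return Layer environment.
#' @keywords internal
layer_conv1d <- function(in_ch, out_ch, kernel = 3L, dilation = 1L) {
  stopifnot(kernel %% 2 == 1)
  ly <- new_layer("conv1d")
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$kernel <- as.integer(kernel); ly$dilation <- as.integer(dilation)
  ly$pad <- dilation * (kernel - 1L) %/% 2L
  ly$params$W <- he_uniform(out_ch, in_ch * kernel, fan_in = in_ch * kernel)
  ly$params$b <- numeric(out_ch)
  ly$grads$W <- ly$params$W * 0
  ly$grads$b <- numeric(out_ch)

  im2col <- function(x) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    p <- ly$pad
    xp <- array(0, dim = c(C, L + 2 * p, B))
    xp[, (p + 1):(p + L), ] <- x
    K <- ly$kernel
    Xc <- matrix(0, C * K, L * B)
    for (k in seq_len(K)) {
      off <- (k - 1L) * ly$dilation
      sl <- xp[, (1 + off):(L + off), , drop = FALSE]
      dim(sl) <- c(C, L * B)
      Xc[((k - 1) * C + 1):(k * C), ] <- sl
    }
    Xc
  }

  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[1] != ly$in_ch) stop("conv1d: expected ", ly$in_ch, " channels")
    if (d[2] < 1) stop("conv1d: empty input")
    ly$in_dim <- d
    Xc <- im2col(x)
    ly$Xc <- Xc
    Y <- ly$params$W %*% Xc + ly$params$b
    array(Y, dim = c(ly$out_ch, d[2], d[3]))
  }

  ly$bwd <- function(dy) {
    d <- ly$in_dim; C <- d[1]; L <- d[2]; B <- d[3]
    dY <- matrix(dy, ly$out_ch, L * B)
    ly$grads$b <- rowSums(dY)
    ly$grads$W <- dY %*% t(ly$Xc)
    dXc <- crossprod(ly$params$W, dY)   # [C*K, L*B]
    p <- ly$pad; K <- ly$kernel
    dxp <- array(0, dim = c(C, L + 2 * p, B))
    for (k in seq_len(K)) {
      off <- (k - 1L) * ly$dilation
      block <- array(dXc[((k - 1) * C + 1):(k * C), ], dim = c(C, L, B))
      dxp[, (1 + off):(L + off), ] <- dxp[, (1 + off):(L + off), ] + block
    }
    ly$Xc <- NULL
    dxp[, (p + 1):(p + L), , drop = FALSE]
  }
  ly$reset <- function() ly$Xc <- NULL
  ly
}

# ---- batch normalization --------------------------------------------------

#' Batch normalization over the feature axis
#'
#' Normalizes each feature (channel) over all remaining axes of the
#' batch: `xhat = (x - mu_B)/sqrt(sigma_B^2 + eps)`, `y = gamma*xhat +
#' beta`. Inference uses running statistics.
#' @keywords internal
layer_batchnorm <- function(n_feat, eps = 1e-5, momentum = 0.1) {
  ly <- new_layer("batchnorm")
  ly$eps <- eps; ly$momentum <- momentum
  ly$params$gamma <- rep(1, n_feat)
  ly$params$beta <- rep(0, n_feat)
  ly$grads$gamma <- rep(0, n_feat)
  ly$grads$beta <- rep(0, n_feat)
  ly$running_mean <- rep(0, n_feat)
  ly$running_var <- rep(1, n_feat)

  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x) %||% c(length(x), 1L)
    ly$in_dim <- d
    ly$training_mode <- training
    xm <- matrix(x, d[1])   # [feat, rest]
    if (training) {
      mu <- rowMeans(xm)
      v <- rowMeans((xm - mu)^2)
      ly$running_mean <- (1 - ly$momentum) * ly$running_mean +
        ly$momentum * mu
      ly$running_var <- (1 - ly$momentum) * ly$running_var +
        ly$momentum * v
    } else {
      mu <- ly$running_mean
      v <- ly$running_var
    }
    sd <- sqrt(v + ly$eps)
    xhat <- (xm - mu) / sd
    ly$xhat <- xhat; ly$sd <- sd
    y <- ly$params$gamma * xhat + ly$params$beta
    array(y, dim = d)
  }

  ly$bwd <- function(dy) {
    d <- ly$in_dim
    dym <- matrix(dy, d[1])
    N <- ncol(dym)
    ly$grads$gamma <- rowSums(dym * ly$xhat)
    ly$grads$beta <- rowSums(dym)
    dxhat <- dym * ly$params$gamma
    dx <- if (isTRUE(ly$training_mode)) {
      (dxhat - rowMeans(dxhat) -
         ly$xhat * rowMeans(dxhat * ly$xhat)) / ly$sd
    } else {
      dxhat / ly$sd   # running statistics are constants at inference
    }
    ly$xhat <- NULL
    array(dx, dim = d)
  }
  ly$reset <- function() ly$xhat <- NULL
  ly
}

# ---- simple elementwise / structural layers -------------------------------

layer_relu <- function() {
  ly <- new_layer("relu")
  ly$fwd <- function(x, training = FALSE) {
    ly$mask <- x > 0
    x * ly$mask
  }
  ly$bwd <- function(dy) { g <- dy * ly$mask; ly$mask <- NULL; g }
  ly$reset <- function() ly$mask <- NULL
  ly
}

layer_maxpool1d <- function(pool = 2L) {
  ly <- new_layer("maxpool1d")
  ly$pool <- as.integer(pool)
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x); L2 <- d[2] %/% ly$pool
    ly$in_dim <- d; ly$L2 <- L2
    i1 <- seq(1L, by = ly$pool, length.out = L2)
    x1 <- x[, i1, , drop = FALSE]
    x2 <- x[, i1 + 1L, , drop = FALSE]
    ly$first_wins <- x1 >= x2
    ifelse(ly$first_wins, x1, x2)
  }
  ly$bwd <- function(dy) {
    d <- ly$in_dim
    dx <- array(0, dim = d)
    i1 <- seq(1L, by = ly$pool, length.out = ly$L2)
    dx[, i1, ] <- dy * ly$first_wins
    dx[, i1 + 1L, ] <- dy * !ly$first_wins
    ly$first_wins <- NULL
    dx
  }
  ly$reset <- function() ly$first_wins <- NULL
  ly
}

#' Dropout layer with inverted scaling
#'
#' Training: `h' = h * m / p_keep` with Bernoulli(p_keep) masks so that
#' `E[h'] = h`; inference is the exact identity.
#' @keywords internal
layer_dropout <- function(rate = 0.3) {
  stopifnot(rate >= 0, rate < 1)
  ly <- new_layer("dropout")
  ly$rate <- rate
  ly$fwd <- function(x, training = FALSE) {
    if (!training || ly$rate == 0) return(x)
    keep <- 1 - ly$rate
    ly$mask <- array(stats::rbinom(length(x), 1, keep) / keep,
                     dim = dim(x) %||% length(x))
    x * ly$mask
  }
  ly$bwd <- function(dy) {
    if (is.null(ly$mask)) return(dy)
    g <- dy * ly$mask
    ly$mask <- NULL
    g
  }
  ly$reset <- function() ly$mask <- NULL
  ly
}

layer_flatten <- function() {
  ly <- new_layer("flatten")
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    ly$in_dim <- d
    matrix(x, d[1] * d[2], d[3])
  }
  ly$bwd <- function(dy) array(dy, dim = ly$in_dim)
  ly
}

# init "output": Glorot scaled by 0.1 so a regression head starts near
# zero prediction instead of random variance that must be unlearned.
layer_dense <- function(in_dim, out_dim, init = c("he", "glorot",
                                                  "output")) {
  init <- match.arg(init)
  ly <- new_layer("dense")
  lim <- sqrt(6 / (in_dim + out_dim))
  ly$params$W <- switch(init,
    he = he_uniform(out_dim, in_dim, fan_in = in_dim),
    glorot = matrix(stats::runif(out_dim * in_dim, -lim, lim),
                    out_dim, in_dim),
    output = 0.1 * matrix(stats::runif(out_dim * in_dim, -lim, lim),
                          out_dim, in_dim)
  )
  ly$params$b <- numeric(out_dim)
  ly$grads$W <- ly$params$W * 0
  ly$grads$b <- numeric(out_dim)
  ly$fwd <- function(x, training = FALSE) {
    x <- as.matrix(x)
    ly$x <- x
    ly$params$W %*% x + ly$params$b
  }
  ly$bwd <- function(dy) {
    dy <- as.matrix(dy)
    ly$grads$W <- dy %*% t(ly$x)
    ly$grads$b <- rowSums(dy)
    g <- crossprod(ly$params$W, dy)
    ly$x <- NULL
    g
  }
  ly$reset <- function() ly$x <- NULL
  ly
}

# ---- layer normalization --------------------------------------------------

layer_layernorm <- function(d_model, eps = 1e-5) {
  ly <- new_layer("layernorm")
  ly$eps <- eps
  ly$params$gamma <- rep(1, d_model)
  ly$params$beta <- rep(0, d_model)
  ly$grads$gamma <- rep(0, d_model)
  ly$grads$beta <- rep(0, d_model)
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    ly$in_dim <- d
    xm <- matrix(x, d[1])
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    sd <- sqrt(colMeans(xc^2) + ly$eps)
    xhat <- sweep(xc, 2, sd, "/")
    ly$xhat <- xhat; ly$sd <- sd
    array(ly$params$gamma * xhat + ly$params$beta, dim = d)
  }
  ly$bwd <- function(dy) {
    d <- ly$in_dim
    dym <- matrix(dy, d[1])
    ly$grads$gamma <- rowSums(dym * ly$xhat)
    ly$grads$beta <- rowSums(dym)
    dxhat <- dym * ly$params$gamma
    dx <- sweep(dxhat, 2, colMeans(dxhat)) -
      ly$xhat * matrix(colMeans(dxhat * ly$xhat), nrow = d[1],
                       ncol = ncol(dym), byrow = TRUE)
    dx <- sweep(dx, 2, ly$sd, "/")
    ly$xhat <- NULL
    array(dx, dim = d)
  }
  ly$reset <- function() ly$xhat <- NULL
  ly
}

# ---- local-window multi-head self-attention -------------------------------

#' Local-window multi-head self-attention block
#'
#' Scaled dot-product attention per head with scores restricted to the
#' symmetric band `|i - j| <= (w-1)/2`; softmax over the unmasked band
#' (re-normalized at sequence edges), heads concatenated and projected by
#' `W^O`. The block is wrapped with a residual connection and layer
#' normalization: `y = LN(x + MHSA(x))`.
#'
#' @param d_model Feature dimension (divisible by `heads`).
#' @param heads Number of attention heads.
#' @param window Odd local-window width (15: each query attends to
#'   itself and 7 neighbors on each side).
#' @param wrap `"residual_ln"` (default) or `"none"` (bare attention,
#'   used by oracle tests).
#' @keywords internal
layer_mhsa_local <- function(d_model, heads = 4L, window = 15L,
                             wrap = c("residual_ln", "none")) {
  wrap <- match.arg(wrap)
  stopifnot(window %% 2 == 1, d_model %% heads == 0)
  ly <- new_layer("mhsa_local")
  ly$d <- d_model; ly$h <- as.integer(heads)
  ly$dk <- d_model %/% heads
  ly$hw <- (as.integer(window) - 1L) %/% 2L
  ly$wrap <- wrap
  lim <- sqrt(6 / (2 * d_model))
  rn <- function() matrix(stats::runif(d_model * d_model, -lim, lim),
                          d_model, d_model)
  ly$params$Wq <- rn(); ly$params$Wk <- rn()
  ly$params$Wv <- rn(); ly$params$Wo <- rn()
  for (nm in c("Wq", "Wk", "Wv", "Wo")) ly$grads[[nm]] <- ly$params[[nm]] * 0
  if (wrap == "residual_ln") ly$ln <- layer_layernorm(d_model)

  band_mask <- function(T) {
    idx <- seq_len(T)
    abs(outer(idx, idx, "-")) <= ly$hw
  }

  # Projections for all (t, b) positions are batched into single GEMMs;
  # only the T x T attention products run per sample and head.
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x); T <- d[2]; B <- d[3]
    stopifnot(d[1] == ly$d)
    ly$in_dim <- d
    mask <- band_mask(T)
    Xm <- matrix(x, d[1], T * B)          # cols: t fastest, then b
    ly$Xm <- Xm
    Qm <- crossprod(ly$params$Wq, Xm)
    Km <- crossprod(ly$params$Wk, Xm)
    Vm <- crossprod(ly$params$Wv, Xm)
    ly$Qm <- Qm; ly$Km <- Km; ly$Vm <- Vm
    ly$P <- vector("list", B)
    Om <- matrix(0, ly$d, T * B)
    for (b in seq_len(B)) {
      cols <- ((b - 1L) * T + 1L):(b * T)
      Q <- t(Qm[, cols, drop = FALSE])    # [T, d]
      K <- t(Km[, cols, drop = FALSE])
      V <- t(Vm[, cols, drop = FALSE])
      Pb <- vector("list", ly$h)
      O <- matrix(0, T, ly$d)
      for (h in seq_len(ly$h)) {
        hc <- ((h - 1) * ly$dk + 1):(h * ly$dk)
        S <- tcrossprod(Q[, hc, drop = FALSE],
                        K[, hc, drop = FALSE]) / sqrt(ly$dk)
        S[!mask] <- -Inf
        S <- S - apply(S, 1, max)
        P <- exp(S)
        P <- P / rowSums(P)
        Pb[[h]] <- P
        O[, hc] <- P %*% V[, hc, drop = FALSE]
      }
      ly$P[[b]] <- Pb
      Om[, cols] <- t(O)
    }
    ly$Om <- Om
    out <- array(crossprod(ly$params$Wo, Om), dim = d)
    if (ly$wrap == "residual_ln") {
      ly$ln$fwd(x + out, training)
    } else {
      out
    }
  }

  ly$bwd <- function(dy) {
    d <- ly$in_dim; T <- d[2]; B <- d[3]
    if (ly$wrap == "residual_ln") dy <- ly$ln$bwd(dy)
    mask <- band_mask(T)
    dym <- matrix(dy, d[1], T * B)
    ly$grads$Wo <- tcrossprod(ly$Om, dym)
    dOm <- ly$params$Wo %*% dym
    dQm <- matrix(0, ly$d, T * B)
    dKm <- dQm; dVm <- dQm
    for (b in seq_len(B)) {
      cols <- ((b - 1L) * T + 1L):(b * T)
      dO <- t(dOm[, cols, drop = FALSE])  # [T, d]
      Q <- t(ly$Qm[, cols, drop = FALSE])
      K <- t(ly$Km[, cols, drop = FALSE])
      V <- t(ly$Vm[, cols, drop = FALSE])
      dQ <- matrix(0, T, ly$d); dK <- dQ; dV <- dQ
      for (h in seq_len(ly$h)) {
        hc <- ((h - 1) * ly$dk + 1):(h * ly$dk)
        P <- ly$P[[b]][[h]]
        dOh <- dO[, hc, drop = FALSE]
        dP <- tcrossprod(dOh, V[, hc, drop = FALSE])
        dV[, hc] <- crossprod(P, dOh)
        dS <- P * (dP - rowSums(dP * P))
        dS[!mask] <- 0
        dQ[, hc] <- dS %*% K[, hc, drop = FALSE] / sqrt(ly$dk)
        dK[, hc] <- crossprod(dS, Q[, hc, drop = FALSE]) / sqrt(ly$dk)
      }
      dQm[, cols] <- t(dQ); dKm[, cols] <- t(dK); dVm[, cols] <- t(dV)
    }
    ly$grads$Wq <- tcrossprod(ly$Xm, dQm)
    ly$grads$Wk <- tcrossprod(ly$Xm, dKm)
    ly$grads$Wv <- tcrossprod(ly$Xm, dVm)
    dXm <- ly$params$Wq %*% dQm + ly$params$Wk %*% dKm +
      ly$params$Wv %*% dVm
    dx <- array(dXm, dim = d)
    if (ly$wrap == "residual_ln") dx <- dx + dy
    ly$reset()
    dx
  }
  ly$reset <- function() {
    ly$Xm <- NULL; ly$Qm <- NULL; ly$Km <- NULL; ly$Vm <- NULL
    ly$P <- NULL; ly$Om <- NULL
    if (!is.null(ly$ln)) ly$ln$reset()
  }
  ly
}

# ---- LSTM / GRU -----------------------------------------------------------

#' Single-direction LSTM layer
#'
#' Gates: input `i`, forget `f`, candidate `g` (tanh, range `[-1, 1]`),
#' output `o`; sigmoids in `[0, 1]`. `output` selects the returned value:
#' the full sequence `[H x T x B]`, the last hidden state `[H x B]`, or
#' (for the bidirectional wrapper) sequence plus final state.
#' @keywords internal
layer_lstm <- function(in_dim, hidden, reverse = FALSE,
                       output = c("seq", "last")) {
  output <- match.arg(output)
  ly <- new_layer("lstm")
  ly$H <- as.integer(hidden); ly$D <- as.integer(in_dim)
  ly$reverse <- reverse; ly$output <- output
  H <- ly$H
  ly$params$Wx <- he_uniform(4 * H, in_dim, fan_in = in_dim)
  ly$params$Wh <- do.call(rbind, lapply(1:4, function(i)
    orthogonal_init(H, H)))
  ly$params$b <- c(rep(0, H), rep(1, H), rep(0, 2 * H))  # forget bias 1
  for (nm in names(ly$params)) ly$grads[[nm]] <- ly$params[[nm]] * 0

  sig <- function(z) 1 / (1 + exp(-z))

  # The input projection Wx %*% x + b for all steps is batched into one
  # GEMM; only the recurrent part runs in the per-step loop. Caches are
  # preallocated arrays [H, B, T] in processing order.
  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x); T <- d[2]; B <- d[3]
    if (T < 1) stop("lstm: empty sequence")
    ly$in_dim <- d
    H <- ly$H
    order_t <- if (ly$reverse) rev(seq_len(T)) else seq_len(T)
    xp <- aperm(x, c(1, 3, 2))            # [D, B, T]
    Xm <- matrix(xp, d[1], B * T)         # cols: b fastest, then t
    ly$Xm <- Xm
    Zx <- ly$params$Wx %*% Xm + ly$params$b
    h <- matrix(0, H, B); cc <- matrix(0, H, B)
    ca <- list(i = array(0, c(H, B, T)), f = array(0, c(H, B, T)),
               g = array(0, c(H, B, T)), o = array(0, c(H, B, T)),
               c_prev = array(0, c(H, B, T)), tc = array(0, c(H, B, T)),
               h_prev = array(0, c(H, B, T)))
    hseq <- array(0, dim = c(H, B, T))    # in processing order
    for (step in seq_len(T)) {
      t <- order_t[step]
      colr <- ((t - 1L) * B + 1L):(t * B)
      z <- Zx[, colr, drop = FALSE] + ly$params$Wh %*% h
      i <- sig(z[1:H, , drop = FALSE])
      f <- sig(z[(H + 1):(2 * H), , drop = FALSE])
      g <- tanh(z[(2 * H + 1):(3 * H), , drop = FALSE])
      o <- sig(z[(3 * H + 1):(4 * H), , drop = FALSE])
      ca$i[, , step] <- i; ca$f[, , step] <- f
      ca$g[, , step] <- g; ca$o[, , step] <- o
      ca$c_prev[, , step] <- cc
      ca$h_prev[, , step] <- h
      cc <- f * cc + i * g
      tc <- tanh(cc)
      ca$tc[, , step] <- tc
      h <- o * tc
      hseq[, , step] <- h
    }
    ly$ca <- ca
    ly$order_t <- order_t
    ly$h_last <- h
    if (ly$output == "last") return(h)
    out <- array(0, dim = c(H, T, B))
    for (step in seq_len(T)) out[, order_t[step], ] <- hseq[, , step]
    out
  }

  ly$bwd <- function(dy) {
    d <- ly$in_dim; T <- d[2]; B <- d[3]; H <- ly$H
    ca <- ly$ca
    order_t <- ly$order_t
    dWh <- ly$params$Wh * 0
    dZ <- matrix(0, 4 * H, B * T)   # cols aligned with Xm (b, then t)
    dh_next <- matrix(0, H, B)
    dc_next <- matrix(0, H, B)
    for (step in rev(seq_len(T))) {
      t <- order_t[step]
      dh <- dh_next
      if (ly$output == "seq") {
        dh <- dh + matrix(dy[, t, ], H, B)
      } else if (step == T) {
        dh <- dh + as.matrix(dy)
      }
      i <- ca$i[, , step]; f <- ca$f[, , step]
      g <- ca$g[, , step]; o <- ca$o[, , step]
      tc <- ca$tc[, , step]
      do_ <- dh * tc
      dcc <- dc_next + dh * o * (1 - tc^2)
      dz <- rbind(dcc * g * i * (1 - i),
                  dcc * ca$c_prev[, , step] * f * (1 - f),
                  dcc * i * (1 - g^2),
                  do_ * o * (1 - o))
      dc_next <- dcc * f
      dWh <- dWh + tcrossprod(dz, ca$h_prev[, , step])
      dZ[, ((t - 1L) * B + 1L):(t * B)] <- dz
      dh_next <- crossprod(ly$params$Wh, dz)
    }
    ly$grads$Wx <- tcrossprod(dZ, ly$Xm)
    ly$grads$Wh <- dWh
    ly$grads$b <- rowSums(dZ)
    dxp <- crossprod(ly$params$Wx, dZ)    # [D, B*T]
    dx <- aperm(array(dxp, dim = c(d[1], B, T)), c(1, 3, 2))
    ly$ca <- NULL; ly$Xm <- NULL
    dx
  }
  ly$reset <- function() { ly$ca <- NULL; ly$Xm <- NULL }
  ly
}

#' Bidirectional LSTM layer
#'
#' Forward and backward recurrences; per-step outputs concatenated to
#' `[2H x T x B]`. `output = "summary"` returns the head interface used
#' by the hybrid model: the time-mean of the output sequence
#' concatenated with the two final states (`[4H x B]`).
#' @keywords internal
layer_bilstm <- function(in_dim, hidden = 64L,
                         output = c("seq", "summary")) {
  output <- match.arg(output)
  ly <- new_layer("bilstm")
  ly$H <- as.integer(hidden); ly$output <- output
  ly$fw <- layer_lstm(in_dim, hidden, reverse = FALSE, output = "seq")
  ly$bw <- layer_lstm(in_dim, hidden, reverse = TRUE, output = "seq")
  ly$params <- list()  # parameters live in the sub-layers

  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x); T <- d[2]; B <- d[3]; H <- ly$H
    ly$in_dim <- d
    sf <- ly$fw$fwd(x, training)
    sb <- ly$bw$fwd(x, training)
    seq_out <- array(0, dim = c(2 * H, T, B))
    seq_out[1:H, , ] <- sf
    seq_out[(H + 1):(2 * H), , ] <- sb
    if (ly$output == "seq") return(seq_out)
    ly$T <- T
    mean_pool <- apply(seq_out, c(1, 3), mean)         # [2H, B]
    rbind(mean_pool, ly$fw$h_last, ly$bw$h_last)       # [4H, B]
  }

  ly$bwd <- function(dy) {
    d <- ly$in_dim; T <- d[2]; B <- d[3]; H <- ly$H
    if (ly$output == "seq") {
      dseq <- dy
      dlast_f <- matrix(0, H, B); dlast_b <- matrix(0, H, B)
    } else {
      dmean <- dy[1:(2 * H), , drop = FALSE] / T
      dlast_f <- dy[(2 * H + 1):(3 * H), , drop = FALSE]
      dlast_b <- dy[(3 * H + 1):(4 * H), , drop = FALSE]
      dseq <- array(0, dim = c(2 * H, T, B))
      for (t in seq_len(T)) dseq[, t, ] <- dmean
    }
    dsf <- dseq[1:H, , , drop = FALSE]
    dsb <- dseq[(H + 1):(2 * H), , , drop = FALSE]
    dim(dsf) <- c(H, T, B); dim(dsb) <- c(H, T, B)
    # final states: forward's last step is t = T; backward's is t = 1
    dsf[, T, ] <- dsf[, T, ] + dlast_f
    dsb[, 1, ] <- dsb[, 1, ] + dlast_b
    ly$fw$bwd(dsf) + ly$bw$bwd(dsb)
  }
  ly$reset <- function() { ly$fw$reset(); ly$bw$reset() }
  ly
}

#' Single-direction GRU layer (update/reset gates, tanh candidate)
#' @keywords internal
layer_gru <- function(in_dim, hidden, output = c("seq", "last")) {
  output <- match.arg(output)
  ly <- new_layer("gru")
  ly$H <- as.integer(hidden); ly$output <- output
  H <- ly$H
  ly$params$Wx <- he_uniform(3 * H, in_dim, fan_in = in_dim)
  ly$params$Wh <- do.call(rbind, lapply(1:3, function(i)
    orthogonal_init(H, H)))
  ly$params$b <- numeric(3 * H)
  for (nm in names(ly$params)) ly$grads[[nm]] <- ly$params[[nm]] * 0
  sig <- function(z) 1 / (1 + exp(-z))

  ly$fwd <- function(x, training = FALSE) {
    d <- dim(x); T <- d[2]; B <- d[3]; H <- ly$H
    ly$in_dim <- d
    h <- matrix(0, H, B)
    ly$cache <- vector("list", T)
    seq_out <- array(0, dim = c(H, T, B))
    for (t in seq_len(T)) {
      xt <- matrix(x[, t, ], d[1], B)
      zx <- ly$params$Wx %*% xt + ly$params$b
      zh <- ly$params$Wh %*% h
      z <- sig(zx[1:H, , drop = FALSE] + zh[1:H, , drop = FALSE])
      r <- sig(zx[(H + 1):(2 * H), , drop = FALSE] +
                 zh[(H + 1):(2 * H), , drop = FALSE])
      hn_h <- zh[(2 * H + 1):(3 * H), , drop = FALSE]
      n <- tanh(zx[(2 * H + 1):(3 * H), , drop = FALSE] + r * hn_h)
      h_prev <- h
      h <- (1 - z) * n + z * h_prev
      ly$cache[[t]] <- list(xt = xt, z = z, r = r, n = n, hn_h = hn_h,
                            h_prev = h_prev)
      seq_out[, t, ] <- h
    }
    ly$h_last <- h
    if (ly$output == "last") h else seq_out
  }

  ly$bwd <- function(dy) {
    d <- ly$in_dim; T <- d[2]; B <- d[3]; H <- ly$H
    for (nm in names(ly$grads)) ly$grads[[nm]][] <- 0
    dx <- array(0, dim = d)
    dh_next <- matrix(0, H, B)
    for (t in rev(seq_len(T))) {
      cc <- ly$cache[[t]]
      dh <- dh_next
      if (ly$output == "seq") dh <- dh + matrix(dy[, t, ], H, B)
      else if (t == T) dh <- dh + as.matrix(dy)
      dz <- dh * (cc$h_prev - cc$n)
      dn <- dh * (1 - cc$z)
      dh_prev <- dh * cc$z
      dzn <- dn * (1 - cc$n^2)          # pre-tanh candidate gradient
      dr <- dzn * cc$hn_h
      dzz <- dz * cc$z * (1 - cc$z)
      dzr <- dr * cc$r * (1 - cc$r)
      dzx <- rbind(dzz, dzr, dzn)
      dzh <- rbind(dzz, dzr, dzn * cc$r)
      ly$grads$Wx <- ly$grads$Wx + dzx %*% t(cc$xt)
      ly$grads$Wh <- ly$grads$Wh + dzh %*% t(cc$h_prev)
      ly$grads$b <- ly$grads$b + rowSums(dzx)
      dx[, t, ] <- dx[, t, ] + crossprod(ly$params$Wx, dzx)
      dh_next <- dh_prev + crossprod(ly$params$Wh, dzh)
    }
    ly$cache <- NULL
    dx
  }
  ly$reset <- function() ly$cache <- NULL
  ly
}

# ---- residual block -------------------------------------------------------

#' 1-D convolutional residual block
#'
#' `y = ReLU(F(x) + shortcut(x))` with
#' `F = conv(k3) -> BN -> ReLU -> conv(k3) -> BN`; the shortcut is the
#' identity when channel counts match and a 1x1 convolution projection
#' otherwise. A dropout layer (rate 0.3) follows the block.
#' @keywords internal
layer_resblock <- function(in_ch, filters, dropout_rate = 0.3) {
  ly <- new_layer("resblock")
  ly$conv1 <- layer_conv1d(in_ch, filters)
  ly$bn1 <- layer_batchnorm(filters)
  ly$relu1 <- layer_relu()
  ly$conv2 <- layer_conv1d(filters, filters)
  ly$bn2 <- layer_batchnorm(filters)
  ly$proj <- if (in_ch != filters) layer_conv1d(in_ch, filters, kernel = 1L)
             else NULL
  ly$relu_out <- layer_relu()
  ly$drop <- layer_dropout(dropout_rate)
  ly$sub <- Filter(Negate(is.null),
                   list(ly$conv1, ly$bn1, ly$conv2, ly$bn2, ly$proj))

  ly$fwd <- function(x, training = FALSE) {
    f <- ly$bn2$fwd(ly$conv2$fwd(
      ly$relu1$fwd(ly$bn1$fwd(ly$conv1$fwd(x, training), training),
                   training), training), training)
    s <- if (is.null(ly$proj)) x else ly$proj$fwd(x, training)
    ly$drop$fwd(ly$relu_out$fwd(f + s, training), training)
  }
  ly$bwd <- function(dy) {
    dsum <- ly$relu_out$bwd(ly$drop$bwd(dy))
    dxs <- if (is.null(ly$proj)) dsum else ly$proj$bwd(dsum)
    dxf <- ly$conv1$bwd(ly$bn1$bwd(ly$relu1$bwd(
      ly$conv2$bwd(ly$bn2$bwd(dsum)))))
    dxf + dxs
  }
  ly$reset <- function() {
    for (s in ly$sub) s$reset()
    ly$relu1$reset(); ly$relu_out$reset(); ly$drop$reset()
  }
  ly
}

# ---- model container ------------------------------------------------------

#' Collect all parameter-bearing layer environments of a model
#' @keywords internal
collect_param_layers <- function(layers) {
  out <- list()
  add <- function(ly) {
    if (is.null(ly)) return()
    if (identical(ly$type, "resblock")) {
      for (s in ly$sub) add(s)
    } else if (identical(ly$type, "bilstm")) {
      add(ly$fw); add(ly$bw)
    } else if (identical(ly$type, "mhsa_local")) {
      out[[length(out) + 1L]] <<- ly
      if (!is.null(ly$ln)) add(ly$ln)
    } else if (length(ly$params) > 0) {
      out[[length(out) + 1L]] <<- ly
    }
  }
  for (ly in layers) add(ly)
  out
}

#' Forward pass through a sequential layer list
#' @keywords internal
seq_forward <- function(layers, x, training = FALSE) {
  for (ly in layers) x <- ly$fwd(x, training)
  x
}

#' Backward pass through a sequential layer list
#' @keywords internal
seq_backward <- function(layers, dy) {
  for (ly in rev(layers)) dy <- ly$bwd(dy)
  dy
}

#' Number of trainable parameters of a model
#' @param model A `torque_net`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(collect_param_layers(model$layers),
             function(ly) sum(vapply(ly$params, length, 0L)), 0))
}
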