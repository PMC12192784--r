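#' Morlet wavelet specification
#'
#' @param omega0 Center-frequency parameter of the Morlet wavelet
#'   (dimensionless; default 7, the value at which estimation accuracy
#'   peaks across RMSE/R^2/PCC).
#' @param n_scales Number of scales `m` on the grid.
#' @param freq_range Frequency band in Hz covered by the scale grid
#'   (default 0.5-5 Hz, the dominant band of gait kinematics).
#' @param sampling_rate Sampling rate in Hz of the analyzed window (for
#'   101-point normalized cycles this is `101 / cycle_duration`).
#' @param representation `"magnitude"` (default scalogram input) or
#'   `"real"` (signed coefficient maps).
#' @return A `wavelet_spec` list.
#' @export
wavelet_spec <- function(omega0 = 7, n_scales = 32L,
                         freq_range = c(0.5, 5), sampling_rate = 101 / 1.1,
                         representation = c("magnitude", "real")) {
  representation <- match.arg(representation)
  stopifnot(omega0 > 0, n_scales >= 2,
            freq_range[1] > 0, freq_range[2] > freq_range[1],
            freq_range[2] < sampling_rate / 2)
  structure(list(omega0 = omega0, n_scales = as.integer(n_scales),
                 freq_range = freq_range, sampling_rate = sampling_rate,
                 representation = representation),
            class = "wavelet_spec")
}

#' Morlet mother wavelet
#'
#' `psi(t) = pi^(-1/4) * exp(-t^2/2) * exp(i * omega0 * t)`.
#'
#' @param t Numeric vector (dimensionless wavelet time).
#' @param omega0 Center-frequency parameter.
#' @return Complex vector.
#' @export
morlet <- function(t, omega0 = 7) {
  pi^(-1 / 4) * exp(-t^2 / 2) * exp(1i * omega0 * t)
}

#' Scale grid for the Morlet CWT
#'
#' `m` scales log-spaced so the Morlet center-frequency relation
#' `f = omega0 / (2 * pi * a)` (scale `a` in seconds) maps them onto
#' `[f_min, f_max]`; returned in increasing-frequency (decreasing-scale)
#' order, with the mapped frequencies as attribute `"frequencies"`.
#'
#' @param spec A [wavelet_spec()].
#' @return Numeric vector of scales (seconds).
#' @export
scale_grid <- function(spec) {
  stopifnot(inherits(spec, "wavelet_spec"))
  freqs <- exp(seq(log(spec$freq_range[1]), log(spec$freq_range[2]),
                   length.out = spec$n_scales))
  scales <- spec$omega0 / (2 * pi * freqs)
  attr(scales, "frequencies") <- freqs
  scales
}

#' Continuous wavelet transform of one signal (Morlet)
#'
#' Discretization of `W(a,b) = a^(-1/2) * integral x(t) psi*((t-b)/a) dt`
#' on the sample grid, zero padding at the edges, computed by FFT
#' convolution. The conjugate (analytic) kernel is used.
#'
#' @param signal Finite numeric vector, length `n >= 1`.
#' @param spec A [wavelet_spec()].
#' @param scales Optional precomputed scale grid.
#' @return Complex matrix `[m x n]` (rows in increasing-frequency order).
#' @export
cwt_morlet <- function(signal, spec = wavelet_spec(), scales = NULL) {
  n <- length(signal)
  if (n == 0) stop("empty signal")
  if (!all(is.finite(signal))) stop("signal must be finite")
  if (is.null(scales)) scales <- scale_grid(spec)
  dt <- 1 / spec$sampling_rate
  m <- length(scales)
  # kernel half-width: Gaussian envelope support of 5 wavelet widths
  Jmax <- max(vapply(scales, function(a) ceiling(5 * a / dt), 0))
  nfft <- stats::nextn(n + 2 * Jmax + 1, 2)
  xpad <- complex(real = c(signal, rep(0, nfft - n)))
  X <- stats::fft(xpad)
  W <- matrix(0i, m, n)
  for (s in seq_len(m)) {
    a <- scales[s]
    J <- ceiling(5 * a / dt)
    u <- (-J:J) * dt
    # cross-correlation taps c_j = psi*((u_j)/a) * dt / sqrt(a)
    cj <- Conj(morlet(u / a, spec$omega0)) * dt / sqrt(a)
    # place c~_j = c_{-j} in wrap-around order for circular convolution
    kw <- complex(length.out = nfft)
    kw[1] <- cj[J + 1]
    kw[1 + seq_len(J)] <- cj[J + 1 - seq_len(J)]       # c_{-j}
    kw[nfft + 1 - seq_len(J)] <- cj[J + 1 + seq_len(J)] # c_{+j}
    y <- stats::fft(X * stats::fft(kw), inverse = TRUE) / nfft
    W[s, ] <- y[seq_len(n)]
  }
  W
}

#' Sliding three-cycle feature windows
#'
#' Windows of 3 consecutive 101-point cycles (303 samples), stride 1
#' cycle; the center cycle is the supervision target. Windows never span
#' recording boundaries (call per recording).
#'
#' @param cycles A `gait_cycles` object (see [preprocess_recording()]).
#' @param stride_cycles Stride in cycles.
#' @return List of `feature_window` objects: `x` `[n_channels x 303]`,
#'   `center_cycle`, `activity`. Fewer than 3 cycles gives an empty list.
#' @export
build_windows <- function(cycles, stride_cycles = 1L) {
  stopifnot(inherits(cycles, "gait_cycles"))
  nc <- dim(cycles$data)[1]
  if (nc < 3) return(list())
  starts <- seq(1L, nc - 2L, by = as.integer(stride_cycles))
  lapply(starts, function(s) {
    x <- cbind(cycles$data[s, , ], cycles$data[s + 1L, , ],
               cycles$data[s + 2L, , ])
    rownames(x) <- cycles$channel_labels
    structure(list(x = x, center_cycle = s + 1L,
                   activity = cycles$activity),
              class = "feature_window")
  })
}

#' Scalogram stack for one feature window
#'
#' Applies the Morlet CWT to each of the window's `k` channels
#' (8 per IMU), yielding a `[k x m x n]` array of coefficient magnitudes
#' (or real parts, per the `representation` field of `spec`).
#'
#' @param window A `feature_window`.
#' @param spec A [wavelet_spec()].
#' @return A `scalogram_stack`: array `[k x m x n]` with attributes
#'   `scale_values` and `representation`.
#' @export
scalogram_stack <- function(window, spec = wavelet_spec()) {
  stopifnot(inherits(window, "feature_window"))
  scales <- scale_grid(spec)
  k <- nrow(window$x); n <- ncol(window$x); m <- length(scales)
  out <- array(0, dim = c(k, m, n))
  for (c in seq_len(k)) {
    W <- cwt_morlet(window$x[c, ], spec, scales)
    out[c, , ] <- if (spec$representation == "magnitude") Mod(W) else Re(W)
  }
  attr(out, "scale_values") <- scales
  attr(out, "representation") <- spec$representation
  class(out) <- "scalogram_stack"
  out
}

#' Flatten a stack to the network's one-dimensional input vector
#'
#' Row-major flatten in (channel, scale, time) order: the element at
#' zero-based `(c, s, t)` lands at flat index `c*m*n + s*n + t`. The
#' operation is lossless; [unflatten_stack()] restores the array exactly.
#'
#' @param stack Array `[k x m x n]`.
#' @return Numeric vector of length `k*m*n` with attribute `"dims"`.
#' @export
flatten_stack <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  v <- as.vector(aperm(unclass(stack), c(3, 2, 1)))
  attr(v, "dims") <- d
  v
}

#' Inverse of [flatten_stack()]
#' @param v Flat vector with `"dims"` attribute (or explicit `dims`).
#' @param dims Integer vector `c(k, m, n)`.
#' @return Array `[k x m x n]`.
#' @export
unflatten_stack <- function(v, dims = attr(v, "dims")) {
  stopifnot(length(dims) == 3)
  aperm(array(as.numeric(v), dim = rev(dims)), c(3, 2, 1))
}

#' Short-time Fourier transform comparator features
#'
#' Magnitude STFT (Hann window) per channel, shaped into the same
#' stack/flatten pathway as the scalograms for like-for-like comparison.
#'
#' @param window A `feature_window`.
#' @param frame_len Frame length in samples.
#' @param hop Hop size in samples.
#' @return Array `[k x n_bins x n_frames]` (class `scalogram_stack`).
#' @export
stft_features <- function(window, frame_len = 64L, hop = 16L) {
  stopifnot(inherits(window, "feature_window"))
  n <- ncol(window$x)
  if (frame_len > n) stop("frame longer than window")
  starts <- seq(1L, n - frame_len + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(frame_len) / (frame_len + 1))
  nb <- frame_len %/% 2 + 1L
  k <- nrow(window$x)
  out <- array(0, dim = c(k, nb, length(starts)))
  for (c in seq_len(k)) {
    for (f in seq_along(starts)) {
      seg <- window$x[c, starts[f]:(starts[f] + frame_len - 1L)] * win
      out[c, , f] <- Mod(stats::fft(seg))[seq_len(nb)]
    }
  }
  class(out) <- "scalogram_stack"
  out
}

haar_step <- function(x) {
  n <- length(x)
  ev <- x[seq(2, n, 2)]; od <- x[seq(1, n, 2)]
  list(approx = (od + ev) / sqrt(2), detail = (od - ev) / sqrt(2))
}

haar_inv_step <- function(approx, detail) {
  od <- (approx + detail) / sqrt(2)
  ev <- (approx - detail) / sqrt(2)
  out <- numeric(2 * length(approx))
  out[seq(1, length(out), 2)] <- od
  out[seq(2, length(out), 2)] <- ev
  out
}

#' Multi-level Haar discrete wavelet decomposition
#'
#' Orthogonal Haar filter bank with perfect reconstruction (see
#' [dwt_reconstruct()]). Signals are zero-padded to the next multiple of
#' `2^levels`.
#'
#' @param signal Numeric vector.
#' @param levels Decomposition depth.
#' @return List: `approx` (coarsest), `details` (list, coarse->fine),
#'   `n` (original length).
#' @export
dwt_haar <- function(signal, levels = 3L) {
  n0 <- length(signal)
  block <- 2^levels
  npad <- ceiling(n0 / block) * block
  x <- c(signal, rep(0, npad - n0))
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    st <- haar_step(x)
    details[[levels - l + 1L]] <- st$detail
    x <- st$approx
  }
  list(approx = x, details = details, n = n0)
}

#' Inverse of [dwt_haar()]
#' @param dec Output of [dwt_haar()].
#' @return Reconstructed signal (original length).
#' @export
dwt_reconstruct <- function(dec) {
  x <- dec$approx
  for (d in dec$details) x <- haar_inv_step(x, d)
  x[seq_len(dec$n)]
}

#' Discrete wavelet transform comparator features
#'
#' Haar multi-level decomposition per channel; all coefficients are
#' concatenated (coarse approximation, then details coarse-to-fine) into
#' one row per channel so the result flows through the same
#' stack/flatten pathway.
#'
#' @param window A `feature_window`.
#' @param levels Decomposition depth.
#' @return Array `[k x 1 x n_coeffs]` (class `scalogram_stack`).
#' @export
dwt_features <- function(window, levels = 3L) {
  stopifnot(inherits(window, "feature_window"))
  k <- nrow(window$x)
  rows <- lapply(seq_len(k), function(c) {
    dec <- dwt_haar(window$x[c, ], levels)
    c(dec$approx, unlist(dec$details))
  })
  nc <- length(rows[[1]])
  out <- array(0, dim = c(k, 1L, nc))
  for (c in seq_len(k)) out[c, 1, ] <- rows[[c]]
  class(out) <- "scalogram_stack"
  out
}

#' Assemble a supervised feature dataset from preprocessed recordings
#'
#' For each recording: per-channel standardization (statistics supplied
#' or computed from the given recordings), three-cycle windows, the
#' selected time-frequency featurization, and the network input layout:
#' `"channels_time"` stacks `k*m` rows over `n` time points;
#' `"flat"` is the literal one-dimensional expansion (1 row of length
#' `k*m*n`).
#'
#' @param cycles_list List of `gait_cycles` (one per recording).
#' @param torque_list List of `torque_trace` arrays aligned with
#'   `cycles_list` (cycle indices must match the *kept* cycles; screening
#'   is assumed not to have dropped cycles when torque supervision is
#'   used).
#' @param spec A [wavelet_spec()].
#' @param method `"cwt"`, `"stft"`, `"dwt"`, or `"raw"` (standardized
#'   raw windows, the no-CWT ablation input).
#' @param layout `"channels_time"` or `"flat"`.
#' @param stats Optional list with `mean`, `sd` per channel label (as
#'   from [channel_stats()]); defaults to statistics of `cycles_list`.
#' @return List: `x` array `[C x L x N]`, `y` array `[3 x 101 x N]`,
#'   `meta` tibble (window, recording, center_cycle, activity).
#' @export
build_feature_dataset <- function(cycles_list, torque_list,
                                  spec = wavelet_spec(),
                                  method = c("cwt", "stft", "dwt", "raw"),
                                  layout = c("channels_time", "flat"),
                                  stats = NULL) {
  method <- match.arg(method)
  layout <- match.arg(layout)
  if (is.null(stats)) stats <- channel_stats(cycles_list)

  xs <- list(); ys <- list(); meta <- list()
  w_id <- 0L
  for (r in seq_along(cycles_list)) {
    cyc <- standardize_cycles(cycles_list[[r]], stats)
    wins <- build_windows(cyc)
    torque <- torque_list[[r]]
    for (w in wins) {
      feat <- switch(method,
        cwt = scalogram_stack(w, spec),
        stft = stft_features(w),
        dwt = dwt_features(w),
        raw = {
          x <- array(w$x, dim = c(nrow(w$x), 1L, ncol(w$x)))
          class(x) <- "scalogram_stack"
          x
        }
      )
      d <- dim(feat)
      xmat <- if (layout == "channels_time") {
        matrix(aperm(unclass(feat), c(3, 2, 1)), nrow = d[1] * d[2],
               ncol = d[3], byrow = TRUE)
      } else {
        matrix(flatten_stack(feat), nrow = 1)
      }
      w_id <- w_id + 1L
      xs[[w_id]] <- xmat
      ys[[w_id]] <- torque[w$center_cycle, , ]
      meta[[w_id]] <- tibble::tibble(
        window = w_id, recording = r, center_cycle = w$center_cycle,
        activity = w$activity
      )
    }
  }
  if (w_id == 0L) stop("no windows: need >= 3 cycles per recording")
  C <- nrow(xs[[1]]); L <- ncol(xs[[1]])
  x <- array(unlist(xs), dim = c(C, L, w_id))
  y <- array(unlist(ys), dim = c(3L, 101L, w_id))
  list(x = x, y = y, meta = dplyr::bind_rows(meta))
}

#' Per-row statistics of a featurized dataset
#'
#' Mean and standard deviation of each feature row (channel x scale)
#' over the time points and windows of the given subset — used to
#' standardize network inputs on training-split statistics (wavelet
#' magnitudes grow with scale, so raw rows are poorly conditioned).
#'
#' @param x Feature array `[C x L x N]`.
#' @param idx Window indices to compute statistics over (training
#'   split); default all.
#' @return List with `mean` and `sd` (length C).
#' @export
feature_stats <- function(x, idx = seq_len(dim(x)[3])) {
  xm <- x[, , idx, drop = FALSE]
  dim(xm) <- c(dim(x)[1], length(xm) / dim(x)[1])
  mu <- rowMeans(xm)
  sd <- sqrt(rowMeans((xm - mu)^2))
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mean = mu, sd = sd)
}

#' Apply [feature_stats()] standardization to a feature array
#' @param x Feature array `[C x L x N]`.
#' @param fstats Output of [feature_stats()].
#' @return Standardized array.
#' @export
apply_feature_stats <- function(x, fstats) {
  (x - fstats$mean) / fstats$sd
}

#' Per-channel mean/sd statistics over a set of recordings
#' @param cycles_list List of `gait_cycles`.
#' @return List with `mean` and `sd` named numeric vectors.
#' @export
channel_stats <- function(cycles_list) {
  labels <- cycles_list[[1]]$channel_labels
  acc <- lapply(seq_along(labels), function(j) {
    unlist(lapply(cycles_list, function(cyc) as.vector(cyc$data[, j, ])))
  })
  mu <- vapply(acc, mean, 0)
  sd <- vapply(acc, stats::sd, 0)
  sd[!is.finite(sd) | sd == 0] <- 1
  names(mu) <- names(sd) <- labels
  list(mean = mu, sd = sd)
}

#' Standardize a `gait_cycles` object with given channel statistics
#' @param cycles A `gait_cycles`.
#' @param stats Output of [channel_stats()].
#' @return Standardized `gait_cycles`.
#' @export
standardize_cycles <- function(cycles, stats) {
  out <- cycles
  for (j in seq_along(cycles$channel_labels)) {
    lb <- cycles$channel_labels[j]
    out$data[, j, ] <- (cycles$data[, j, ] - stats$mean[[lb]]) /
      stats$sd[[lb]]
  }
  out
}
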