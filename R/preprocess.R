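#' Sensor filtering specification
#'
#' Accelerometer channels are smoothed with a centered moving-average
#' (mean) filter; gyroscope channels with a zero-phase 6th-order
#' Butterworth low-pass at 3.5 Hz.
#'
#' @param accel_window Moving-average window length in samples (odd).
#' @param butter_order Butterworth filter order.
#' @param butter_cutoff Low-pass cutoff frequency in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(accel_window = 5L, butter_order = 6L,
                        butter_cutoff = 3.5, sampling_rate = 200) {
  stopifnot(accel_window >= 1, accel_window %% 2 == 1,
            butter_order >= 1, butter_cutoff > 0,
            butter_cutoff < sampling_rate / 2)
  structure(list(accel_window = as.integer(accel_window),
                 butter_order = as.integer(butter_order),
                 butter_cutoff = butter_cutoff,
                 sampling_rate = sampling_rate),
            class = "filter_spec")
}

#' Segment a recording into raw gait-cycle slices
#'
#' Cycles run heel strike to next heel strike, half-open
#' `[strike_i, strike_{i+1})` in sample indices.
#'
#' @param rec An `imu_recording` (or plain matrix/data frame of samples).
#' @param events Strictly increasing heel-strike sample indices (1-based).
#' @return List of per-cycle numeric matrices `[len x n_channels]`.
#' @export
segment_cycles <- function(rec, events) {
  if (length(events) < 2) stop("need at least 2 heel-strike events")
  if (any(diff(events) <= 0)) stop("events must be strictly increasing")
  labels <- attr(rec, "channel_labels")
  x <- if (!is.null(labels)) as.matrix(rec[, labels, drop = FALSE]) else
    as.matrix(rec)
  if (events[1] < 1 || events[length(events)] > nrow(x) + 1L) {
    stop("events out of recording range")
  }
  lapply(seq_len(length(events) - 1L), function(c) {
    x[events[c]:(events[c + 1L] - 1L), , drop = FALSE]
  })
}

#' Time-normalize one cycle slice to 101 phase points
#'
#' Each channel is linearly interpolated onto 101 equally spaced points
#' spanning the slice; endpoints are preserved exactly. NaNs are
#' propagated locally (an output point between two finite samples is
#' finite; one adjacent to a NaN is NaN) so that missing-data screening
#' can run after normalization.
#'
#' @param slice Numeric matrix `[len x n_channels]`, `len >= 2`.
#' @param n_points Number of phase points (101).
#' @return Matrix `[n_points x n_channels]`.
#' @export
normalize_cycle <- function(slice, n_points = 101L) {
  slice <- as.matrix(slice)
  len <- nrow(slice)
  if (len < 2) stop("cycle slice must have at least 2 samples")
  xin <- seq_len(len)
  xout <- seq(1, len, length.out = n_points)
  apply(slice, 2, function(ch) {
    # approx() drops NA support points; handle NaN runs explicitly
    if (anyNA(ch)) {
      ok <- is.finite(ch)
      out <- rep(NaN, n_points)
      if (sum(ok) >= 2) {
        # a resampled point is valid only if both bracketing samples are
        lo <- floor(xout); hi <- ceiling(xout)
        valid <- ok[lo] & ok[hi]
        out[valid] <- stats::approx(xin[ok], ch[ok], xout = xout[valid],
                                    rule = 2)$y
        out[!valid] <- NaN
      }
      out
    } else {
      stats::approx(xin, ch, xout = xout)$y
    }
  })
}

#' Screen normalized cycles for missing data
#'
#' A cycle containing a run of `>= max_nan_run` consecutive missing values
#' in any channel is dropped; shorter gaps are repaired by linear
#' interpolation between the adjacent valid samples (edge gaps use the
#' nearest valid value).
#'
#' @param cycles List of `[101 x n_channels]` matrices (NaNs allowed).
#' @param max_nan_run Consecutive-NaN run length that triggers removal.
#' @return List with `cycles` (kept, repaired) and `report`
#'   (tibble: n_input, n_kept, n_dropped, n_repaired_values).
#' @export
screen_cycles <- function(cycles, max_nan_run = 3L) {
  longest_run <- function(v) {
    if (!anyNA(v)) return(0L)
    r <- rle(!is.finite(v))
    max(c(0L, r$lengths[r$values]))
  }
  repaired <- 0L
  kept <- list()
  dropped <- 0L
  for (cyc in cycles) {
    runs <- apply(cyc, 2, longest_run)
    if (any(runs >= max_nan_run)) {
      dropped <- dropped + 1L
      next
    }
    if (anyNA(cyc)) {
      for (j in seq_len(ncol(cyc))) {
        ch <- cyc[, j]
        bad <- !is.finite(ch)
        if (any(bad)) {
          idx <- seq_along(ch)
          cyc[bad, j] <- stats::approx(idx[!bad], ch[!bad], xout = idx[bad],
                                       rule = 2)$y
          repaired <- repaired + sum(bad)
        }
      }
    }
    kept[[length(kept) + 1L]] <- cyc
  }
  list(
    cycles = kept,
    report = tibble::tibble(
      n_input = length(cycles), n_kept = length(kept),
      n_dropped = dropped, n_repaired_values = repaired
    )
  )
}

#' Centered moving-average (mean) filter with reflection padding
#'
#' @param series Numeric vector.
#' @param window Odd window length; `window = 1` is the identity.
#' @return Filtered vector, same length.
#' @export
filter_accel <- function(series, window = 5L) {
  window <- as.integer(window)
  if (window %% 2 == 0) stop("mean-filter window must be odd")
  if (window == 1L) return(series)
  half <- (window - 1L) %/% 2L
  n <- length(series)
  if (n == 0) return(series)
  h <- min(half, n)
  pad <- c(series[h:1L], series, series[n:(n - h + 1L)])
  if (h < half) {  # very short series: extend with edge values
    pad <- c(rep(pad[1], half - h), pad, rep(pad[length(pad)], half - h))
  }
  as.numeric(stats::filter(pad, rep(1 / window, window), sides = 2))[
    (half + 1L):(half + n)]
}

#' Zero-phase Butterworth low-pass for gyroscope channels
#'
#' Forward-backward application (`signal::filtfilt`) of a 6th-order
#' low-pass Butterworth, cutoff 3.5 Hz by default: zero phase lag, DC
#' gain 1, squared magnitude response.
#'
#' @param series Numeric vector.
#' @param spec A [filter_spec()].
#' @return Filtered vector, same length.
#' @export
filter_gyro <- function(series, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$butter_cutoff >= spec$sampling_rate / 2) {
    stop("cutoff must be below the Nyquist frequency")
  }
  bf <- signal::butter(spec$butter_order,
                       spec$butter_cutoff / (spec$sampling_rate / 2),
                       type = "low")
  bf$b <- bf$b * (sum(bf$a) / sum(bf$b))   # pin DC gain exactly to 1
  n <- length(series)
  if (n < 2) return(series)
  # forward-backward pass with odd (anti-symmetric) reflection padding
  # sized from the slowest pole so edge transients decay below 1e-9
  r <- max(Mod(polyroot(rev(bf$a))))
  np <- max(ceiling(log(1e-16) / log(r)), 3 * spec$butter_order)
  tri <- function(k) {           # reflect offsets into [0, n-1]
    m <- 2L * (n - 1L)
    j <- k %% m
    ifelse(j <= n - 1L, j, m - j)
  }
  # filter around the mean: exact for constants, better conditioned
  mu <- mean(series)
  series <- series - mu
  left <- 2 * series[1] - series[1 + tri(np:1)]
  right <- 2 * series[n] - series[n - tri(1:np)]
  xp <- c(left, series, right)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(np + 1):(np + n)] + mu
}

#' Acceleration-to-angular-velocity ratio (AGRatio)
#'
#' Per-sample ratio of the acceleration vector norm to the
#' angular-velocity vector norm. The denominator is floored at `eps` so
#' rest periods stay finite.
#'
#' @param accel3 Matrix `[T x 3]` of Ax, Ay, Az.
#' @param gyro3 Matrix `[T x 3]` of Gx, Gy, Gz.
#' @param eps Denominator floor.
#' @return Numeric vector length T (non-negative).
#' @export
agratio <- function(accel3, gyro3, eps = 1e-8) {
  accel3 <- as.matrix(accel3); gyro3 <- as.matrix(gyro3)
  stopifnot(ncol(accel3) == 3, ncol(gyro3) == 3,
            nrow(accel3) == nrow(gyro3))
  num <- sqrt(rowSums(accel3^2))
  den <- pmax(sqrt(rowSums(gyro3^2)), eps)
  num / den
}

#' Dynamic acceleration (ADynamic)
#'
#' Per-sample `sqrt((Ax-g)^2 + (Ay-g)^2 + (Az-g)^2)` with
#' g = 9.81 m/s^2 subtracted from every axis (the literal published
#' form, default), or from a single configured axis
#' (`gravity_axis` in `"x","y","z"`) for physical consistency with a
#' gravity vector lying along one axis.
#'
#' @param accel3 Matrix `[T x 3]`.
#' @param g Gravitational acceleration.
#' @param gravity_axis `"all"` (literal, default) or one of
#'   `"x"`, `"y"`, `"z"`.
#' @return Numeric vector length T (non-negative).
#' @export
adynamic <- function(accel3, g = GRAVITY, gravity_axis = "all") {
  accel3 <- as.matrix(accel3)
  stopifnot(ncol(accel3) == 3)
  sub <- switch(gravity_axis,
    all = c(g, g, g),
    x = c(g, 0, 0), y = c(0, g, 0), z = c(0, 0, g),
    stop("gravity_axis must be 'all', 'x', 'y' or 'z'")
  )
  d <- sweep(accel3, 2, sub)
  sqrt(rowSums(d^2))
}

#' Delta-method noise variance of the AGRatio
#'
#' First-order approximation of `Var(|A|/|G|)` under independent
#' perturbations of the two norms:
#' `(sigma_A/mu_G)^2 + (mu_A*sigma_G/mu_G^2)^2`.
#'
#' @param mu_A,sigma_A Mean and noise sd of the acceleration norm.
#' @param mu_G,sigma_G Mean and noise sd of the angular-velocity norm.
#' @return Approximate variance (scalar).
#' @export
agr_variance_approx <- function(mu_A, sigma_A, mu_G, sigma_G) {
  if (mu_G == 0) stop("mu_G must be nonzero")
  (sigma_A / mu_G)^2 + (mu_A * sigma_G / mu_G^2)^2
}

#' Full preprocessing of one recording into 101-point gait cycles
#'
#' Pipeline: per-channel sensor filtering on the raw recording (mean
#' filter for accelerometers, zero-phase Butterworth for gyroscopes) ->
#' heel-strike segmentation -> 101-point time normalization -> NaN
#' screening -> appending the AGRatio and ADynamic channels per IMU
#' (8 channels per IMU total).
#'
#' @param rec An `imu_recording`.
#' @param events Heel-strike indices.
#' @param spec A [filter_spec()]; its sampling rate is overridden by the
#'   recording's.
#' @param filter Apply the sensor filters (disable for raw fidelity
#'   tests).
#' @param gravity_axis Passed to [adynamic()].
#' @return A `gait_cycles` object: list with `data` (array
#'   `[n_cycles x n_channels x 101]`), `channel_labels`, `activity`,
#'   and `report` (screening tibble).
#' @export
preprocess_recording <- function(rec, events, spec = filter_spec(),
                                 filter = TRUE, gravity_axis = "all") {
  labels <- attr(rec, "channel_labels")
  n_imus <- attr(rec, "n_imus")
  fs <- attr(rec, "sampling_rate")
  x <- as.matrix(rec[, labels, drop = FALSE])
  if (filter) {
    spec$sampling_rate <- fs
    is_acc <- grepl("_A[xyz]$", labels)
    for (j in seq_along(labels)) {
      if (anyNA(x[, j])) next  # filters run only on complete channels
      x[, j] <- if (is_acc[j]) filter_accel(x[, j], spec$accel_window)
                else filter_gyro(x[, j], spec)
    }
  }
  xr <- rec
  xr[, labels] <- tibble::as_tibble(as.data.frame(x))
  slices <- segment_cycles(xr, events)
  cycles <- lapply(slices, normalize_cycle)
  scr <- screen_cycles(cycles)

  out_labels <- as.vector(vapply(seq_len(n_imus), function(i) {
    c(paste0("imu", i, "_", c("Ax", "Ay", "Az", "Gx", "Gy", "Gz")),
      paste0("imu", i, "_AGRatio"), paste0("imu", i, "_ADynamic"))
  }, character(8)))

  n_kept <- length(scr$cycles)
  data <- array(0, dim = c(n_kept, 8L * n_imus, 101L),
                dimnames = list(NULL, out_labels, NULL))
  for (c in seq_len(n_kept)) {
    cyc <- scr$cycles[[c]]
    for (i in seq_len(n_imus)) {
      a <- cyc[, (i - 1) * 6 + 1:3, drop = FALSE]
      g <- cyc[, (i - 1) * 6 + 4:6, drop = FALSE]
      block <- cbind(a, g, agratio(a, g),
                     adynamic(a, gravity_axis = gravity_axis))
      data[c, (i - 1) * 8 + 1:8, ] <- t(block)
    }
  }
  structure(
    list(data = data, channel_labels = out_labels,
         activity = attr(rec, "activity_label") %||% "unknown",
         report = scr$report),
    class = "gait_cycles"
  )
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat("<gait_cycles> ", dim(x$data)[1], " cycles x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " phase points\n", sep = "")
  invisible(x)
}

#' Heuristic heel-strike detector from gyroscope energy (convenience)
#'
#' Detects cycle boundaries as prominent minima of the smoothed summed
#' gyroscope norm. Provided for recordings without annotations; synthetic
#' recordings carry exact events and published protocols use external
#' (EMG-based) event detection, so this is a convenience only.
#'
#' @param rec An `imu_recording`.
#' @param min_cycle_s Minimum cycle duration in seconds.
#' @return Integer vector of candidate heel-strike indices.
#' @export
detect_heel_strikes <- function(rec, min_cycle_s = 0.5) {
  labels <- attr(rec, "channel_labels")
  fs <- attr(rec, "sampling_rate")
  gy <- as.matrix(rec[, grepl("_G[xyz]$", labels), drop = FALSE])
  e <- filter_accel(sqrt(rowSums(gy^2)), 21L)
  n <- length(e)
  min_gap <- as.integer(min_cycle_s * fs)
  # local minima below the median, separated by at least min_gap
  cand <- which(diff(sign(diff(e))) > 0) + 1L
  cand <- cand[e[cand] < stats::median(e)]
  out <- integer(0)
  for (i in cand) {
    if (length(out) == 0L || i - out[length(out)] >= min_gap) {
      out <- c(out, i)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
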