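#' Configuration for the synthetic multi-IMU gait generator
#'
#' The generator emulates the structure of treadmill/overground gait
#' recordings used for joint-torque regression: periodic multi-IMU signals
#' segmented heel-strike to heel-strike, with per-cycle duration and
#' amplitude variability, a gravity component on the accelerometers, and a
#' smooth phase-locked torque template per joint.
#'
#' @param n_imus Number of IMUs (each contributes 6 raw channels).
#' @param sampling_rate Sampling rate in Hz.
#' @param n_cycles Number of gait cycles to generate.
#' @param cycle_duration_mean Mean cycle duration in seconds.
#' @param cycle_duration_jitter Fractional standard deviation of per-cycle
#'   duration (0 disables duration variability).
#' @param amplitude_jitter Fractional standard deviation of the per-cycle
#'   multiplicative amplitude factor.
#' @param harmonic_count Number of Fourier harmonics per channel.
#' @param harmonic_scale Overall motion amplitude scale; 0 yields a
#'   motion-free recording (gravity projection only).
#' @param torque_profile Identifier of the per-joint phase-to-torque
#'   template set. Only `"default"` is defined.
#' @param noise_floor Standard deviation of additive white sensor noise, in
#'   raw units (m/s^2 and rad/s).
#' @param subject_mass Subject mass in kg (metadata only; torques are
#'   already mass-normalized).
#' @param activity_label Activity category attached to every cycle.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_imus = 4,
                         sampling_rate = 200,
                         n_cycles = 30,
                         cycle_duration_mean = 1.1,
                         cycle_duration_jitter = 0.05,
                         amplitude_jitter = 0.10,
                         harmonic_count = 4,
                         harmonic_scale = 1,
                         torque_profile = "default",
                         noise_floor = 0.02,
                         subject_mass = 70,
                         activity_label = "walk",
                         seed = 1L) {
  stopifnot(
    n_imus >= 1, sampling_rate > 0, n_cycles >= 1,
    cycle_duration_mean > 0, cycle_duration_jitter >= 0,
    amplitude_jitter >= 0, harmonic_count >= 0, noise_floor >= 0
  )
  if (!identical(torque_profile, "default")) {
    stop("unknown torque_profile: ", torque_profile)
  }
  structure(
    list(
      n_imus = as.integer(n_imus), sampling_rate = sampling_rate,
      n_cycles = as.integer(n_cycles),
      cycle_duration_mean = cycle_duration_mean,
      cycle_duration_jitter = cycle_duration_jitter,
      amplitude_jitter = amplitude_jitter,
      harmonic_count = as.integer(harmonic_count),
      harmonic_scale = harmonic_scale,
      torque_profile = torque_profile,
      noise_floor = noise_floor, subject_mass = subject_mass,
      activity_label = activity_label, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Standard gravitational acceleration used throughout the package (m/s^2)
#' @export
GRAVITY <- 9.81

raw_channel_labels <- function(n_imus) {
  as.vector(vapply(seq_len(n_imus), function(i) {
    paste0("imu", i, "_", c("Ax", "Ay", "Az", "Gx", "Gy", "Gz"))
  }, character(6)))
}

#' Per-joint torque templates on the 0-100% phase grid
#'
#' Smooth, phase-locked, mass-normalized (N·m/kg) templates: a biphasic
#' hip profile and single-bump knee/ankle profiles with amplitudes near
#' 1 N·m/kg. The shapes are deliberately simple stand-ins for inverse
#' dynamics output — chosen only to be smooth and learnable.
#'
#' @param phase Numeric vector of phases in `[0, 1]`.
#' @return Matrix `[length(phase) x 3]` with columns hip, knee, ankle.
#' @export
torque_templates <- function(phase = seq(0, 1, length.out = 101)) {
  hip <- 0.8 * sin(2 * pi * phase) + 0.25 * sin(4 * pi * phase)
  knee <- 0.9 * exp(-((phase - 0.25) / 0.12)^2) -
    0.35 * exp(-((phase - 0.70) / 0.10)^2)
  ankle <- 1.2 * exp(-((phase - 0.45) / 0.10)^2) - 0.1
  cbind(hip = hip, knee = knee, ankle = ankle)
}

#' Generate a synthetic multi-IMU gait recording
#'
#' Channels are sums of cycle-phase-locked harmonics with per-cycle
#' duration and amplitude jitter; accelerometer channels carry gravity on
#' the z axis so the rest-state acceleration norm is 9.81 m/s^2. Torque is
#' the fixed smooth template of cycle phase evaluated on the 101-point
#' grid. Heel strikes mark cycle boundaries.
#'
#' @param config A [synth_config()].
#' @return A list with components
#'   \describe{
#'     \item{recording}{`imu_recording`: tibble with `time_s` and one
#'       column per channel, plus attributes `sampling_rate`,
#'       `subject_mass`, `n_imus`, `channel_labels`.}
#'     \item{events}{Integer vector of heel-strike sample indices
#'       (1-based, strictly increasing, length `n_cycles + 1`).}
#'     \item{torque}{`torque_trace`: array `[n_cycles x 3 x 101]`.}
#'   }
#' @export
generate_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr_seed <- config$seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)

  n_ch <- 6L * config$n_imus
  fs <- config$sampling_rate

  # per-cycle durations (samples)
  dur_s <- config$cycle_duration_mean *
    (1 + config$cycle_duration_jitter * stats::rnorm(config$n_cycles))
  dur_s <- pmax(dur_s, 0.3 * config$cycle_duration_mean)
  dur_n <- pmax(4L, as.integer(round(dur_s * fs)))
  heel_strikes <- as.integer(cumsum(c(1L, dur_n)))
  total_n <- heel_strikes[length(heel_strikes)] - 1L

  # phase signal over the whole recording, in [0,1) per cycle
  phase <- numeric(total_n)
  cycle_id <- integer(total_n)
  for (c in seq_len(config$n_cycles)) {
    idx <- heel_strikes[c]:(heel_strikes[c + 1L] - 1L)
    phase[idx] <- (seq_along(idx) - 1) / length(idx)
    cycle_id[idx] <- c
  }

  # channel-specific harmonic amplitudes and phase offsets (seeded)
  H <- config$harmonic_count
  amp <- matrix(stats::rnorm(n_ch * max(H, 1)), n_ch, max(H, 1))
  amp <- amp * config$harmonic_scale / outer(rep(1, n_ch), seq_len(max(H, 1)))
  phs <- matrix(stats::runif(n_ch * max(H, 1), 0, 2 * pi), n_ch, max(H, 1))
  # accel channels get a larger base scale than gyro (m/s^2 vs rad/s)
  ch_scale <- rep(rep(c(3, 1.5), each = 3), config$n_imus)

  # per-cycle multiplicative amplitude factor
  cyc_amp <- 1 + config$amplitude_jitter * stats::rnorm(config$n_cycles)

  samples <- matrix(0, total_n, n_ch)
  if (H >= 1) {
    for (h in seq_len(H)) {
      base <- sin(outer(2 * pi * h * phase, rep(1, n_ch)) +
                    matrix(phs[, h], total_n, n_ch, byrow = TRUE))
      samples <- samples +
        base * matrix(amp[, h] * ch_scale, total_n, n_ch, byrow = TRUE)
    }
    samples <- samples * cyc_amp[cycle_id]
  }

  # gravity on each IMU's z accelerometer: rest-state norm = 9.81
  labels <- raw_channel_labels(config$n_imus)
  az <- grepl("_Az$", labels)
  samples[, az] <- samples[, az] + GRAVITY

  if (config$noise_floor > 0) {
    samples <- samples + config$noise_floor * stats::rnorm(length(samples))
  }

  colnames(samples) <- labels
  rec <- tibble::as_tibble(as.data.frame(samples))
  rec <- tibble::add_column(rec, time_s = (seq_len(total_n) - 1) / fs,
                            .before = 1)
  attr(rec, "sampling_rate") <- fs
  attr(rec, "subject_mass") <- config$subject_mass
  attr(rec, "n_imus") <- config$n_imus
  attr(rec, "channel_labels") <- labels
  attr(rec, "activity_label") <- config$activity_label
  class(rec) <- c("imu_recording", class(rec))

  tmpl <- torque_templates()
  torque <- array(0, dim = c(config$n_cycles, 3L, 101L),
                  dimnames = list(NULL, c("hip", "knee", "ankle"), NULL))
  for (j in 1:3) torque[, j, ] <- matrix(tmpl[, j], config$n_cycles, 101,
                                         byrow = TRUE)
  class(torque) <- "torque_trace"

  list(recording = rec, events = heel_strikes, torque = torque)
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

#' Specification of a sensor perturbation
#'
#' Exactly one perturbation kind is active: i.i.d. Gaussian noise
#' (default sd 0.05), a constant offset (default 0.1), or a fixed 5-degree
#' rigid rotation of each IMU's acceleration and angular-velocity triplets
#' about a seeded random axis (modelling unknown mounting misalignment).
#'
#' Gaussian and offset magnitudes are dimensionless; with
#' `normalized = TRUE` (default) they act on the per-channel standardized
#' signal scale (i.e., they are multiplied by each channel's standard
#' deviation before being added in raw units), otherwise they are applied
#' in raw sensor units.
#'
#' @param kind One of `"gaussian"`, `"offset"`, `"rotation"`.
#' @param gaussian_std Noise standard deviation (signal-scale units).
#' @param offset_value Constant offset (signal-scale units).
#' @param rotation_deg Rotation angle in degrees.
#' @param normalized Apply gaussian/offset on the standardized scale.
#' @param seed Integer seed for the noise draw / rotation axis.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(kind = c("gaussian", "offset", "rotation"),
                       gaussian_std = 0.05, offset_value = 0.1,
                       rotation_deg = 5, normalized = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(gaussian_std >= 0, rotation_deg >= 0)
  structure(
    list(kind = kind, gaussian_std = gaussian_std,
         offset_value = offset_value, rotation_deg = rotation_deg,
         normalized = normalized, seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Rotation matrix about an arbitrary axis (Rodrigues formula)
#' @param axis Length-3 axis (normalized internally).
#' @param angle_deg Angle in degrees.
#' @return 3x3 proper rotation matrix (determinant +1).
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Inject a sensor perturbation into a recording
#'
#' @param rec An `imu_recording`.
#' @param spec A [noise_spec()].
#' @return A perturbed copy of `rec` (inputs are never mutated).
#' @export
inject_noise <- function(rec, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  labels <- attr(rec, "channel_labels")
  x <- as.matrix(rec[, labels, drop = FALSE])
  set.seed(spec$seed)
  scale_per_ch <- if (isTRUE(spec$normalized)) {
    s <- apply(x, 2, stats::sd)
    ifelse(s > 0, s, 1)
  } else {
    rep(1, ncol(x))
  }

  if (spec$kind == "gaussian") {
    noise <- matrix(stats::rnorm(length(x), sd = spec$gaussian_std),
                    nrow(x), ncol(x))
    x <- x + noise * matrix(scale_per_ch, nrow(x), ncol(x), byrow = TRUE)
  } else if (spec$kind == "offset") {
    x <- x + matrix(spec$offset_value * scale_per_ch,
                    nrow(x), ncol(x), byrow = TRUE)
  } else if (spec$kind == "rotation") {
    n_imus <- attr(rec, "n_imus")
    axis <- stats::rnorm(3)
    R <- rotation_matrix(axis, spec$rotation_deg)
    for (i in seq_len(n_imus)) {
      a_cols <- (i - 1) * 6 + 1:3
      g_cols <- (i - 1) * 6 + 4:6
      x[, a_cols] <- x[, a_cols] %*% t(R)
      x[, g_cols] <- x[, g_cols] %*% t(R)
    }
  } else {
    stop("unknown perturbation kind: ", spec$kind)
  }
  out <- rec
  out[, labels] <- tibble::as_tibble(as.data.frame(x))
  out
}

#' Replace runs of samples with NaN (fixture for the screening rule)
#'
#' @param rec An `imu_recording`.
#' @param positions Integer vector of run start indices (1-based rows).
#' @param run_lengths Integer vector (recycled against `positions`).
#' @param channels Channel labels to corrupt; default all.
#' @return Corrupted copy of `rec`.
#' @export
corrupt_with_nans <- function(rec, positions, run_lengths = 1L,
                              channels = attr(rec, "channel_labels")) {
  if (length(positions) == 0L) return(rec)
  run_lengths <- rep_len(as.integer(run_lengths), length(positions))
  n <- nrow(rec)
  ends <- positions + run_lengths - 1L
  if (any(positions < 1L) || any(ends > n)) {
    stop("NaN run positions out of range [1, ", n, "]")
  }
  out <- rec
  for (k in seq_along(positions)) {
    rows <- positions[k]:ends[k]
    out[rows, channels] <- NaN
  }
  out
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_imus, " IMU(s), ", x$n_cycles, " cycles @ ",
      x$sampling_rate, " Hz, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
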