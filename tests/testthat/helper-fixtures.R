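# Shared fixtures, built in code at test time.

tiny_recording <- function(n_cycles = 5, n_imus = 1, seed = 7, ...) {
  generate_recording(synth_config(n_imus = n_imus, n_cycles = n_cycles,
                                  seed = seed, ...))
}

# A tiny hybrid configuration that exercises every block cheaply.
tiny_model_config <- function(variant = "full", dropout_rate = 0) {
  model_config(in_channels = 6L, in_length = 24L,
               input_layout = "channels_time",
               stem_filters = c(4L, 8L), res_filters = c(4L, 8L),
               fc_sizes = c(16L, 8L), lstm_hidden = 4L, attn_window = 5L,
               dropout_rate = dropout_rate, n_joints = 2L,
               out_points = 5L, variant = variant)
}

# Brute-force CWT by direct summation of the transform integral on the
# same scale grid (independent oracle for cwt_morlet).
brute_force_cwt <- function(x, scales, fs, omega0 = 7) {
  n <- length(x)
  dt <- 1 / fs
  out <- matrix(0i, length(scales), n)
  for (s in seq_along(scales)) {
    a <- scales[s]
    for (b in seq_len(n)) {
      t <- (seq_len(n) - b) * dt
      out[s, b] <- sum(x * Conj(morlet(t / a, omega0))) * dt / sqrt(a)
    }
  }
  out
}

# Central-difference loss gradient for a parameter entry of a layer.
numeric_grad <- function(layer, name, index, loss_fn, eps = 1e-5) {
  p0 <- layer$params[[name]][index]
  layer$params[[name]][index] <- p0 + eps
  lp <- loss_fn()
  layer$params[[name]][index] <- p0 - eps
  lm <- loss_fn()
  layer$params[[name]][index] <- p0
  (lp - lm) / (2 * eps)
}

# Small standardized random window for time-frequency tests.
tiny_window <- function(k = 2, n = 30, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(k * n), k, n)
  structure(list(x = x, center_cycle = 2L, activity = "walk"),
            class = "feature_window")
}
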