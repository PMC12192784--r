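test_that("Morlet wavelet matches its closed form", {
  expect_equal(Re(morlet(0)), pi^(-1 / 4), tolerance = 1e-12)
  expect_equal(Im(morlet(0)), 0)
  t <- seq(-3, 3, by = 0.37)
  expect_equal(Mod(morlet(t)), Mod(morlet(-t)))
  # squared norm by quadrature: integral of pi^(-1/2) exp(-t^2) = 1
  tt <- seq(-12, 12, length.out = 20001)
  q <- sum(Mod(morlet(tt, 7))^2) * diff(tt)[1]
  expect_equal(q, 1, tolerance = 1e-6)
})

test_that("scale grid maps the center-frequency relation onto the band", {
  sp <- wavelet_spec(n_scales = 2, freq_range = c(0.5, 5), omega0 = 7)
  sc <- scale_grid(sp)
  expect_equal(sc[1], 7 / (2 * pi * 0.5), tolerance = 1e-12)
  expect_equal(sc[2], 7 / (2 * pi * 5), tolerance = 1e-12)
  expect_equal(sc[1], 2.2282, tolerance = 1e-4)
  expect_equal(sc[2], 0.22282, tolerance = 1e-4)

  sp32 <- wavelet_spec(n_scales = 32)
  f <- attr(scale_grid(sp32), "frequencies")
  expect_equal(f[1], 0.5, tolerance = 1e-9)
  expect_equal(f[32], 5, tolerance = 1e-9)
  expect_true(all(diff(f) > 0))

  sp14 <- wavelet_spec(omega0 = 14, n_scales = 32)
  expect_equal(scale_grid(sp14), 2 * scale_grid(sp32),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(wavelet_spec(freq_range = c(5, 0.5)))
})

test_that("CWT is linear, zero-preserving and matches direct summation", {
  sp <- wavelet_spec(n_scales = 4, sampling_rate = 50)
  expect_equal(cwt_morlet(rep(0, 40), sp), matrix(0i, 4, 40))

  set.seed(3)
  x <- rnorm(40)
  W <- cwt_morlet(x, sp)
  expect_lt(max(Mod(cwt_morlet(2.5 * x, sp) - 2.5 * W)), 1e-10)

  Wb <- brute_force_cwt(x, scale_grid(sp), 50, 7)
  expect_lt(max(Mod(W - Wb)), 1e-10)

  expect_error(cwt_morlet(numeric(0), sp), "empty")
  expect_error(cwt_morlet(c(1, NA, 2), sp), "finite")
})

test_that("pure tones peak at the scale given by f = omega0/(2 pi a)", {
  sp <- wavelet_spec(n_scales = 32, sampling_rate = 101 / 1.1)
  sc <- scale_grid(sp)
  n <- 303
  tt <- (0:(n - 1)) / sp$sampling_rate
  central <- 102:202
  for (f in c(0.8, 1.6, 3.2)) {
    W <- cwt_morlet(sin(2 * pi * f * tt), sp)
    got <- which.max(rowMeans(Mod(W[, central])^2))
    want <- which.min(abs(sc - 7 / (2 * pi * f)))
    expect_lte(abs(got - want), 1)
  }
})

test_that("window construction slides three cycles with stride one", {
  g <- tiny_recording(n_cycles = 10)
  cyc <- preprocess_recording(g$recording, g$events)
  w <- build_windows(cyc)
  expect_length(w, 8)
  expect_equal(dim(w[[1]]$x), c(8, 303))
  expect_equal(vapply(w, function(z) z$center_cycle, 0L), 2:9)
  # window content is the concatenation of its three cycles
  expect_equal(w[[1]]$x[, 102:202], cyc$data[2, , ], ignore_attr = TRUE)

  cyc3 <- cyc; cyc3$data <- cyc$data[1:3, , , drop = FALSE]
  expect_length(build_windows(cyc3), 1)
  cyc2 <- cyc; cyc2$data <- cyc$data[1:2, , , drop = FALSE]
  expect_length(build_windows(cyc2), 0)
})

test_that("scalogram stacks have k = 8 x n_imus channels", {
  for (k in c(1, 4)) {
    g <- tiny_recording(n_cycles = 3, n_imus = k)
    cyc <- preprocess_recording(g$recording, g$events)
    w <- build_windows(cyc)[[1]]
    st <- scalogram_stack(w, wavelet_spec(n_scales = 6))
    expect_equal(dim(st), c(8 * k, 6, 303))
    expect_true(all(is.finite(st)))
    expect_true(all(unclass(st) >= 0))  # magnitudes
  }
  zero_w <- structure(list(x = matrix(0, 2, 303), center_cycle = 2L,
                           activity = "walk"),
                      class = "feature_window")
  st0 <- scalogram_stack(zero_w, wavelet_spec(n_scales = 3))
  expect_equal(max(abs(st0)), 0)
})

test_that("scalogram energy grows monotonically with signal amplitude", {
  w <- tiny_window(k = 1, n = 60)
  sp <- wavelet_spec(n_scales = 5, sampling_rate = 60)
  energies <- vapply(c(0.5, 1, 2, 4), function(a) {
    wa <- w; wa$x <- a * w$x
    sum(unclass(scalogram_stack(wa, sp))^2)
  }, 0)
  expect_true(all(diff(energies) > 0))
})

test_that("flatten is the lossless (channel, scale, time) expansion", {
  set.seed(9)
  S <- array(rnorm(2 * 3 * 5), dim = c(2, 3, 5))
  v <- flatten_stack(S)
  expect_length(v, 30)
  expect_identical(unflatten_stack(v), S)
  # zero-based (c, s, t) lands at c*m*n + s*n + t
  expect_equal(v[1 * 15 + 0 * 5 + 0 + 1], S[2, 1, 1])
  expect_equal(v[1 * 15 + 2 * 5 + 3 + 1], S[2, 3, 4])
  # random stacks round trip exactly
  for (i in 1:5) {
    S2 <- array(rnorm(4 * 2 * 7), dim = c(4, 2, 7))
    expect_identical(unflatten_stack(flatten_stack(S2)), S2)
  }
})

test_that("STFT and DWT comparators behave as standard transforms", {
  zw <- tiny_window(k = 2, n = 96)
  zw$x[] <- 0
  expect_equal(max(abs(stft_features(zw, 32, 8))), 0)
  expect_equal(max(abs(dwt_features(zw))), 0)

  cw <- zw; cw$x[] <- 1
  st <- stft_features(cw, 32, 8)
  spec1 <- st[1, , 1]
  expect_equal(which.max(spec1), 1L)  # energy concentrated at DC
  # bin 2 carries Hann leakage; beyond it the spectrum is negligible
  expect_gt(spec1[1], 10 * max(spec1[-(1:2)]))

  expect_error(stft_features(zw, 1000, 8), "frame longer")

  set.seed(4)
  x <- rnorm(96)
  dec <- dwt_haar(x, 3)
  expect_lt(max(abs(dwt_reconstruct(dec) - x)), 1e-8)
  # orthogonality: coefficient energy equals signal energy
  expect_equal(sum(dec$approx^2) + sum(unlist(dec$details)^2), sum(x^2),
               tolerance = 1e-10)
})

test_that("feature dataset shapes follow method and layout", {
  g <- tiny_recording(n_cycles = 5, n_imus = 1)
  cyc <- preprocess_recording(g$recording, g$events)
  sp <- wavelet_spec(n_scales = 3)
  ds <- build_feature_dataset(list(cyc), list(g$torque), sp)
  expect_equal(dim(ds$x), c(8 * 3, 303, 3))
  expect_equal(dim(ds$y), c(3, 101, 3))
  expect_equal(ds$meta$center_cycle, 2:4)
  expect_equal(ds$y[, , 1], unclass(g$torque)[2, , ],
               ignore_attr = TRUE)

  flat <- build_feature_dataset(list(cyc), list(g$torque), sp,
                                layout = "flat")
  expect_equal(dim(flat$x), c(1, 8 * 3 * 303, 3))

  raw <- build_feature_dataset(list(cyc), list(g$torque), sp,
                               method = "raw")
  expect_equal(dim(raw$x), c(8, 303, 3))
})
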