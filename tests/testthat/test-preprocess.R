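test_that("segmentation follows the half-open heel-strike convention", {
  x <- matrix(rnorm(500 * 2), 500, 2)
  sl <- segment_cycles(x, c(1, 201, 431))
  expect_length(sl, 2)
  expect_equal(nrow(sl[[1]]), 200)
  expect_equal(nrow(sl[[2]]), 230)
  expect_equal(sl[[1]][1, ], x[1, ])

  sl1 <- segment_cycles(x, c(1, 101))
  expect_length(sl1, 1)
  expect_equal(nrow(sl1[[1]]), 100)

  expect_error(segment_cycles(x, c(100, 100)), "strictly increasing")
  expect_error(segment_cycles(x, 5), "at least 2")
})

test_that("time normalization emits 101 points, preserves endpoints and
           reproduces linear ramps exactly", {
  sl <- matrix(rnorm(87 * 3), 87, 3)
  out <- normalize_cycle(sl)
  expect_equal(dim(out), c(101, 3))
  expect_equal(out[1, ], sl[1, ])
  expect_equal(out[101, ], sl[87, ])

  const <- normalize_cycle(matrix(4.2, 13, 1))
  expect_equal(as.vector(const), rep(4.2, 101))

  ramp <- normalize_cycle(matrix(seq(0, 1, length.out = 55), 55, 1))
  expect_lt(max(abs(as.vector(ramp) - seq(0, 1, length.out = 101))),
            1e-12)

  expect_error(normalize_cycle(matrix(1, 1, 1)), "at least 2")
})

test_that("screening drops >=3-run NaN cycles and repairs single gaps", {
  clean <- matrix(rnorm(101 * 2), 101, 2)
  bad <- clean
  bad[40:42, 1] <- NaN            # run of 3 in one channel -> dropped
  repairable <- clean
  repairable[50, 2] <- NaN        # single gap -> interpolated
  repairable[49, 2] <- 2
  repairable[51, 2] <- 4

  res <- screen_cycles(list(clean, bad, repairable))
  expect_equal(res$report$n_input, 3)
  expect_equal(res$report$n_kept, 2)
  expect_equal(res$report$n_dropped, 1)
  expect_equal(res$report$n_repaired_values, 1)
  expect_identical(res$cycles[[1]], clean)           # untouched
  expect_equal(res$cycles[[2]][50, 2], 3)            # mean of neighbors
  # kept cycles modified only at repaired positions
  expect_equal(res$cycles[[2]][-50, ], repairable[-50, ])

  two_run <- clean; two_run[10:11, 1] <- NaN
  expect_equal(screen_cycles(list(two_run))$report$n_kept, 1)
  all_bad <- clean; all_bad[, 1] <- NaN
  expect_length(screen_cycles(list(all_bad))$cycles, 0)
})

test_that("mean filter matches hand-computed symmetric-padding cases", {
  # window 3 on (0,3,0): pad -> (0, 0,3,0, 0); means are (1, 1, 1)
  expect_equal(filter_accel(c(0, 3, 0), 3), c(1, 1, 1))
  # window 3 on (1,2,4,8): pad -> (1, 1,2,4,8, 8)
  expect_equal(filter_accel(c(1, 2, 4, 8), 3),
               c(4 / 3, 7 / 3, 14 / 3, 20 / 3))
  expect_equal(filter_accel(rep(2.5, 10), 5), rep(2.5, 10))
  expect_equal(filter_accel(1:7, 1), 1:7)
  expect_error(filter_accel(1:10, 4), "odd")
})

test_that("zero-phase Butterworth matches the closed-form magnitude
           response", {
  spec <- filter_spec(sampling_rate = 200)
  const <- filter_gyro(rep(3, 400), spec)
  expect_lt(max(abs(const - 3)), 1e-9)

  # |H(f)|^2 for one pass is 1/(1+(f/fc)^(2n)); filtfilt squares it
  gain <- function(f) (1 / (1 + (f / 3.5)^12))
  t <- (0:1999) / 200
  for (f in c(0.5, 35)) {
    y <- filter_gyro(sin(2 * pi * f * t), spec)
    mid <- 500:1500
    amp <- (max(y[mid]) - min(y[mid])) / 2
    if (f == 0.5) {
      expect_equal(amp, gain(0.5), tolerance = 0.01)
      expect_gt(amp, 0.99)
    } else {
      expect_lt(amp, 1e-5)  # >= 100 dB attenuation at 35 Hz
    }
  }
  bad <- filter_spec(sampling_rate = 200)
  bad$butter_cutoff <- 150
  expect_error(filter_gyro(rnorm(100), bad), "Nyquist")
})

test_that("passband filtering is nearly idempotent", {
  t <- (0:3999) / 200
  x <- sin(2 * pi * 0.1 * t)
  spec <- filter_spec(sampling_rate = 200)
  y1 <- filter_gyro(x, spec)
  y2 <- filter_gyro(y1, spec)
  mid <- 1000:3000
  a1 <- (max(y1[mid]) - min(y1[mid])) / 2
  a2 <- (max(y2[mid]) - min(y2[mid])) / 2
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("AGRatio arithmetic, epsilon floor and rotation invariance", {
  expect_equal(agratio(matrix(c(3, 0, 0), 1), matrix(c(0, 4, 0), 1)),
               0.75)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(agratio(a, a), rep(1, 10))
  expect_equal(agratio(matrix(c(3, 4, 0), 1), matrix(0, 1, 3)),
               5 / 1e-8)

  set.seed(2)
  g <- matrix(rnorm(30), 10, 3)
  R <- rotation_matrix(rnorm(3), 37)
  expect_lt(max(abs(agratio(a %*% t(R), g %*% t(R)) - agratio(a, g))),
            1e-9)
})

test_that("ADynamic follows the printed per-axis subtraction", {
  expect_equal(adynamic(matrix(c(9.81, 9.81, 9.81), 1)), 0)
  expect_equal(adynamic(matrix(c(12.81, 9.81, 13.81), 1)), 5)
  expect_equal(adynamic(matrix(0, 1, 3)), 9.81 * sqrt(3))
  expect_equal(adynamic(matrix(c(0, 0, 9.81), 1), gravity_axis = "z"), 0)
})

test_that("AGRatio noise-variance approximation matches Monte Carlo", {
  expect_equal(agr_variance_approx(1, 0, 2, 0), 0)
  expect_equal(agr_variance_approx(1, 0.1, 2, 0), 0.0025)
  expect_error(agr_variance_approx(1, 0.1, 0, 0.1), "nonzero")

  # delta-method vs simulation, error shrinking along a sigma ladder
  set.seed(11)
  n <- 1e6
  mu_A <- 10; mu_G <- 5
  rel_err <- vapply(c(0.4, 0.2, 0.1), function(s) {
    A <- mu_A + s * 2 * rnorm(n)
    G <- mu_G + s * rnorm(n)
    mc <- var(A / G)
    ap <- agr_variance_approx(mu_A, s * 2, mu_G, s)
    abs(ap - mc) / mc
  }, 0)
  expect_lt(rel_err[3], 0.15)
  expect_true(rel_err[3] < rel_err[1])
})

test_that("preprocessing emits 8 channels per IMU and 101 points", {
  for (k in c(1, 4)) {
    g <- tiny_recording(n_cycles = 4, n_imus = k)
    cyc <- preprocess_recording(g$recording, g$events)
    expect_equal(dim(cyc$data), c(4, 8 * k, 101))
    expect_true(all(is.finite(cyc$data)))
    agr <- cyc$data[, grepl("AGRatio", cyc$channel_labels), ]
    expect_true(all(agr >= 0))
  }
  # heavily corrupted recording -> empty output plus report
  g <- tiny_recording(n_cycles = 3)
  bad <- corrupt_with_nans(g$recording,
                           positions = g$events[1:3] + 5,
                           run_lengths = 60)
  cyc <- preprocess_recording(bad, g$events)
  expect_equal(dim(cyc$data)[1], 0)
  expect_equal(cyc$report$n_dropped, 3)
})

test_that("segmentation recovers exactly n_cycles from generated data", {
  for (nc in c(2, 7)) {
    g <- tiny_recording(n_cycles = nc, seed = nc)
    expect_length(segment_cycles(g$recording, g$events), nc)
  }
})
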