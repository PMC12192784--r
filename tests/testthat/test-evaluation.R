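test_that("metrics match hand-computed values and definitions", {
  y <- c(1, 2, 3)
  yh <- c(1.5, 2, 2.5)
  m <- torque_metrics(y, yh)
  expect_equal(m$rmse, sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(m$mae, 1 / 3, tolerance = 1e-12)
  expect_equal(m$r2, 0.75, tolerance = 1e-12)
  expect_equal(m$pcc, 1, tolerance = 1e-12)

  perfect <- torque_metrics(y, y)
  expect_equal(perfect[, c("rmse", "r2", "mae", "pcc")],
               tibble::tibble(rmse = 0, r2 = 1, mae = 0, pcc = 1))

  mean_pred <- torque_metrics(y, rep(mean(y), 3))
  expect_equal(mean_pred$r2, 0)
  expect_true(is.na(mean_pred$pcc))  # constant prediction: undefined
  expect_equal(mean_pred$rmse, sqrt(2 / 3))
})

test_that("metrics agree with a brute-force implementation on random
           vectors", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    y <- rnorm(n); yh <- rnorm(n)
    m <- torque_metrics(y, yh)
    expect_equal(m$rmse, sqrt(sum((yh - y)^2) / n), tolerance = 1e-10)
    expect_equal(m$mae, sum(abs(yh - y)) / n, tolerance = 1e-10)
    expect_equal(m$r2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
    expect_equal(m$pcc,
                 sum((yh - mean(yh)) * (y - mean(y))) /
                   ((n - 1) * sd(yh) * sd(y)),
                 tolerance = 1e-10)
    expect_gte(m$rmse, m$mae)  # power-mean inequality
  }
})

test_that("metric invariances: shifts and scalings", {
  set.seed(18)
  y <- rnorm(50); yh <- y + rnorm(50, sd = 0.3)
  m0 <- torque_metrics(y, yh)
  ms <- torque_metrics(y + 5, yh + 5)
  expect_equal(ms$rmse, m0$rmse, tolerance = 1e-12)
  expect_equal(ms$mae, m0$mae, tolerance = 1e-12)
  expect_equal(ms$pcc, m0$pcc, tolerance = 1e-12)
  mg <- torque_metrics(3 * y + 2, 3 * yh + 2)
  expect_equal(mg$pcc, m0$pcc, tolerance = 1e-12)
})

test_that("per-joint breakdown pools consistently", {
  set.seed(19)
  y <- array(rnorm(3 * 101 * 4), dim = c(3, 101, 4))
  yh <- y + array(rnorm(length(y), sd = 0.1), dim = dim(y))
  tab <- metrics_by_joint(y, yh)
  expect_equal(tab$joint, c("hip", "knee", "ankle", "all"))
  expect_equal(tab$n, c(rep(101 * 4, 3), 3 * 101 * 4))
  expect_equal(tab$rmse[4], torque_metrics(y, yh)$rmse)
})

test_that("repeated trials aggregate deterministic pipelines exactly", {
  stub <- function(seed) tibble::tibble(rmse = 0.5, r2 = 0.9)
  ts <- repeated_trials(stub, seeds = 1:5)
  expect_equal(nrow(ts$trials), 5)
  expect_equal(ts$summary$sd, c(0, 0))
  expect_equal(ts$summary$mean, c(0.5, 0.9))

  lin <- function(seed) tibble::tibble(value = seed)
  t2 <- repeated_trials(lin, seeds = c(2L, 4L))
  expect_equal(t2$summary$mean, 3)
  expect_equal(t2$summary$mean,
               mean(t2$trials$value), tolerance = 1e-12)
  expect_match(t2$summary$formatted, "±")

  expect_error(repeated_trials(stub, seeds = c(1, 1)), "distinct")
  flaky <- function(seed) {
    if (seed == 2) stop("boom")
    tibble::tibble(v = 1)
  }
  expect_warning(t3 <- repeated_trials(flaky, seeds = 1:3), "failed")
  expect_equal(nrow(t3$trials), 2)
})

test_that("model comparison reproduces the closed-form t statistic", {
  a <- c(0.151, 0.148, 0.155, 0.150, 0.149)
  b <- c(0.176, 0.180, 0.172, 0.178, 0.175)
  res <- compare_models(a, b)
  # Welch formula by hand
  tw <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
  expect_equal(res$t_value, tw, tolerance = 1e-10)
  expect_true(res$significant)
  expect_equal(res$shapiro_p_a, shapiro.test(a)$p.value)

  pooled <- compare_models(a, b, var_equal = TRUE)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  tp <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 5))
  expect_equal(pooled$t_value, tp, tolerance = 1e-10)

  set.seed(20)
  same <- rnorm(10)
  eq <- compare_models(same, same)
  expect_equal(eq$t_value, 0)
  expect_equal(eq$p_value, 1)
  expect_false(eq$significant)

  sep <- compare_models(c(0, 0, 0, 0) + rnorm(4, sd = 1e-4),
                        c(1, 1, 1, 1) + rnorm(4, sd = 1e-4))
  expect_lt(sep$p_value, 0.05)

  expect_error(compare_models(1:2, 1:5), ">= 3")
})

test_that("robustness suite: zero-magnitude perturbations reproduce the
           clean evaluation", {
  g <- tiny_recording(n_cycles = 5, n_imus = 1)
  cyc <- preprocess_recording(g$recording, g$events)
  sp <- wavelet_spec(n_scales = 3)
  stats <- channel_stats(list(cyc))
  ds <- build_feature_dataset(list(cyc), list(g$torque), sp,
                              stats = stats)
  set.seed(21)
  cfg <- model_config(in_channels = dim(ds$x)[1],
                      in_length = dim(ds$x)[2],
                      input_layout = "channels_time",
                      stem_filters = c(4L, 8L), res_filters = c(4L, 8L),
                      fc_sizes = c(16L, 8L), lstm_hidden = 4L,
                      attn_window = 5L)
  model <- build_hybrid(cfg)
  recs <- list(list(recording = g$recording, events = g$events,
                    torque = g$torque))
  zero_specs <- list(
    gaussian = noise_spec("gaussian", gaussian_std = 0),
    offset = noise_spec("offset", offset_value = 0),
    rotation = noise_spec("rotation", rotation_deg = 0))
  tab <- robustness_suite(model, recs, sp, stats,
                          noise_specs = zero_specs)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$condition,
               c("clean", "gaussian", "offset", "rotation"))
  for (r in 2:4) {
    expect_equal(tab$rmse[r], tab$rmse[1], tolerance = 1e-12)
    expect_equal(tab$r2[r], tab$r2[1], tolerance = 1e-12)
  }
})
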