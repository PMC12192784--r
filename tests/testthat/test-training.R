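test_that("stratified split hits the 70/10/20 fractions and is a seeded
           disjoint cover", {
  meta <- tibble::tibble(window = 1:100, recording = 1:100,
                         activity = "walk")
  sp <- split_windows(meta, unit = "window", seed = 3)
  expect_equal(as.vector(table(sp$split)), c(70, 10, 20))
  expect_identical(split_windows(meta, unit = "window", seed = 3)$split,
                   sp$split)
  expect_false(identical(
    split_windows(meta, unit = "window", seed = 4)$split, sp$split))
  expect_false(anyNA(sp$split))

  # recording unit keeps whole recordings together
  meta2 <- tibble::tibble(window = 1:60,
                          recording = rep(1:10, each = 6),
                          activity = rep(c("walk", "ramp"), each = 30))
  sp2 <- split_windows(meta2, unit = "recording", seed = 1)
  per_rec <- tapply(as.character(sp2$split), sp2$recording,
                    function(v) length(unique(v)))
  expect_true(all(per_rec == 1))

  expect_error(split_windows(tibble::tibble(window = 1:2,
                                            recording = 1:2,
                                            activity = "a"),
                             unit = "window"), "fewer than 3")
})

test_that("Adam step reproduces the hand-unrolled recurrence", {
  st <- adam_step(0, 1, NULL, lr = 1e-4)
  expect_equal(st$state$m, 0.1)
  expect_equal(st$state$v, 0.001)
  # bias-corrected mhat = 1, vhat = 1 -> theta = -lr/(1 + 1e-8)
  expect_equal(st$param, -1e-4 / (1 + 1e-8), tolerance = 1e-12)

  # zero gradient from zero state leaves parameters unchanged
  z <- adam_step(c(1, -2), c(0, 0), NULL, lr = 0.1)
  expect_equal(z$param, c(1, -2))

  # first step moves opposite the gradient sign
  s1 <- adam_step(c(0, 0, 0), c(3, -0.5, 1e-3), NULL, lr = 0.01)
  expect_equal(sign(s1$param - 0), -sign(c(3, -0.5, 1e-3)))

  # 10-step randomized scalar problems against an independent recurrence
  set.seed(14)
  for (rep in 1:5) {
    g <- rnorm(10)
    lr <- 10^runif(1, -4, -1)
    theta <- 0.5; m <- 0; v <- 0
    st <- NULL; param <- 0.5
    for (t in 1:10) {
      m <- 0.9 * m + 0.1 * g[t]
      v <- 0.999 * v + 0.001 * g[t]^2
      theta <- theta - lr * (m / (1 - 0.9^t)) /
        (sqrt(v / (1 - 0.999^t)) + 1e-8)
      st <- adam_step(param, g[t], st$state, lr = lr)
      param <- st$param
      st <- list(state = st$state)
    }
    expect_equal(param, theta, tolerance = 1e-12)
  }
})

test_that("plateau schedule reduces by 0.1 after stagnation, floors at
           1e-6, and leaves improving runs untouched", {
  # epoch 2 improves; epochs 3-7 are the five stagnant epochs
  lrs <- lr_schedule(c(1, 0.99, 0.99, 0.99, 0.99, 0.99, 0.99),
                     lr0 = 1e-4)
  expect_equal(lrs, c(rep(1e-4, 6), 1e-5))

  expect_equal(lr_schedule(seq(1, 0.1, length.out = 8), lr0 = 1e-4),
               rep(1e-4, 8))

  long <- lr_schedule(c(1, rep(1, 30)), lr0 = 1e-4)
  expect_equal(min(long), 1e-6)
  expect_true(all(diff(long) <= 0))
  expect_error(lr_schedule(numeric(0)), "empty")
})

test_that("weight decay shrinks parameter norms under zero data
           gradient", {
  set.seed(15)
  p <- rnorm(20)
  st <- NULL
  lambda <- 0.001
  norms <- numeric(6)
  norms[1] <- sqrt(sum(p^2))
  for (t in 1:5) {
    g <- lambda * p  # pure L2 gradient
    st <- adam_step(p, g, st$state, lr = 1e-3)
    p <- st$param
    st <- list(state = st$state)
    norms[t + 1] <- sqrt(sum(p^2))
  }
  expect_true(all(diff(norms) < 0))
})

test_that("training reduces the loss, records history and is seeded", {
  set.seed(16)
  N <- 24
  x <- array(rnorm(4 * 16 * N), dim = c(4, 16, N))
  cfg <- model_config(in_channels = 4L, in_length = 16L,
                      input_layout = "channels_time",
                      stem_filters = c(4L, 8L), res_filters = c(4L, 8L),
                      fc_sizes = c(16L, 8L), lstm_hidden = 4L,
                      attn_window = 5L, n_joints = 2L, out_points = 5L)
  # target depends linearly on a channel mean so it is learnable
  y <- array(0, dim = c(2, 5, N))
  for (i in seq_len(N)) y[, , i] <- mean(x[1, , i])
  tc <- train_config(batch_size = 8L, max_epochs = 5L, seed = 1L,
                     lr0 = 3e-3)
  set.seed(1)
  m1 <- build_hybrid(cfg)
  fit1 <- train_model(m1, x, y, config = tc)
  expect_equal(nrow(fit1$history), 5)
  expect_lt(fit1$history$train_loss[5], fit1$history$train_loss[1])
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr",
                    "reduced") %in% names(fit1$history)))

  set.seed(1)
  m2 <- build_hybrid(cfg)
  fit2 <- train_model(m2, x, y, config = tc)
  expect_equal(fit1$history$train_loss, fit2$history$train_loss,
               tolerance = 1e-6)

  # non-finite targets abort with a diagnostic
  yn <- y; yn[1] <- NaN
  set.seed(1)
  m3 <- build_hybrid(cfg)
  expect_error(train_model(m3, x, yn, config = tc), "non-finite")
})
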