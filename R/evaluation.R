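#' Regression metrics for torque trajectories
#'
#' Computed exactly as defined for the evaluation protocol:
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`;
#' `RMSE = sqrt(mean((yhat - y)^2))`; `MAE = mean(|yhat - y|)`;
#' `PCC = sum((x - xbar)(y - ybar)) / ((n-1) * sd_x * sd_y)` with sample
#' (n-1) standard deviations. Inputs are pooled over all supplied
#' samples; use [metrics_by_joint()] for the per-joint breakdown.
#'
#' @param y_true,y_pred Numeric vectors (or arrays, flattened) of equal
#'   length, `n >= 2`.
#' @return One-row tibble: `rmse`, `r2`, `mae`, `pcc`, `n`. If either
#'   series is constant the PCC is undefined and returned as `NA` (the
#'   other metrics are still computed).
#' @export
torque_metrics <- function(y_true, y_pred) {
  y <- as.numeric(y_true)
  x <- as.numeric(y_pred)
  if (length(y) != length(x)) stop("length mismatch")
  n <- length(y)
  if (n < 2) stop("need at least 2 samples")
  err <- x - y
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  ss_res <- sum(err^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  pcc <- if (sx == 0 || sy == 0) {
    NA_real_
  } else {
    sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  }
  tibble::tibble(rmse = rmse, r2 = r2, mae = mae, pcc = pcc, n = n)
}

#' Per-joint metric breakdown
#'
#' @param y_true,y_pred Arrays `[J x P x N]` (or `[J x P]`).
#' @param joints Joint labels.
#' @return Tibble with one row per joint plus a pooled `"all"` row.
#' @export
metrics_by_joint <- function(y_true, y_pred,
                             joints = c("hip", "knee", "ankle")) {
  if (length(dim(y_true)) == 2) {
    dim(y_true) <- c(dim(y_true), 1L)
    dim(y_pred) <- c(dim(y_pred), 1L)
  }
  J <- dim(y_true)[1]
  per <- purrr::map(seq_len(J), function(j) {
    dplyr::mutate(torque_metrics(y_true[j, , ], y_pred[j, , ]),
                  joint = joints[j], .before = 1)
  })
  all <- dplyr::mutate(torque_metrics(y_true, y_pred), joint = "all",
                       .before = 1)
  dplyr::bind_rows(c(per, list(all)))
}

#' Repeat a stochastic train/evaluate pipeline over seeds
#'
#' Runs `pipeline(seed)` for each seed; each run must return a one-row
#' data frame of metrics. Aborted runs are recorded and the summary is
#' computed over completed runs (with a warning).
#'
#' @param pipeline Function of one argument (the seed).
#' @param seeds Distinct integer seeds (default 20 trials).
#' @param n_trials Used when `seeds` is not supplied.
#' @return A `trial_summary`: list with `trials` (per-seed tibble),
#'   `summary` (mean, sd and `"mean ± sd"` string per metric).
#' @export
repeated_trials <- function(pipeline, seeds = NULL, n_trials = 20L) {
  if (is.null(seeds)) seeds <- seq_len(n_trials)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  rows <- list()
  failures <- integer(0)
  for (s in seeds) {
    res <- tryCatch(pipeline(s), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, s)
      next
    }
    rows[[length(rows) + 1L]] <- dplyr::mutate(tibble::as_tibble(res),
                                               seed = s, .before = 1)
  }
  if (length(failures) > 0) {
    warning("trials failed for seeds: ", paste(failures, collapse = ", "))
  }
  trials <- dplyr::bind_rows(rows)
  num_cols <- setdiff(names(trials)[vapply(trials, is.numeric, TRUE)],
                      "seed")
  summary <- dplyr::bind_rows(lapply(num_cols, function(cl) {
    v <- trials[[cl]]
    tibble::tibble(metric = cl, mean = mean(v), sd = stats::sd(v),
                   formatted = sprintf("%.3f ± %.3f", mean(v),
                                       stats::sd(v)))
  }))
  structure(list(trials = trials, summary = summary,
                 n_failed = length(failures)),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("<trial_summary> ", nrow(x$trials), " completed trials\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Compare two models' per-trial metrics
#'
#' Shapiro-Wilk normality check on each group, then a two-sided
#' independent-samples t-test (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance test).
#'
#' @param metric_samples_a,metric_samples_b Numeric vectors (>= 3 each).
#' @param alpha Significance level.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return One-row tibble: `t_value`, `p_value`, `shapiro_p_a`,
#'   `shapiro_p_b`, `normal_ok`, `alpha`, `significant`.
#' @export
compare_models <- function(metric_samples_a, metric_samples_b,
                           alpha = 0.05, var_equal = FALSE) {
  a <- as.numeric(metric_samples_a)
  b <- as.numeric(metric_samples_b)
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 samples per group")
  sw_a <- if (stats::sd(a) == 0) NA_real_ else stats::shapiro.test(a)$p.value
  sw_b <- if (stats::sd(b) == 0) NA_real_ else stats::shapiro.test(b)$p.value
  tt <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(
    t_value = unname(tt$statistic), p_value = tt$p.value,
    shapiro_p_a = sw_a, shapiro_p_b = sw_b,
    normal_ok = isTRUE(sw_a > alpha) && isTRUE(sw_b > alpha),
    alpha = alpha, significant = tt$p.value < alpha
  )
}

#' Module-ablation comparison
#'
#' Trains the full model and each single-module-removed variant under
#' identical data, splits and seeds, and reports validation MSE and
#' held-out test metrics per (variant, seed).
#'
#' @param data Featurized dataset list (`x`, `y`, `meta` with `split`),
#'   plus a parallel `data_raw` with the `"raw"`-method features for the
#'   `no_cwt` variant.
#' @param variants Character vector of variants to run.
#' @param seeds Integer seeds (weights/batches re-seeded per run; the
#'   split is fixed).
#' @param base_config A [model_config()] for the featurized input; the
#'   `no_cwt` variant adapts `in_channels` to the raw input.
#' @param train_cfg A [train_config()]; its `seed` is replaced per run.
#' @param data_raw Raw-window dataset for `no_cwt` (same meta/split).
#' @return Tibble: variant, seed, val_mse, test rmse/r2/mae/pcc.
#' @export
ablation_suite <- function(data, base_config, train_cfg,
                           variants = c("full", "no_cwt", "no_resnet",
                                        "no_mhsa", "lstm_only",
                                        "no_bilstm"),
                           seeds = 1:3, data_raw = NULL) {
  stopifnot(!is.null(data$meta$split))
  if ("no_cwt" %in% variants && is.null(data_raw)) {
    stop("no_cwt variant requires data_raw")
  }
  idx <- split(seq_len(nrow(data$meta)), data$meta$split)
  rows <- list()
  for (v in variants) {
    ds <- if (v == "no_cwt") data_raw else data
    cfg <- base_config
    cfg$variant <- v
    cfg$in_channels <- dim(ds$x)[1]
    cfg$in_length <- dim(ds$x)[2]
    for (s in seeds) {
      set.seed(s)
      model <- build_hybrid(cfg)
      tc <- train_cfg
      tc$seed <- s
      fit <- train_model(model,
                         ds$x[, , idx$train, drop = FALSE],
                         ds$y[, , idx$train, drop = FALSE],
                         ds$x[, , idx$val, drop = FALSE],
                         ds$y[, , idx$val, drop = FALSE], tc)
      pred <- predict_torque_batched(fit$model,
                                     ds$x[, , idx$test, drop = FALSE])
      m <- torque_metrics(ds$y[, , idx$test, drop = FALSE], pred)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        m, variant = v, seed = s,
        val_mse = utils::tail(fit$history$val_loss, 1), .before = 1)
    }
  }
  dplyr::bind_rows(rows)
}

#' Robustness of a trained model to sensor perturbations
#'
#' Evaluates the model on the clean test recordings and on copies
#' perturbed at the raw-recording stage (before preprocessing) by each
#' supplied [noise_spec()]: Gaussian noise (sd 0.05), constant offset
#' (0.1) and 5-degree sensor misalignment by default.
#'
#' @param model Trained `torque_net`.
#' @param test_recordings List of `list(recording, events, torque)` for
#'   the held-out recordings.
#' @param spec A [wavelet_spec()] matching the training featurization.
#' @param stats Channel statistics used at training time
#'   ([channel_stats()]).
#' @param noise_specs Named list of [noise_spec()] perturbations.
#' @param fspec A [filter_spec()].
#' @param method,layout Featurization method/layout used in training.
#' @param feature_norm Optional [feature_stats()] used at training time.
#' @return Tibble with one row per condition (clean first).
#' @export
robustness_suite <- function(model, test_recordings, spec, stats,
                             noise_specs = list(
                               gaussian = noise_spec("gaussian"),
                               offset = noise_spec("offset"),
                               rotation = noise_spec("rotation")),
                             fspec = filter_spec(),
                             method = "cwt", layout = "channels_time",
                             feature_norm = NULL) {
  conditions <- c(list(clean = NULL), noise_specs)
  rows <- list()
  for (nm in names(conditions)) {
    cycles_list <- list()
    torque_list <- list()
    for (tr in test_recordings) {
      rec <- tr$recording
      if (!is.null(conditions[[nm]])) {
        rec <- inject_noise(rec, conditions[[nm]])
      }
      cycles_list[[length(cycles_list) + 1L]] <-
        preprocess_recording(rec, tr$events, fspec)
      torque_list[[length(torque_list) + 1L]] <- tr$torque
    }
    ds <- build_feature_dataset(cycles_list, torque_list, spec,
                                method = method, layout = layout,
                                stats = stats)
    if (!is.null(feature_norm)) {
      ds$x <- apply_feature_stats(ds$x, feature_norm)
    }
    pred <- predict_torque_batched(model, ds$x)
    rows[[length(rows) + 1L]] <-
      dplyr::mutate(torque_metrics(ds$y, pred), condition = nm,
                    .before = 1)
  }
  dplyr::bind_rows(rows)
}
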