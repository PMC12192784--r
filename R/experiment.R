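#' Generate and featurize a complete synthetic study dataset
#'
#' Generates `n_recordings` synthetic recordings, preprocesses each into
#' 101-point gait cycles, assembles three-cycle scalogram windows (or a
#' comparator featurization), and splits them 70/10/20 with whole
#' recordings kept in one split. Channel statistics for standardization
#' are computed from the training recordings only.
#'
#' @param n_recordings Number of recordings.
#' @param cycles_per_recording Gait cycles per recording.
#' @param n_imus IMUs per recording.
#' @param n_scales Scales `m` of the wavelet grid.
#' @param method Featurization: `"cwt"`, `"stft"`, `"dwt"`, `"raw"`.
#' @param layout `"channels_time"` or `"flat"`.
#' @param seed Master seed (recording seeds and the split derive from
#'   it).
#' @param synth_overrides Named list of [synth_config()] overrides.
#' @return List: `x`, `y`, `meta` (with `split`), `stats`, `spec`
#'   ([wavelet_spec()]), `recordings` (raw per-recording list),
#'   `split_idx` (list of index vectors).
#' @export
synth_study <- function(n_recordings = 10L, cycles_per_recording = 30L,
                        n_imus = 4L, n_scales = 8L,
                        method = "cwt", layout = "channels_time",
                        seed = 1L, synth_overrides = list()) {
  recordings <- purrr::map(seq_len(n_recordings), function(r) {
    args <- utils::modifyList(
      list(n_imus = n_imus, n_cycles = cycles_per_recording,
           seed = seed * 1000L + r),
      synth_overrides)
    gen <- generate_recording(do.call(synth_config, args))
    list(recording = gen$recording, events = gen$events,
         torque = gen$torque)
  })
  cycles_list <- purrr::map(recordings, function(tr) {
    preprocess_recording(tr$recording, tr$events)
  })
  torque_list <- purrr::map(recordings, "torque")

  cd <- recordings[[1]]$recording
  cyc_dur <- (recordings[[1]]$events[2] - recordings[[1]]$events[1]) /
    attr(cd, "sampling_rate")
  spec <- wavelet_spec(n_scales = n_scales,
                       sampling_rate = 101 / cyc_dur)

  # provisional split at recording level to compute train-only stats
  meta0 <- tibble::tibble(
    window = seq_len(n_recordings), recording = seq_len(n_recordings),
    activity = vapply(recordings,
                      function(tr) attr(tr$recording, "activity_label"),
                      "")
  )
  rec_split <- split_windows(meta0, unit = "recording", seed = seed)
  train_recs <- rec_split$recording[rec_split$split == "train"]
  stats <- channel_stats(cycles_list[train_recs])

  ds <- build_feature_dataset(cycles_list, torque_list, spec,
                              method = method, layout = layout,
                              stats = stats)
  ds$meta$split <- rec_split$split[match(ds$meta$recording,
                                         rec_split$recording)]
  split_idx <- split(seq_len(nrow(ds$meta)), ds$meta$split)
  fstats <- feature_stats(ds$x, split_idx$train)
  list(x = apply_feature_stats(ds$x, fstats), y = ds$y, meta = ds$meta,
       stats = stats, feature_norm = fstats, spec = spec,
       recordings = recordings, split_idx = split_idx)
}

#' Fit the hybrid model (or a variant) on a synthetic study dataset
#'
#' @param data Output of [synth_study()].
#' @param epochs Training epochs.
#' @param variant Model variant (see [model_config()]).
#' @param seed Seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @param train_overrides Named list of [train_config()] overrides.
#' @return A `torque_fit`: list with `model`, `history`, `config`,
#'   `train_cfg`, `data_ref` (split sizes), `test_metrics` (tibble).
#' @export
fit_torque_model <- function(data, epochs = 30L, variant = "full",
                             seed = 1L, verbose = FALSE,
                             train_overrides = list()) {
  idx <- data$split_idx
  cfg <- model_config(in_channels = dim(data$x)[1],
                      in_length = dim(data$x)[2],
                      input_layout = "channels_time", variant = variant)
  set.seed(seed)
  model <- build_hybrid(cfg)
  tc <- do.call(train_config,
                utils::modifyList(list(max_epochs = epochs, seed = seed,
                                       verbose = verbose),
                                  train_overrides))
  fit <- train_model(model, data$x[, , idx$train, drop = FALSE],
                     data$y[, , idx$train, drop = FALSE],
                     data$x[, , idx$val, drop = FALSE],
                     data$y[, , idx$val, drop = FALSE], tc)
  pred <- predict_torque_batched(fit$model,
                                 data$x[, , idx$test, drop = FALSE])
  tm <- metrics_by_joint(data$y[, , idx$test, drop = FALSE], pred)
  structure(
    list(model = fit$model, history = fit$history, config = cfg,
         train_cfg = tc,
         data_ref = vapply(idx, length, 0L),
         test_metrics = tm),
    class = "torque_fit"
  )
}

#' @export
print.torque_fit <- function(x, ...) {
  cat("<torque_fit> variant '", x$config$variant, "', ",
      nrow(x$history), " epochs\n", sep = "")
  print(x$test_metrics)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted torque model
#' @param x A `torque_fit`.
#' @param ... Unused.
#' @return Tibble: epoch, train_loss, val_loss, lr, reduced.
#' @export
tidy.torque_fit <- function(x, ...) x$history

#' One-row summary of a fitted torque model
#' @param x A `torque_fit`.
#' @param ... Unused.
#' @return One-row tibble with pooled held-out metrics and run facts.
#' @export
glance.torque_fit <- function(x, ...) {
  pooled <- dplyr::filter(x$test_metrics, .data$joint == "all")
  tibble::tibble(
    variant = x$config$variant, epochs = nrow(x$history),
    n_parameters = n_parameters(x$model),
    final_train_loss = utils::tail(x$history$train_loss, 1),
    final_val_loss = utils::tail(x$history$val_loss, 1),
    test_rmse = pooled$rmse, test_r2 = pooled$r2,
    test_mae = pooled$mae, test_pcc = pooled$pcc
  )
}

#' Per-trial metrics of a trial summary
#' @param x A `trial_summary`.
#' @param ... Unused.
#' @export
tidy.trial_summary <- function(x, ...) x$trials

#' Aggregated mean/sd per metric of a trial summary
#' @param x A `trial_summary`.
#' @param ... Unused.
#' @export
glance.trial_summary <- function(x, ...) {
  wide <- x$summary
  out <- tibble::as_tibble(as.list(stats::setNames(wide$mean,
                                                   wide$metric)))
  out$n_trials <- nrow(x$trials)
  out
}

#' Plot the training history of a fit
#' @param object A `torque_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.torque_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE loss", color = NULL,
                  title = paste0("Training history (",
                                 object$config$variant, ")")) +
    ggplot2::theme_minimal()
}

#' Plot predicted vs. actual torque trajectories for one window
#'
#' @param y_true,y_pred Matrices `[n_joints x 101]`.
#' @param joints Joint labels.
#' @return A ggplot with one facet per joint.
#' @export
plot_torque_prediction <- function(y_true, y_pred,
                                   joints = c("hip", "knee", "ankle")) {
  phase <- seq(0, 100, length.out = ncol(y_true))
  df <- dplyr::bind_rows(lapply(seq_len(nrow(y_true)), function(j) {
    tibble::tibble(joint = joints[j], phase = phase,
                   actual = y_true[j, ], predicted = y_pred[j, ])
  }))
  df <- tidyr::pivot_longer(df, c("actual", "predicted"),
                            names_to = "series", values_to = "torque")
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$torque,
                                   color = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = "gait cycle (%)", y = "torque (N·m/kg)",
                  color = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a scalogram (one channel of a stack)
#'
#' @param stack A `scalogram_stack`.
#' @param channel Channel index.
#' @return A ggplot raster of |W(a, b)| over time and frequency.
#' @export
plot_scalogram <- function(stack, channel = 1L) {
  scales <- attr(stack, "scale_values")
  freqs <- attr(scales, "frequencies")
  d <- dim(stack)
  df <- expand.grid(scale = seq_len(d[2]), time = seq_len(d[3]))
  df$value <- as.vector(unclass(stack)[channel, , ])
  df$frequency <- freqs[df$scale] %||% df$scale
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample", y = "frequency (Hz)",
                  fill = "|W|") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
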