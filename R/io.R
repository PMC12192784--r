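# Text-based I/O: recordings as CSV + JSON sidecar, torque traces and
# cycle sets as CSV, run configs as JSON. CSV dialect: comma-separated,
# UTF-8, '.' decimal, mandatory header, NaN spelled "nan"; numbers at
# 17 significant digits so round trips preserve doubles exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v) && !is.nan(v)) return("na")
    if (is.nan(v)) return("nan")
    format(v, digits = 17, scientific = TRUE, trim = TRUE)
  }, "")
  out
}

write_num_csv <- function(df, path) {
  cols <- lapply(df, function(cl) {
    if (is.numeric(cl)) fmt_num(cl) else as.character(cl)
  })
  m <- do.call(cbind, cols)
  lines <- c(paste(names(df), collapse = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
}

read_num_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("nan", "na"))
  tibble::as_tibble(df)
}

#' Write a recording as CSV with a JSON metadata sidecar
#'
#' The CSV holds `time_s` plus one column per channel; the sidecar
#' (`<path>.json`) holds `sampling_rate`, `n_imus`, `subject_mass`,
#' `activity_label` and `heel_strikes`.
#'
#' @param rec An `imu_recording`.
#' @param events Heel-strike indices.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, events, path) {
  write_num_csv(rec, path)
  jsonlite::write_json(
    list(sampling_rate = attr(rec, "sampling_rate"),
         n_imus = attr(rec, "n_imus"),
         subject_mass = attr(rec, "subject_mass"),
         activity_label = attr(rec, "activity_label"),
         channel_labels = attr(rec, "channel_labels"),
         heel_strikes = as.integer(events)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return List with `recording` (`imu_recording`) and `events`.
#' @export
read_recording <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  need <- c("sampling_rate", "n_imus", "heel_strikes", "channel_labels")
  missing <- setdiff(need, names(side))
  if (length(missing) > 0) {
    stop("sidecar schema error; missing fields: ",
         paste(missing, collapse = ", "))
  }
  rec <- read_num_csv(path)
  want <- c("time_s", side$channel_labels)
  absent <- setdiff(want, names(rec))
  if (length(absent) > 0) {
    stop("CSV schema error; missing columns: ",
         paste(absent, collapse = ", "))
  }
  if (length(side$channel_labels) != 6 * side$n_imus) {
    stop("channel count mismatch: sidecar declares ", side$n_imus,
         " IMU(s) but lists ", length(side$channel_labels), " channels")
  }
  attr(rec, "sampling_rate") <- side$sampling_rate
  attr(rec, "subject_mass") <- side$subject_mass
  attr(rec, "n_imus") <- as.integer(side$n_imus)
  attr(rec, "channel_labels") <- side$channel_labels
  attr(rec, "activity_label") <- side$activity_label
  class(rec) <- c("imu_recording", class(rec))
  list(recording = rec, events = as.integer(side$heel_strikes))
}

#' Write a torque trace as CSV (cycle, joint, 101 phase columns)
#' @param torque `torque_trace` array `[n_cycles x n_joints x 101]`.
#' @param path CSV path.
#' @export
write_torque <- function(torque, path) {
  d <- dim(torque)
  joints <- dimnames(torque)[[2]] %||% paste0("joint", seq_len(d[2]))
  rows <- list()
  for (c in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      vals <- as.list(unclass(torque)[c, j, ])
      names(vals) <- paste0("p", 0:(d[3] - 1))
      rows[[length(rows) + 1L]] <- tibble::as_tibble(
        c(list(cycle = c, joint = joints[j]), vals))
    }
  }
  write_num_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Read a torque trace written by [write_torque()]
#' @param path CSV path.
#' @return `torque_trace` array.
#' @export
read_torque <- function(path) {
  df <- read_num_csv(path)
  joints <- unique(df$joint)
  n_cycles <- max(df$cycle)
  pcols <- grep("^p[0-9]+$", names(df), value = TRUE)
  out <- array(0, dim = c(n_cycles, length(joints), length(pcols)),
               dimnames = list(NULL, joints, NULL))
  for (r in seq_len(nrow(df))) {
    out[df$cycle[r], df$joint[r], ] <- as.numeric(df[r, pcols])
  }
  class(out) <- "torque_trace"
  out
}

#' Write preprocessed gait cycles as long CSV
#' @param cycles A `gait_cycles`.
#' @param path CSV path (screening report goes to `<path>.report.json`).
#' @export
write_cycles <- function(cycles, path) {
  d <- dim(cycles$data)
  rows <- vector("list", d[1] * d[2])
  k <- 0L
  for (c in seq_len(d[1])) for (j in seq_len(d[2])) {
    k <- k + 1L
    vals <- as.list(cycles$data[c, j, ])
    names(vals) <- paste0("p", 0:(d[3] - 1))
    rows[[k]] <- tibble::as_tibble(
      c(list(cycle = c, channel = cycles$channel_labels[j],
             activity = cycles$activity), vals))
  }
  write_num_csv(dplyr::bind_rows(rows), path)
  jsonlite::write_json(as.list(cycles$report),
                       paste0(path, ".report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read gait cycles written by [write_cycles()]
#' @param path CSV path.
#' @return A `gait_cycles`.
#' @export
read_cycles <- function(path) {
  df <- read_num_csv(path)
  channels <- unique(df$channel)
  n_cycles <- max(df$cycle)
  pcols <- grep("^p[0-9]+$", names(df), value = TRUE)
  data <- array(0, dim = c(n_cycles, length(channels), length(pcols)),
                dimnames = list(NULL, channels, NULL))
  for (r in seq_len(nrow(df))) {
    data[df$cycle[r], df$channel[r], ] <- as.numeric(df[r, pcols])
  }
  rep_path <- paste0(path, ".report.json")
  report <- if (file.exists(rep_path)) {
    tibble::as_tibble(jsonlite::read_json(rep_path,
                                          simplifyVector = TRUE))
  } else {
    tibble::tibble()
  }
  structure(list(data = data, channel_labels = channels,
                 activity = df$activity[1], report = report),
            class = "gait_cycles")
}

#' Serialize a nested run configuration to JSON (lossless round trip)
#' @param config Named list (possibly nested).
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path JSON path.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
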