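#' Construct an ankle-IMU recording
#'
#' An `imu_recording` is a tibble with one row per sample and columns
#' `t` (seconds), `acc_x`, `acc_y`, `acc_z` (acceleration, g) and
#' `gyr_x`, `gyr_y`, `gyr_z` (angular velocity, deg/s), carrying the
#' sampling rate and subject/trial identifiers as attributes. Timestamps
#' must be uniform at `1/fs` (tolerance 1e-6 s).
#'
#' @param data data frame with columns `t, acc_x, acc_y, acc_z, gyr_x,
#'   gyr_y, gyr_z`.
#' @param fs sampling rate in Hz. Default 50, the rate of the ankle-worn
#'   device the pipeline targets. If `NULL`, inferred from the median
#'   timestamp step.
#' @param subject_id,trial_id opaque identifier strings.
#' @return a validated `imu_recording` tibble.
#' @export
imu_recording <- function(data, fs = 50, subject_id = "S01", trial_id = "T01") {
  cols <- imu_channels()
  missing <- setdiff(c("t", cols), names(data))
  if (length(missing) > 0) {
    abort(paste0("IMU data is missing column(s): ", paste(missing, collapse = ", ")),
          class = "sitseg_format_error")
  }
  out <- as_tibble(data)[, c("t", cols)]
  if (is.null(fs)) {
    dt <- median(diff(out$t))
    fs <- 1 / dt
  }
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- subject_id
  attr(out, "trial_id") <- trial_id
  class(out) <- c("imu_recording", class(out))
  validate_imu(out)
}

imu_channels <- function() {
  c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
}

#' @rdname imu_recording
#' @param rec an `imu_recording`.
#' @export
validate_imu <- function(rec) {
  fs <- imu_fs(rec)
  if (!is.numeric(fs) || fs <= 0) {
    abort("Sampling rate fs must be > 0.", class = "sitseg_format_error")
  }
  if (nrow(rec) < 1) {
    abort("IMU recording must contain at least one sample.",
          class = "sitseg_format_error")
  }
  if (nrow(rec) > 1) {
    step <- diff(rec$t)
    if (any(step <= 0) || any(abs(step - 1 / fs) > 1e-6)) {
      abort(paste0("Timestamps must be strictly increasing with constant step 1/fs (",
                   signif(1 / fs, 6), " s, tolerance 1e-6 s)."),
            class = "sitseg_integrity_error")
    }
  }
  rec
}

#' @rdname imu_recording
#' @export
imu_fs <- function(rec) attr(rec, "fs")

#' Read and write IMU recordings as CSV
#'
#' The on-disk dialect is comma-separated with one header line and columns
#' `t,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z`, time in seconds first. Units
#' default to g and deg/s; recordings exported in m/s^2 or rad/s are
#' converted on read via the unit declarations.
#'
#' @param path file path.
#' @param fs sampling rate in Hz; if `NULL`, inferred from timestamps.
#' @param acc_unit `"g"` or `"m/s2"`.
#' @param gyr_unit `"deg/s"` or `"rad/s"`.
#' @param subject_id,trial_id identifiers attached to the recording.
#' @return `read_imu()` returns an [imu_recording]; `write_imu()` returns
#'   `path` invisibly.
#' @export
read_imu <- function(path, fs = NULL, acc_unit = c("g", "m/s2"),
                     gyr_unit = c("deg/s", "rad/s"),
                     subject_id = "S01", trial_id = "T01") {
  acc_unit <- match.arg(acc_unit)
  gyr_unit <- match.arg(gyr_unit)
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "sitseg_file_error")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("t", imu_channels()), names(dat))
  if (length(missing) > 0) {
    abort(paste0("IMU file ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "sitseg_format_error")
  }
  acc_cols <- c("acc_x", "acc_y", "acc_z")
  gyr_cols <- c("gyr_x", "gyr_y", "gyr_z")
  if (acc_unit == "m/s2") dat[acc_cols] <- dat[acc_cols] / 9.80665
  if (gyr_unit == "rad/s") dat[gyr_cols] <- dat[gyr_cols] * 180 / pi
  imu_recording(dat, fs = fs, subject_id = subject_id, trial_id = trial_id)
}

#' @rdname read_imu
#' @param rec an [imu_recording].
#' @export
write_imu <- function(rec, path) {
  readr::write_csv(as_tibble(rec)[, c("t", imu_channels())], path, progress = FALSE)
  invisible(path)
}

activity_labels <- function() c("SIT", "TRANSITION", "WALKING")

#' Construct an activity-interval track
#'
#' A `label_track` holds ground-truth or predicted activity intervals as a
#' tibble with columns `start_s`, `end_s`, `label`, half-open
#' `[start_s, end_s)` in seconds, with the trial duration as an attribute.
#' Labels are restricted to `SIT`, `TRANSITION` and `WALKING`; any other
#' activity in a recording is implicit background. On construction,
#' same-label overlapping or abutting intervals are merged and rows sorted
#' by start (canonical form).
#'
#' @param intervals data frame with columns `start_s`, `end_s`, `label`
#'   (may have zero rows).
#' @param duration_s trial duration in seconds.
#' @return a canonical `label_track` tibble.
#' @export
label_track <- function(intervals, duration_s) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    out <- tibble(start_s = double(), end_s = double(), label = character())
  } else {
    bad <- setdiff(unique(intervals$label), activity_labels())
    if (length(bad) > 0) {
      abort(paste0("Unknown activity label(s): ", paste(bad, collapse = ", "),
                   " (expected SIT, TRANSITION or WALKING)"),
            class = "sitseg_format_error")
    }
    if (any(intervals$end_s <= intervals$start_s)) {
      abort("Every interval must satisfy start_s < end_s.",
            class = "sitseg_format_error")
    }
    if (any(intervals$start_s < 0) || any(intervals$end_s > duration_s + 1e-9)) {
      abort("Intervals must lie within [0, duration_s].",
            class = "sitseg_format_error")
    }
    out <- intervals |>
      as_tibble() |>
      group_by(.data$label) |>
      dplyr::group_modify(~canonicalize_intervals(.x)) |>
      ungroup() |>
      select("start_s", "end_s", "label") |>
      arrange(.data$start_s, .data$label)
  }
  attr(out, "duration_s") <- duration_s
  class(out) <- c("label_track", class(out))
  out
}

#' @rdname label_track
#' @param track a `label_track`.
#' @export
track_duration <- function(track) attr(track, "duration_s")

#' @rdname label_track
#' @param label one of `"SIT"`, `"TRANSITION"`, `"WALKING"`.
#' @export
track_intervals <- function(track, label) {
  as_intervals(track[track$label == label, , drop = FALSE])
}

#' Read and write activity-interval annotations
#'
#' Label CSVs have columns `start_s,end_s,label`. An empty file (header
#' only) yields an empty track.
#'
#' @param path file path.
#' @param duration_s trial duration in seconds; if `NULL`, the maximum
#'   interval end is used.
#' @return `read_labels()` returns a [label_track]; `write_labels()`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path, duration_s = NULL) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "sitseg_file_error")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           start_s = readr::col_double(),
                           end_s = readr::col_double(),
                           label = readr::col_character()))
  if (is.null(duration_s)) {
    duration_s <- if (nrow(dat) == 0) 0 else max(dat$end_s)
  }
  label_track(dat, duration_s = duration_s)
}

#' @rdname read_labels
#' @param track a [label_track].
#' @export
write_labels <- function(track, path) {
  readr::write_csv(as_tibble(track)[, c("start_s", "end_s", "label")], path,
                   progress = FALSE)
  invisible(path)
}

#' Complement of a label's intervals within the trial
#'
#' Returns the maximal intervals of `[0, duration)` not covered by the
#' given label. The main use is deriving no-Walking segments — the gating
#' context of the merge algorithm — as the complement of `WALKING`.
#'
#' @param track a [label_track].
#' @param label the label to complement.
#' @return tibble with columns `start_s`, `end_s` (pairwise disjoint; the
#'   union with the label's own intervals is `[0, duration)`).
#' @export
complement_intervals <- function(track, label = "WALKING") {
  complement_of(track_intervals(track, label), track_duration(track))
}
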