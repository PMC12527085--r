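#' Convert positive window predictions to a detection track
#'
#' Each positive window contributes its full span
#' `[start, start + length_s)`; overlapping or abutting spans are unioned.
#'
#' @param predictions integer 0/1 vector, one per window.
#' @param window_start_s window start times, seconds.
#' @param spec the [window_spec] used for prediction.
#' @return canonical tibble of intervals `start_s`, `end_s`.
#' @export
windows_to_intervals <- function(predictions, window_start_s, spec = window_spec()) {
  pos <- which(predictions == 1L)
  if (length(pos) == 0) return(empty_intervals())
  canonicalize_intervals(tibble(start_s = window_start_s[pos],
                                end_s = window_start_s[pos] + spec$length_s))
}

#' Concatenate detections separated by short gaps
#'
#' Consecutive intervals whose gap is strictly less than `gap_s` are
#' merged into one spanning interval; in the result every gap is at least
#' `gap_s`. The 1.5 s default is the empirically chosen bridging constant
#' of the merge algorithm.
#'
#' @param track tibble of intervals `start_s`, `end_s`.
#' @param gap_s gap threshold in seconds (strict "less than").
#' @return canonical tibble of intervals.
#' @export
concatenate_close <- function(track, gap_s = 1.5) {
  x <- canonicalize_intervals(track)
  if (nrow(x) <= 1) return(x)
  out_s <- x$start_s[1]
  out_e <- x$end_s[1]
  k <- 1
  for (i in 2:nrow(x)) {
    if (x$start_s[i] - out_e[k] < gap_s) {
      out_e[k] <- max(out_e[k], x$end_s[i])
    } else {
      k <- k + 1
      out_s[k] <- x$start_s[i]
      out_e[k] <- x$end_s[i]
    }
  }
  tibble(start_s = out_s, end_s = out_e)
}

#' Stand-in walking detector
#'
#' Marks WALKING wherever the windowed mean of the 4 Hz-filtered
#' gyroscope magnitude exceeds a threshold for a minimum duration, with
#' close gaps concatenated. This is a deliberately simple energy detector
#' standing in for a validated gait-detection algorithm: whenever
#' ground-truth or externally produced Walking labels are available,
#' prefer passing those through ([walking_from_labels()]), which is what
#' the pipeline does by default.
#'
#' @param processed a `processed_imu` tibble.
#' @param threshold_deg_s gyroscope-magnitude threshold in deg/s (default
#'   30; quiet standing and sitting sit well below, gait well above).
#' @param min_duration_s minimum walking-bout duration in seconds
#'   (default 2).
#' @param gap_s gap-bridging constant in seconds (default 1.5).
#' @param spec a [window_spec].
#' @return a [label_track] of WALKING intervals.
#' @export
detect_walking <- function(processed, threshold_deg_s = 30, min_duration_s = 2,
                           gap_s = 1.5, spec = window_spec()) {
  inform("detect_walking(): simple gyroscope-energy stand-in, not a validated gait detector; prefer provided Walking labels where available.")
  fs <- attr(processed, "fs")
  win <- window_indices(nrow(processed), spec, fs)
  g <- window_geometry(spec, fs)
  idx <- outer(seq_len(g$length_n), win$start_n, `+`)
  m <- colMeans(matrix(processed$gyr_filt_mag[idx], nrow = g$length_n))
  track <- windows_to_intervals(as.integer(m > threshold_deg_s), win$start_s, spec)
  track <- concatenate_close(track, gap_s)
  track <- track[track$end_s - track$start_s >= min_duration_s, , drop = FALSE]
  duration <- nrow(processed) / fs
  track <- clip_intervals(track, 0, duration)
  label_track(mutate(track, label = "WALKING"), duration_s = duration)
}

#' @rdname detect_walking
#' @param track a [label_track] with externally produced WALKING
#'   intervals; returned unchanged (pass-through mode).
#' @export
walking_from_labels <- function(track) {
  label_track(as_tibble(track)[track$label == "WALKING", , drop = FALSE],
              duration_s = track_duration(track))
}

# Assign each interval to the no-walking segment holding the majority of
# its duration (ties to the earlier segment). Returns the segment index,
# or NA when the majority of the interval lies outside every segment.
assign_to_segment <- function(intervals, segments) {
  if (nrow(intervals) == 0) return(integer())
  vapply(seq_len(nrow(intervals)), function(i) {
    a <- intervals$start_s[i]
    b <- intervals$end_s[i]
    ov <- pmax(pmin(b, segments$end_s) - pmax(a, segments$start_s), 0)
    if (length(ov) == 0 || max(ov) <= 0) return(NA_integer_)
    best <- which.max(ov)  # which.max takes the earliest on ties
    if (ov[best] < (b - a) / 2 - 1e-12) return(NA_integer_)
    as.integer(best)
  }, integer(1))
}

#' Merge Sit and Transition detections into final Sit phases
#'
#' The rule-based merge, gated by no-Walking segments, applied in fixed
#' order:
#' (a) detections of each track separated by less than `gap_s` are
#' concatenated; (b) Transition detections whose majority does not lie in
#' a no-Walking segment are discarded; (c) Sit detections (clipped to the
#' no-Walking segments) with no surviving Transition detection in the
#' same no-Walking segment are discarded; (d) surviving Sit detections in
#' the same no-Walking segment are concatenated, the emitted phase
#' spanning the earliest to the latest of them.
#'
#' @param sit_track,transition_track canonical interval tibbles
#'   (`start_s`, `end_s`) from the Sit and Transition classifiers.
#' @param no_walking tibble of disjoint no-Walking segments.
#' @param gap_s concatenation constant in seconds (default 1.5).
#' @return a `sit_phases` tibble: `start_s`, `end_s` of each final Sit
#'   phase, plus provenance columns `segment_start_s`, `segment_end_s`
#'   (its no-Walking segment), `n_sit` and `n_transition` (surviving
#'   detection counts in the segment).
#' @export
merge_sit_phases <- function(sit_track, transition_track, no_walking,
                             gap_s = 1.5) {
  segments <- canonicalize_intervals(no_walking)
  sit <- concatenate_close(sit_track, gap_s)          # rule (a)
  tra <- concatenate_close(transition_track, gap_s)   # rule (a)
  tra_seg <- assign_to_segment(tra, segments)
  tra_seg <- tra_seg[!is.na(tra_seg)]                 # rule (b)
  # clip Sit detections to no-Walking territory, then assign
  if (nrow(sit) > 0 && nrow(segments) > 0) {
    sit <- bind_rows(lapply(seq_len(nrow(segments)), function(s) {
      clip_intervals(sit, segments$start_s[s], segments$end_s[s])
    }))
    sit <- canonicalize_intervals(sit)
  } else {
    sit <- empty_intervals()
  }
  sit_seg <- assign_to_segment(sit, segments)
  keep <- !is.na(sit_seg) & sit_seg %in% tra_seg      # rule (c)
  sit <- sit[keep, , drop = FALSE]
  sit_seg <- sit_seg[keep]
  if (nrow(sit) == 0) {
    out <- tibble(start_s = double(), end_s = double(),
                  segment_start_s = double(), segment_end_s = double(),
                  n_sit = integer(), n_transition = integer())
  } else {
    out <- tibble(start_s = sit$start_s, end_s = sit$end_s, seg = sit_seg) |>
      group_by(.data$seg) |>
      summarise(start_s = min(.data$start_s), end_s = max(.data$end_s),
                n_sit = dplyr::n(), .groups = "drop") |>   # rule (d)
      mutate(segment_start_s = segments$start_s[.data$seg],
             segment_end_s = segments$end_s[.data$seg],
             n_transition = vapply(.data$seg, function(s)
               sum(tra_seg == s), integer(1))) |>
      arrange(.data$start_s) |>
      select("start_s", "end_s", "segment_start_s", "segment_end_s",
             "n_sit", "n_transition")
  }
  class(out) <- c("sit_phases", class(out))
  out
}
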