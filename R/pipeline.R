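#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the
#' published protocol where one exists: 1 s windows with 90% overlap,
#' 0.5 Hz (acceleration) and 4 Hz (gyroscope) low-pass cutoffs, 35
#' Transition and 25 Sit trees, 10 folds, 5 training repeats, 1.5 s merge
#' gap.
#'
#' @param window_length_s,window_overlap sliding-window geometry.
#' @param acc_cutoff_hz,gyr_cutoff_hz low-pass cutoffs, Hz.
#' @param n_trees_transition,n_trees_sit forest sizes.
#' @param k_folds cross-validation folds.
#' @param n_repeats training repeats per model (best-OOB kept).
#' @param merge_gap_s concatenation constant of the merge rules, s.
#' @param min_overlap window-labeling occupancy threshold.
#' @param normalization `"pooled"` (percentiles over all subjects and
#'   trials) or `"per_subject"`.
#' @param walking_mode `"labels"` (pass provided Walking labels through;
#'   default) or `"detector"` (gyroscope-energy stand-in).
#' @param grouping CV fold grouping, `"subject"` or `"window"`.
#' @param n_subjects,trial_durations_s synthetic-cohort shape.
#' @param seed master seed; all randomness derives from it.
#' @return a `run_config` list.
#' @export
run_config <- function(window_length_s = 1.0, window_overlap = 0.9,
                       acc_cutoff_hz = 0.5, gyr_cutoff_hz = 4,
                       n_trees_transition = 35, n_trees_sit = 25,
                       k_folds = 10, n_repeats = 5,
                       merge_gap_s = 1.5, min_overlap = 0.5,
                       normalization = c("pooled", "per_subject"),
                       walking_mode = c("labels", "detector"),
                       grouping = c("subject", "window"),
                       n_subjects = 20, trial_durations_s = c(180, 240, 300),
                       seed = 1) {
  normalization <- match.arg(normalization)
  walking_mode <- match.arg(walking_mode)
  grouping <- match.arg(grouping)
  structure(as.list(environment()), class = "run_config")
}

config_spec <- function(config) {
  window_spec(config$window_length_s, config$window_overlap)
}

#' Preprocess and featurize every trial of a cohort
#'
#' Runs filtering, windowed feature extraction and ground-truth window
#' labeling for each trial.
#'
#' @param cohort an `imu_cohort` tibble.
#' @param config a [run_config].
#' @return the cohort tibble with a list-column `features` of labeled
#'   (un-normalized) feature tibbles.
#' @export
featurize_cohort <- function(cohort, config = run_config()) {
  spec <- config_spec(config)
  cohort$features <- map2(cohort$recording, cohort$labels, function(rec, lab) {
    proc <- preprocess_recording(rec, config$acc_cutoff_hz, config$gyr_cutoff_hz)
    label_windows(compute_features(proc, spec), lab, spec, config$min_overlap)
  })
  cohort
}

# no-Walking segments for one trial under the configured walking mode
no_walking_segments <- function(recording, labels, config) {
  if (config$walking_mode == "labels") {
    complement_intervals(labels, "WALKING")
  } else {
    proc <- preprocess_recording(recording, config$acc_cutoff_hz,
                                 config$gyr_cutoff_hz)
    walking <- suppressMessages(detect_walking(proc, spec = config_spec(config)))
    complement_intervals(walking, "WALKING")
  }
}

#' Segment one trial's window predictions into Sit phases
#'
#' Window predictions become detection intervals, and the merge rules —
#' gated by the trial's no-Walking segments — emit the final Sit phases.
#'
#' @param pred tibble with `window_start_s`, `transition_pred`,
#'   `sit_pred` for one trial.
#' @param recording the trial's [imu_recording].
#' @param labels the trial's [label_track] (source of Walking segments in
#'   `"labels"` mode).
#' @param config a [run_config].
#' @return a `sit_phases` tibble.
#' @export
segment_trial <- function(pred, recording, labels, config = run_config()) {
  spec <- config_spec(config)
  sit_track <- windows_to_intervals(pred$sit_pred, pred$window_start_s, spec)
  tra_track <- windows_to_intervals(pred$transition_pred, pred$window_start_s, spec)
  nw <- no_walking_segments(recording, labels, config)
  merge_sit_phases(sit_track, tra_track, nw, config$merge_gap_s)
}

#' Run the full pipeline on a cohort
#'
#' Featurizes every trial, runs grouped k-fold cross-validation of the
#' Transition/Sit detector pair (normalization refit within each training
#' split), segments each trial's held-out predictions into Sit phases,
#' and evaluates them against the ground-truth SIT intervals — per trial,
#' per trial length, and overall.
#'
#' @param cohort an `imu_cohort`.
#' @param config a [run_config].
#' @return a `sit_report`: `trials` (per-trial phases and evaluation),
#'   `by_duration` (summary per trial length), `overall` (one-row
#'   summary), `cv` (the `sit_cv` object), `config`.
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  feats <- featurize_cohort(cohort, config)
  cv <- crossvalidate(feats, k = config$k_folds, grouping = config$grouping,
                      seed = config$seed,
                      n_trees_transition = config$n_trees_transition,
                      n_trees_sit = config$n_trees_sit,
                      n_repeats = config$n_repeats,
                      normalization = config$normalization)
  preds <- cv$predictions
  feats <- left_join(feats, preds[, c("subject_id", "trial_id", "pred")],
                     by = c("subject_id", "trial_id"))
  fs_of <- function(rec) imu_fs(rec)
  trials <- feats |>
    mutate(phases = pmap(list(.data$pred, .data$recording, .data$labels),
                         function(p, r, l) segment_trial(p, r, l, config)),
           eval = pmap(list(.data$phases, .data$labels, .data$recording),
                       function(ph, l, r)
                         evaluate_trial(ph, l, fs_of(r), config_spec(config))))
  per_trial <- bind_rows(map(trials$eval, glance)) |>
    mutate(subject_id = trials$subject_id, trial_id = trials$trial_id,
           duration_s = trials$duration_s, .before = 1)
  summarise_set <- function(evals) {
    conf <- bind_rows(map(evals, function(e) e$confusion)) |>
      summarise(across(everything(), sum))
    dts <- unlist(map(evals, function(e) e$delta_t$delta_t_s))
    n_truth <- sum(map_int(evals, function(e) e$n_truth_events))
    n_matched <- sum(map_int(evals, function(e) e$n_matched))
    ob <- if (length(dts) >= 4) boxplot_outliers(dts) else
      list(n_outliers = 0L, pct_outliers = 0)
    dplyr::bind_cols(
      conf, classification_metrics(conf),
      tibble(n_truth_events = n_truth, n_matched = n_matched,
             event_sensitivity = ifelse(n_truth > 0, n_matched / n_truth, NA),
             median_delta_t_s = if (length(dts)) median(dts) else NA_real_,
             n_delta_t = length(dts),
             n_outliers = ob$n_outliers, pct_outliers = ob$pct_outliers))
  }
  by_duration <- trials |>
    group_by(.data$duration_s) |>
    summarise(res = list(summarise_set(.data$eval)), .groups = "drop") |>
    tidyr::unnest("res")
  overall <- summarise_set(trials$eval)
  structure(list(trials = trials[, c("subject_id", "trial_id", "duration_s",
                                     "pred", "phases", "eval")],
                 per_trial = per_trial,
                 by_duration = by_duration,
                 overall = overall,
                 cv = cv,
                 config = config),
            class = "sit_report")
}

#' @exportS3Method generics::glance
glance.sit_report <- function(x, ...) x$overall

#' @exportS3Method generics::tidy
tidy.sit_report <- function(x, ...) x$by_duration

#' @export
print.sit_report <- function(x, ...) {
  cat("Sit-phase pipeline report (", nrow(x$trials), " trials, ",
      x$cv$k, "-fold ", x$cv$grouping, "-grouped CV)\n", sep = "")
  cat("\nPer trial length:\n")
  print(as.data.frame(x$by_duration), digits = 3)
  cat("\nOverall:\n")
  print(as.data.frame(x$overall), digits = 3)
  invisible(x)
}
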