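#' Window-level confusion counts
#'
#' Scores prediction and truth on a common evaluation grid of sliding
#' windows (same geometry as the feature windows): a window counts as
#' positive when at least half of its span (inclusive) is covered by the
#' respective interval set.
#'
#' @param pred_phases tibble of predicted intervals (`start_s`, `end_s`).
#' @param truth tibble of ground-truth intervals.
#' @param duration_s trial duration, seconds.
#' @param fs sampling rate, Hz.
#' @param spec a [window_spec] defining the evaluation grid.
#' @param min_overlap occupancy threshold (default 0.5).
#' @return one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
window_confusion <- function(pred_phases, truth, duration_s, fs,
                             spec = window_spec(), min_overlap = 0.5) {
  win <- window_indices(floor(duration_s * fs), spec, fs)
  a <- win$start_s
  b <- a + spec$length_s
  thr <- min_overlap * spec$length_s - 1e-12
  p <- overlap_with_set(a, b, canonicalize_intervals(pred_phases)) >= thr
  t_ <- overlap_with_set(a, b, canonicalize_intervals(truth)) >= thr
  tibble(tp = sum(p & t_), fp = sum(p & !t_), tn = sum(!p & !t_),
         fn = sum(!p & t_))
}

#' Sensitivity, specificity and F-score from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), F-score (F1) =
#' 2TP/(2TP+FP+FN), each reported as a percentage. A ratio with a zero
#' denominator is reported as `NA` with a warning, never silently 0.
#'
#' @param counts one-row tibble (or list) with `tp`, `fp`, `tn`, `fn`.
#' @return one-row tibble with `sensitivity`, `specificity`, `f_score`
#'   in percent.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined (zero denominator); reported as NA."))
      return(NA_real_)
    }
    100 * num / den
  }
  tibble(sensitivity = ratio(tp, tp + fn, "Sensitivity"),
         specificity = ratio(tn, tn + fp, "Specificity"),
         f_score = ratio(2 * tp, 2 * tp + fp + fn, "F-score"))
}

#' Greedy one-to-one event matching by temporal overlap
#'
#' Candidate (truth, prediction) pairs with positive overlap are matched
#' greedily in order of descending overlap (ties: earlier truth event,
#' then earlier prediction); each event participates in at most one pair.
#' Unmatched truth events are detection misses.
#'
#' @param truth_phases,pred_phases canonical interval tibbles.
#' @return tibble with one row per matched pair: `truth_start`,
#'   `truth_end`, `pred_start`, `pred_end`, `overlap_s`.
#' @export
match_events <- function(truth_phases, pred_phases) {
  truth <- canonicalize_intervals(truth_phases)
  pred <- canonicalize_intervals(pred_phases)
  out <- tibble(truth_start = double(), truth_end = double(),
                pred_start = double(), pred_end = double(),
                overlap_s = double())
  if (nrow(truth) == 0 || nrow(pred) == 0) return(out)
  cand <- tidyr::expand_grid(ti = seq_len(nrow(truth)), pi = seq_len(nrow(pred)))
  cand$overlap <- pmax(0, pmin(truth$end_s[cand$ti], pred$end_s[cand$pi]) -
                            pmax(truth$start_s[cand$ti], pred$start_s[cand$pi]))
  cand <- cand[cand$overlap > 0, , drop = FALSE]
  cand <- cand[order(-cand$overlap, cand$ti, cand$pi), , drop = FALSE]
  used_t <- logical(nrow(truth))
  used_p <- logical(nrow(pred))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    ti <- cand$ti[i]; pi <- cand$pi[i]
    if (used_t[ti] || used_p[pi]) next
    used_t[ti] <- TRUE
    used_p[pi] <- TRUE
    rows[[length(rows) + 1]] <- tibble(
      truth_start = truth$start_s[ti], truth_end = truth$end_s[ti],
      pred_start = pred$start_s[pi], pred_end = pred$end_s[pi],
      overlap_s = cand$overlap[i])
  }
  if (length(rows) > 0) out <- bind_rows(rows)
  out
}

#' Segmentation timing errors of matched events
#'
#' For each matched pair, two values: the absolute onset difference
#' `|start_truth - start_pred|` and the absolute offset difference
#' `|end_truth - end_pred|` (each segmentation point contributes one
#' value). Set `per_event = TRUE` to aggregate the two into their mean
#' per event instead.
#'
#' @param matches tibble from [match_events()].
#' @param per_event aggregate start/end per event? Default `FALSE`.
#' @return tibble with columns `event`, `point` (`"start"`/`"end"`, or
#'   `"event"`), `delta_t_s`.
#' @export
delta_t <- function(matches, per_event = FALSE) {
  ds <- abs(matches$truth_start - matches$pred_start)
  de <- abs(matches$truth_end - matches$pred_end)
  if (per_event) {
    return(tibble(event = seq_along(ds), point = "event",
                  delta_t_s = (ds + de) / 2))
  }
  tibble(event = rep(seq_along(ds), each = 2),
         point = rep(c("start", "end"), length(ds)),
         delta_t_s = as.vector(rbind(ds, de)))
}

#' Tukey boxplot outliers
#'
#' Values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with
#' linear-interpolation quartiles — the standard boxplot fence rule.
#'
#' @param values numeric vector (at least 4 values for a meaningful
#'   fence; fewer yields an empty outlier set with a warning).
#' @return list with `outliers` (the outlying values), `n_outliers`,
#'   `pct_outliers` (share of all values, percent), `lower`, `upper`
#'   (the fences).
#' @export
boxplot_outliers <- function(values) {
  if (length(values) < 4) {
    warn("Fewer than 4 values; outlier fences not estimated.")
    return(list(outliers = numeric(), n_outliers = 0L, pct_outliers = 0,
                lower = NA_real_, upper = NA_real_))
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  out <- values[values < lower | values > upper]
  list(outliers = out, n_outliers = length(out),
       pct_outliers = 100 * length(out) / length(values),
       lower = lower, upper = upper)
}

#' Evaluate predicted Sit phases against ground truth for one trial
#'
#' Combines window-level confusion metrics, greedy event matching,
#' per-point timing errors and the Tukey outlier summary into one report.
#'
#' @param pred_phases predicted Sit phases (tibble `start_s`, `end_s`).
#' @param truth_track ground-truth [label_track]; its SIT intervals are
#'   the reference events.
#' @param fs sampling rate, Hz.
#' @param spec evaluation [window_spec].
#' @return a `sit_eval` object with elements `confusion`, `metrics`,
#'   `matches`, `delta_t`, `n_truth_events`, `n_matched`.
#' @export
evaluate_trial <- function(pred_phases, truth_track, fs, spec = window_spec()) {
  truth <- track_intervals(truth_track, "SIT")
  conf <- window_confusion(pred_phases, truth, track_duration(truth_track),
                           fs, spec)
  matches <- match_events(truth, pred_phases)
  dt <- delta_t(matches)
  structure(list(confusion = conf,
                 metrics = classification_metrics(conf),
                 matches = matches,
                 delta_t = dt,
                 n_truth_events = nrow(truth),
                 n_matched = nrow(matches)),
            class = "sit_eval")
}

#' @exportS3Method generics::glance
glance.sit_eval <- function(x, ...) {
  dplyr::bind_cols(
    x$confusion, x$metrics,
    tibble(n_truth_events = x$n_truth_events,
           n_matched = x$n_matched,
           event_sensitivity = ifelse(x$n_truth_events > 0,
                                      x$n_matched / x$n_truth_events, NA_real_),
           median_delta_t_s = if (nrow(x$delta_t) > 0)
             median(x$delta_t$delta_t_s) else NA_real_))
}

#' @export
print.sit_eval <- function(x, ...) {
  cat("Sit-phase evaluation\n")
  print(glance(x))
  invisible(x)
}
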