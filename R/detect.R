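#' Label windows from an annotation track
#'
#' A window is positive for a class when at least `min_overlap` of its
#' time span (inclusive threshold) lies inside an interval of that class.
#' Two label columns are produced: `transition_label` (stand-to-sit or
#' sit-to-stand postural changes) and `sit_label` (the seated state); all
#' other windows are negatives for both classifiers.
#'
#' @param features a feature tibble from [compute_features()].
#' @param track a [label_track] covering the trial.
#' @param spec the [window_spec] the features were computed with.
#' @param min_overlap minimum occupancy fraction, default 0.5.
#' @return `features` with integer columns `transition_label` and
#'   `sit_label` appended.
#' @export
label_windows <- function(features, track, spec = window_spec(), min_overlap = 0.5) {
  a <- features$window_start_s
  b <- a + spec$length_s
  lab <- function(label) {
    ov <- overlap_with_set(a, b, track_intervals(track, label))
    as.integer(ov >= min_overlap * spec$length_s - 1e-12)
  }
  features$transition_label <- lab("TRANSITION")
  features$sit_label <- lab("SIT")
  features
}

forest_mtry <- function(p) max(1L, as.integer(round(sqrt(p))))

feature_matrix_of <- function(features) {
  as.matrix(features[, feature_columns()])
}

#' Train a bagged random forest with best-of-repeats selection
#'
#' Trains `n_repeats` independent forests (bootstrap sample of size n per
#' tree, features-per-split `round(sqrt(p))`, unlimited depth, minimum
#' node size 1) and keeps the repeat with the smallest out-of-bag
#' classification error. Deterministic given `seed`.
#'
#' @param features feature tibble or numeric matrix of predictors.
#' @param labels binary 0/1 vector, one per row.
#' @param n_trees ensemble size.
#' @param n_repeats number of training repeats (default 5).
#' @param seed integer seed; per-repeat seeds are derived from it.
#' @return a `sit_forest` object: the chosen [ranger::ranger] model plus
#'   OOB diagnostics (`oob_error`, `oob_errors`, `repeat_chosen`).
#' @export
train_forest <- function(features, labels, n_trees, n_repeats = 5, seed = 1) {
  x <- if (is.matrix(features)) features else feature_matrix_of(features)
  if (nrow(x) != length(labels)) {
    abort("Feature rows and labels differ in length.",
          class = "sitseg_parameter_error")
  }
  y <- factor(as.integer(labels), levels = c(0, 1))
  if (length(unique(labels)) < 2) {
    abort("Training labels contain a single class; cannot train a classifier.",
          class = "sitseg_training_error")
  }
  fits <- lapply(seq_len(n_repeats), function(r) {
    ranger::ranger(x = x, y = y,
                   num.trees = n_trees,
                   mtry = forest_mtry(ncol(x)),
                   min.node.size = 1,
                   replace = TRUE, sample.fraction = 1,
                   seed = derive_seed(seed, 101, r),
                   num.threads = 1)
  })
  oob <- vapply(fits, function(f) f$prediction.error, numeric(1))
  best <- which.min(oob)
  structure(list(model = fits[[best]],
                 n_trees = n_trees,
                 oob_error = oob[best],
                 oob_errors = oob,
                 repeat_chosen = best,
                 seed = seed),
            class = "sit_forest")
}

#' Predict window classes with a trained forest
#'
#' Majority vote over the trees; a window is positive when strictly more
#' than half the trees vote positive (ties break to negative).
#'
#' @param model a `sit_forest` from [train_forest()].
#' @param features feature tibble or matrix with the training columns.
#' @return integer 0/1 vector, one prediction per row.
#' @export
predict_windows <- function(model, features) {
  x <- if (is.matrix(features)) features else {
    missing <- setdiff(feature_columns(), names(features))
    if (length(missing) > 0) {
      abort(paste0("Feature matrix is missing column(s): ",
                   paste(missing, collapse = ", ")),
            class = "sitseg_schema_error")
    }
    feature_matrix_of(features)
  }
  if (ncol(x) != model$model$num.independent.variables) {
    abort("Feature columns do not match the trained model.",
          class = "sitseg_schema_error")
  }
  if (nrow(x) == 0) return(integer())
  pr <- predict(model$model, data = x, predict.all = TRUE, num.threads = 1)
  votes <- pr$predictions  # n x trees matrix of class indices (1 = "0", 2 = "1")
  frac_pos <- rowMeans(votes == 2L)
  as.integer(frac_pos > 0.5)
}

#' Out-of-bag error as a function of ensemble size
#'
#' Grows `n_runs` independently seeded forests of `max_trees` trees and
#' records, for each run, the OOB misclassification rate of the leading
#' sub-ensemble of 1..`max_trees` trees (the cumulative OOB trace of
#' [randomForest::randomForest]). Used to pick an ensemble size past the
#' knee of the error curve; the pipeline defaults of 35 (Transition) and
#' 25 (Sit) trees were chosen this way.
#'
#' @param features feature tibble or matrix.
#' @param labels binary 0/1 vector.
#' @param max_trees largest ensemble size to trace.
#' @param n_runs number of independent runs (default 10).
#' @param seed integer seed.
#' @return an `oob_curve` tibble with columns `trees`, `mean_oob`,
#'   `sd_oob`.
#' @export
oob_error_curve <- function(features, labels, max_trees, n_runs = 10, seed = 1) {
  x <- if (is.matrix(features)) features else feature_matrix_of(features)
  if (length(unique(labels)) < 2) {
    abort("Labels contain a single class.", class = "sitseg_training_error")
  }
  y <- factor(as.integer(labels), levels = c(0, 1))
  runs <- vapply(seq_len(n_runs), function(r) {
    with_local_seed(derive_seed(seed, 202, r), {
      fit <- randomForest::randomForest(
        x = x, y = y, ntree = max_trees,
        mtry = forest_mtry(ncol(x)), nodesize = 1,
        replace = TRUE, sampsize = nrow(x))
      as.numeric(fit$err.rate[, "OOB"])
    })
  }, numeric(max_trees))
  runs <- matrix(runs, nrow = max_trees)
  out <- tibble(trees = seq_len(max_trees),
                mean_oob = rowMeans(runs),
                sd_oob = apply(runs, 1, sd))
  if (n_runs == 1) out$sd_oob <- rep(0, max_trees)
  class(out) <- c("oob_curve", class(out))
  out
}

#' Train the Transition/Sit detector pair
#'
#' @param features normalized feature tibble or matrix.
#' @param transition_label,sit_label binary 0/1 window labels.
#' @param n_trees_transition,n_trees_sit ensemble sizes (defaults 35 and
#'   25).
#' @param n_repeats training repeats per model (default 5; the best-OOB
#'   repeat is kept).
#' @param seed integer seed.
#' @return a `detector_pair` object with elements `transition` and `sit`.
#' @export
train_detectors <- function(features, transition_label, sit_label,
                            n_trees_transition = 35, n_trees_sit = 25,
                            n_repeats = 5, seed = 1) {
  x <- if (is.matrix(features)) features else feature_matrix_of(features)
  structure(list(
    transition = train_forest(x, transition_label, n_trees_transition,
                              n_repeats, derive_seed(seed, 1)),
    sit = train_forest(x, sit_label, n_trees_sit,
                       n_repeats, derive_seed(seed, 2)),
    seed = seed),
    class = "detector_pair")
}

#' @exportS3Method generics::tidy
tidy.detector_pair <- function(x, ...) {
  tibble(model = c("transition", "sit"),
         n_trees = c(x$transition$n_trees, x$sit$n_trees),
         oob_error = c(x$transition$oob_error, x$sit$oob_error),
         repeat_chosen = c(x$transition$repeat_chosen, x$sit$repeat_chosen))
}

#' @exportS3Method generics::glance
glance.detector_pair <- function(x, ...) {
  tibble(oob_error_transition = x$transition$oob_error,
         oob_error_sit = x$sit$oob_error,
         n_trees_transition = x$transition$n_trees,
         n_trees_sit = x$sit$n_trees,
         seed = x$seed)
}

#' @export
print.detector_pair <- function(x, ...) {
  cat("Transition/Sit detector pair\n")
  print(tidy(x))
  invisible(x)
}

#' Grouped k-fold cross-validation of the detector pair
#'
#' Splits the labeled trials into `k` folds, by default grouping at the
#' subject level so no subject contributes windows to both the training
#' and test side of a fold (window-level grouping is available to mimic a
#' plain segment split). Per fold, normalization percentiles are refit on
#' the training windows only, the detector pair is trained on them, and
#' the held-out trials are predicted — so every trial receives held-out
#' window predictions exactly once.
#'
#' @param trials a tibble with one row per trial: columns `subject_id`,
#'   `trial_id` and a list-column `features` of labeled (un-normalized)
#'   feature tibbles from [label_windows()].
#' @param k number of folds (default 10).
#' @param grouping `"subject"` (default) or `"window"`.
#' @param seed integer seed driving fold assignment and training.
#' @param n_trees_transition,n_trees_sit,n_repeats forwarded to
#'   [train_detectors()].
#' @param normalization `"pooled"` (default: percentiles fit once on the
#'   pooled training windows) or `"per_subject"` (each subject normalized
#'   by percentiles of their own windows; self-contained, so held-out
#'   subjects use their own percentiles without leakage).
#' @return a `sit_cv` object: `folds` (fold assignment), `predictions`
#'   (one row per trial with list-column `pred` holding
#'   `window_start_s`, `transition_pred`, `sit_pred`, plus the window
#'   labels), `detectors` (per-fold `detector_pair`s), and `norm_params`
#'   per fold.
#' @export
crossvalidate <- function(trials, k = 10, grouping = c("subject", "window"),
                          seed = 1, n_trees_transition = 35, n_trees_sit = 25,
                          n_repeats = 5,
                          normalization = c("pooled", "per_subject")) {
  grouping <- match.arg(grouping)
  normalization <- match.arg(normalization)
  if (grouping == "window") {
    return(crossvalidate_windows(trials, k, seed, n_trees_transition,
                                 n_trees_sit, n_repeats))
  }
  subjects <- sort(unique(trials$subject_id))
  if (length(subjects) < k) {
    abort(paste0("Need at least k = ", k, " subjects for subject-grouped ",
                 k, "-fold cross-validation; got ", length(subjects), "."),
          class = "sitseg_parameter_error")
  }
  fold_of <- with_local_seed(derive_seed(seed, 303), {
    setNames(sample(rep_len(seq_len(k), length(subjects))), subjects)
  })
  folds <- tibble(subject_id = subjects, fold = as.integer(fold_of[subjects]))
  detectors <- vector("list", k)
  norms <- vector("list", k)
  pred_rows <- vector("list", nrow(trials))
  trial_fold <- folds$fold[match(trials$subject_id, folds$subject_id)]
  # per-subject normalization is self-contained: each subject's windows are
  # scaled by that subject's own percentiles, training and test alike
  subj_norm <- NULL
  if (normalization == "per_subject") {
    subj_norm <- lapply(split(seq_len(nrow(trials)), trials$subject_id),
                        function(ix) fit_normalization(trials$features[ix]))
  }
  norm_trial <- function(i, np_pooled) {
    if (normalization == "pooled") {
      apply_normalization(trials$features[[i]], np_pooled)
    } else {
      apply_normalization(trials$features[[i]],
                          subj_norm[[trials$subject_id[i]]])
    }
  }
  for (f in seq_len(k)) {
    np <- if (normalization == "pooled") {
      fit_normalization(bind_rows(trials$features[trial_fold != f]))
    } else NULL
    train_norm <- bind_rows(lapply(which(trial_fold != f), norm_trial,
                                   np_pooled = np))
    pair <- train_detectors(train_norm,
                            train_norm$transition_label, train_norm$sit_label,
                            n_trees_transition, n_trees_sit, n_repeats,
                            seed = derive_seed(seed, 404, f))
    detectors[[f]] <- pair
    norms[[f]] <- np
    for (i in which(trial_fold == f)) {
      te <- norm_trial(i, np)
      pred_rows[[i]] <- tibble(
        window_start_s = te$window_start_s,
        transition_pred = predict_windows(pair$transition, te),
        sit_pred = predict_windows(pair$sit, te),
        transition_label = te$transition_label,
        sit_label = te$sit_label)
    }
  }
  structure(list(
    folds = folds,
    predictions = mutate(trials[, c("subject_id", "trial_id")],
                         fold = trial_fold, pred = pred_rows),
    detectors = detectors,
    norm_params = norms,
    k = k, grouping = grouping, normalization = normalization, seed = seed),
    class = "sit_cv")
}

# Window-level folds: pool all windows, split rows into k folds ignoring
# subject/trial structure. Kept as the permissive alternative reading of a
# plain "90% training / 10% testing segments" split.
crossvalidate_windows <- function(trials, k, seed, n_trees_transition,
                                  n_trees_sit, n_repeats) {
  pooled <- bind_rows(trials$features)
  n <- nrow(pooled)
  if (n < k) abort("Fewer windows than folds.", class = "sitseg_parameter_error")
  fold <- with_local_seed(derive_seed(seed, 303), sample(rep_len(seq_len(k), n)))
  detectors <- vector("list", k)
  norms <- vector("list", k)
  preds <- integer(n)
  preds_sit <- integer(n)
  for (f in seq_len(k)) {
    tr <- pooled[fold != f, ]
    np <- fit_normalization(tr)
    trn <- apply_normalization(tr, np)
    pair <- train_detectors(trn, trn$transition_label, trn$sit_label,
                            n_trees_transition, n_trees_sit, n_repeats,
                            seed = derive_seed(seed, 404, f))
    te <- apply_normalization(pooled[fold == f, ], np)
    preds[fold == f] <- predict_windows(pair$transition, te)
    preds_sit[fold == f] <- predict_windows(pair$sit, te)
    detectors[[f]] <- pair
    norms[[f]] <- np
  }
  pooled$fold <- fold
  pooled$transition_pred <- preds
  pooled$sit_pred <- preds_sit
  by_trial <- pooled |>
    select("subject_id", "trial_id", "window_start_s", "transition_pred",
           "sit_pred", "transition_label", "sit_label") |>
    group_by(.data$subject_id, .data$trial_id) |>
    tidyr::nest(pred = c("window_start_s", "transition_pred", "sit_pred",
                         "transition_label", "sit_label")) |>
    ungroup()
  structure(list(folds = tibble(window = seq_len(n), fold = fold),
                 predictions = mutate(by_trial, fold = NA_integer_),
                 detectors = detectors, norm_params = norms,
                 k = k, grouping = "window", seed = seed),
            class = "sit_cv")
}

#' @exportS3Method generics::glance
glance.sit_cv <- function(x, ...) {
  oob <- bind_rows(lapply(x$detectors, glance))
  tibble(k = x$k, grouping = x$grouping, seed = x$seed,
         mean_oob_transition = mean(oob$oob_error_transition),
         mean_oob_sit = mean(oob$oob_error_sit))
}
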