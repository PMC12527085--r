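test_that("window labeling follows the inclusive majority-occupancy rule", {
  f <- tibble::tibble(subject_id = "S", trial_id = "T",
                      window_start_s = c(10, 20, 30.2, 40.5))
  track <- label_track(tibble::tibble(
    start_s = c(10, 30.9, 41), end_s = c(12, 40, 45),
    label = c("SIT", "TRANSITION", "TRANSITION")), duration_s = 60)
  out <- label_windows(f, track, window_spec())
  expect_equal(out$sit_label, c(1L, 0L, 0L, 0L))       # full overlap, none
  expect_equal(out$transition_label[3], 0L)            # 0.3 s overlap < 0.5
  expect_equal(out$transition_label[4], 1L)            # exactly 0.5 s, inclusive
})

test_that("forests separate Gaussian blobs and beat a centroid oracle check", {
  blobs <- make_blob_features(n = 500, sep = 4, sd = 1)
  fit <- train_forest(blobs$x, blobs$y, n_trees = 35, seed = 5)
  expect_lt(fit$oob_error, 0.05)
  # independent sanity oracle: nearest-centroid achieves 0 error here
  mu0 <- colMeans(blobs$x[blobs$y == 0, ])
  mu1 <- colMeans(blobs$x[blobs$y == 1, ])
  d0 <- rowSums(sweep(blobs$x, 2, mu0)^2)
  d1 <- rowSums(sweep(blobs$x, 2, mu1)^2)
  expect_equal(sum((d1 < d0) != blobs$y), 0)
})

test_that("permuted labels give chance-level OOB error", {
  blobs <- make_blob_features(n = 400, sep = 4, sd = 1)
  set.seed(77)
  yperm <- sample(blobs$y)
  fit <- train_forest(blobs$x, yperm, n_trees = 35, seed = 5)
  baseline <- 1 - max(mean(yperm), 1 - mean(yperm))
  expect_lt(abs(fit$oob_error - baseline), 0.1)
})

test_that("training keeps the best of the repeats and is deterministic", {
  blobs <- make_blob_features(n = 300, sep = 1, sd = 1.5, seed = 3)
  a <- train_forest(blobs$x, blobs$y, n_trees = 15, n_repeats = 5, seed = 21)
  b <- train_forest(blobs$x, blobs$y, n_trees = 15, n_repeats = 5, seed = 21)
  expect_equal(a$oob_error, min(a$oob_errors))
  expect_length(a$oob_errors, 5)
  expect_equal(a$oob_errors, b$oob_errors)
  expect_equal(a$repeat_chosen, b$repeat_chosen)
  expect_equal(predict_windows(a, blobs$x), predict_windows(b, blobs$x))
  expect_error(train_forest(blobs$x, rep(1L, 300), n_trees = 5),
               class = "sitseg_training_error")
})

test_that("prediction is majority vote; resubstitution is not worse than OOB", {
  blobs <- make_blob_features(n = 400, sep = 1.2, sd = 1.5, seed = 13)
  fit <- train_forest(blobs$x, blobs$y, n_trees = 25, seed = 2)
  pred <- predict_windows(fit, blobs$x)
  expect_true(all(pred %in% c(0L, 1L)))
  expect_lte(mean(pred != blobs$y), fit$oob_error)
  expect_equal(predict_windows(fit, blobs$x[0, , drop = FALSE]), integer())

  f <- tibble::as_tibble(as.data.frame(blobs$x))
  f$window_start_s <- seq_len(nrow(f))
  expect_equal(predict_windows(fit, f), pred)
  expect_error(predict_windows(fit, f[, -1]), class = "sitseg_schema_error")
})

test_that("OOB error curves have the documented shape and contract", {
  blobs <- make_blob_features(n = 300, sep = 2, sd = 1.2, seed = 4)
  curve <- oob_error_curve(blobs$x, blobs$y, max_trees = 20, n_runs = 5,
                           seed = 3)
  expect_equal(nrow(curve), 20)
  expect_equal(curve$trees, 1:20)
  expect_true(all(curve$mean_oob >= 0 & curve$mean_oob <= 1))
  expect_lte(curve$mean_oob[20], curve$mean_oob[1])
  one <- oob_error_curve(blobs$x, blobs$y, max_trees = 5, n_runs = 1, seed = 3)
  expect_equal(one$sd_oob, rep(0, 5))
})

test_that("subject-grouped cross-validation partitions without leakage", {
  trials <- make_tiny_trials(n_subjects = 20)
  cv <- crossvalidate(trials, k = 10, seed = 6, n_trees_transition = 10,
                      n_trees_sit = 10, n_repeats = 2)
  # each fold holds out exactly 2 of the 20 subjects
  expect_equal(as.integer(table(cv$folds$fold)), rep(2L, 10))
  # held-out predictions cover every trial exactly once
  expect_equal(sort(cv$predictions$trial_id), sort(trials$trial_id))
  expect_true(all(purrr::map_int(cv$predictions$pred, nrow) == 40))
  # determinism of fold assignment
  cv2 <- crossvalidate(trials, k = 10, seed = 6, n_trees_transition = 10,
                       n_trees_sit = 10, n_repeats = 2)
  expect_equal(cv$folds, cv2$folds)
  # no leakage: per-fold normalization equals a refit on training rows only
  for (f in c(1, 5)) {
    train_subj <- cv$folds$subject_id[cv$folds$fold != f]
    refit <- fit_normalization(trials$features[trials$subject_id %in% train_subj])
    expect_equal(cv$norm_params[[f]], refit)
  }
  expect_error(crossvalidate(make_tiny_trials(n_subjects = 5), k = 10),
               class = "sitseg_parameter_error")
})

test_that("window-grouped folds are supported as an alternative split", {
  trials <- make_tiny_trials(n_subjects = 4, n_windows = 60)
  cv <- crossvalidate(trials, k = 5, grouping = "window", seed = 2,
                      n_trees_transition = 8, n_trees_sit = 8, n_repeats = 2)
  expect_equal(sort(unique(cv$folds$fold)), 1:5)
  expect_equal(sum(purrr::map_int(cv$predictions$pred, nrow)), 240)
})

test_that("detector pair training reports per-model OOB diagnostics", {
  trials <- make_tiny_trials(n_subjects = 6)
  pooled <- dplyr::bind_rows(trials$features)
  pair <- train_detectors(pooled, pooled$transition_label, pooled$sit_label,
                          n_trees_transition = 12, n_trees_sit = 8,
                          n_repeats = 2, seed = 3)
  td <- tidy(pair)
  expect_equal(td$model, c("transition", "sit"))
  expect_equal(td$n_trees, c(12, 8))
  expect_true(all(td$oob_error >= 0 & td$oob_error <= 1))
  expect_equal(nrow(glance(pair)), 1)
})
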