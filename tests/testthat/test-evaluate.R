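test_that("window confusion handles identity, empty and disjoint cases", {
  fs <- 50
  truth <- tibble::tibble(start_s = c(10, 40), end_s = c(20, 50))
  same <- window_confusion(truth, truth, 60, fs)
  expect_equal(same$fp, 0)
  expect_equal(same$fn, 0)
  expect_equal(sum(same), nrow(window_indices(60 * fs, window_spec(), fs)))

  none <- window_confusion(tibble::tibble(start_s = double(), end_s = double()),
                           truth, 60, fs)
  expect_equal(none$tp, 0)
  expect_equal(none$fp, 0)

  shifted <- window_confusion(tibble::tibble(start_s = 25, end_s = 35),
                              tibble::tibble(start_s = 5, end_s = 15), 60, fs)
  expect_equal(shifted$tp, 0)
  expect_equal(shifted$fp, shifted$fn)
})

test_that("metrics match their closed forms and brute-force counting", {
  m <- classification_metrics(list(tp = 8, fp = 1, tn = 9, fn = 2))
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 90)
  expect_equal(m$f_score, 100 * 16 / 19)

  perfect <- classification_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(as.numeric(perfect), c(100, 100, 100))

  w <- capture_warnings(
    z <- classification_metrics(list(tp = 0, fp = 0, tn = 3, fn = 0)))
  expect_true(all(grepl("undefined", w)))  # sensitivity and F-score warn
  expect_true(is.na(z$sensitivity))
  expect_true(is.na(z$f_score))
  expect_equal(z$specificity, 100)

  set.seed(19)
  for (i in 1:30) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    tn <- sample(1:50, 1); fn <- sample(0:50, 1)
    if (tp + fn == 0 || tp == 0 && fp == 0 && fn == 0) next
    m <- classification_metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
    # F1 as harmonic mean of precision and recall
    if (tp > 0) {
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      expect_equal(m$f_score, 100 * 2 * p * r / (p + r), tolerance = 1e-12)
    }
    # invariant to TN
    m2 <- classification_metrics(list(tp = tp, fp = fp, tn = tn + 37, fn = fn))
    expect_equal(m2$f_score, m$f_score)
  }
})

test_that("window scoring agrees with an exhaustive per-window count", {
  fs <- 10
  spec <- window_spec()
  set.seed(29)
  for (i in 1:20) {
    dur <- sample(10:20, 1)  # <= 200 windows at fs = 10
    pred <- random_intervals(sample(0:4, 1), dur)
    truth <- random_intervals(sample(0:4, 1), dur)
    got <- window_confusion(pred, truth, dur, fs, spec)
    w <- window_indices(dur * fs, spec, fs)
    tp <- fp <- tn <- fn <- 0
    for (j in seq_len(nrow(w))) {
      a <- w$start_s[j]; b <- a + spec$length_s
      occ <- function(iv) {
        s <- 0
        for (r in seq_len(nrow(iv))) {
          s <- s + max(0, min(b, iv$end_s[r]) - max(a, iv$start_s[r]))
        }
        s >= 0.5 * spec$length_s - 1e-12
      }
      p <- occ(sitseg:::canonicalize_intervals(pred))
      t_ <- occ(sitseg:::canonicalize_intervals(truth))
      if (p && t_) tp <- tp + 1 else if (p) fp <- fp + 1
      else if (t_) fn <- fn + 1 else tn <- tn + 1
    }
    expect_equal(as.numeric(got), c(tp, fp, tn, fn))
  }
})

test_that("event matching is greedy by overlap and one-to-one", {
  m <- match_events(tibble::tibble(start_s = 10, end_s = 20),
                    tibble::tibble(start_s = 11, end_s = 19))
  expect_equal(nrow(m), 1)
  expect_equal(m$overlap_s, 8)

  m2 <- match_events(tibble::tibble(start_s = 10, end_s = 20),
                     tibble::tibble(start_s = c(9, 18), end_s = c(17, 21)))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$pred_start, 9)  # larger overlap wins

  m3 <- match_events(tibble::tibble(start_s = 0, end_s = 5),
                     tibble::tibble(start_s = 6, end_s = 9))
  expect_equal(nrow(m3), 0)
})

test_that("timing errors take one value per segmentation point", {
  m <- match_events(tibble::tibble(start_s = 10, end_s = 20),
                    tibble::tibble(start_s = 10.5, end_s = 19.2))
  dt <- delta_t(m)
  expect_equal(dt$delta_t_s, c(0.5, 0.8), tolerance = 1e-9)
  expect_equal(dt$point, c("start", "end"))

  ident <- delta_t(match_events(tibble::tibble(start_s = 1, end_s = 2),
                                tibble::tibble(start_s = 1, end_s = 2)))
  expect_equal(ident$delta_t_s, c(0, 0))
  expect_equal(median(c(0.2, 0.4, 0.6, 0.8)), 0.5)

  # |a - b| symmetry under swapped roles
  a <- tibble::tibble(start_s = c(3, 9), end_s = c(6, 14))
  b <- tibble::tibble(start_s = c(3.4, 8.1), end_s = c(6.2, 13.5))
  expect_equal(sort(delta_t(match_events(a, b))$delta_t_s),
               sort(delta_t(match_events(b, a))$delta_t_s))

  per_ev <- delta_t(m, per_event = TRUE)
  expect_equal(per_ev$delta_t_s, 0.65, tolerance = 1e-9)
})

test_that("Tukey fences flag outliers like a quartile-by-sorting oracle", {
  ob <- boxplot_outliers(c(1, 2, 3, 4, 100))
  expect_equal(ob$outliers, 100)
  # brute-force: quartiles by linear interpolation of sorted values
  v <- sort(c(1, 2, 3, 4, 100))
  q1 <- v[2]  # 0.25*(n-1)+1 = 2 exactly
  q3 <- v[4]
  expect_equal(ob$lower, q1 - 1.5 * (q3 - q1))
  expect_equal(ob$upper, q3 + 1.5 * (q3 - q1))

  flat <- boxplot_outliers(rep(2, 10))
  expect_equal(flat$n_outliers, 0L)

  expect_warning(few <- boxplot_outliers(c(1, 2)), "Fewer")
  expect_equal(few$n_outliers, 0L)

  # clean Gaussian: expected Tukey outlier share ~0.7%
  set.seed(37)
  fracs <- replicate(20, boxplot_outliers(rnorm(1000))$pct_outliers)
  expect_lt(abs(mean(fracs) - 0.7), 1)
})

test_that("trial evaluation assembles the full report", {
  truth <- label_track(tibble::tibble(start_s = c(10, 40), end_s = c(25, 55),
                                      label = "SIT"), duration_s = 60)
  pred <- tibble::tibble(start_s = c(10.4, 41), end_s = c(24.2, 54))
  ev <- evaluate_trial(pred, truth, fs = 50)
  g <- glance(ev)
  expect_equal(g$n_truth_events, 2)
  expect_equal(g$n_matched, 2)
  expect_equal(g$event_sensitivity, 1)
  expect_equal(g$median_delta_t_s, median(c(0.4, 0.8, 1, 1)))
  expect_gte(g$sensitivity, 80)
})
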