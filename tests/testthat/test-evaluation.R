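test_that("match labelling follows the overlap rule in both modes", {
  ann <- data.frame(recording_id = "r1", start_s = 10, end_s = 10.5,
                    n_syllables = 2L, site_id = "s1", year = "Y1",
                    group = "train", stringsAsFactors = FALSE)
  # exact cover -> TP; match in silence -> FP
  m <- data.frame(recording_id = "r1",
                  start_s = c(10, 3), end_s = c(10.5, 3.2),
                  score = c(80, 60), label = "unverified",
                  stringsAsFactors = FALSE)
  lab <- label_matches(m, ann)
  expect_equal(lab$label, c("TP", "FP"))

  # two matches on the two syllables of one call
  m2 <- data.frame(recording_id = "r1",
                   start_s = c(10.0, 10.3), end_s = c(10.2, 10.5),
                   score = c(70, 60), label = "unverified",
                   stringsAsFactors = FALSE)
  expect_equal(label_matches(m2, ann, mode = "per-match")$label,
               c("TP", "TP"))
  expect_equal(label_matches(m2, ann, mode = "per-call")$label,
               c("TP", "FP"))

  expect_error(label_matches(
    data.frame(recording_id = "zzz", start_s = 1, end_s = 2, score = 5,
               label = "unverified"),
    ann, recording_ids = "r1"), "unknown recording_id")
})

test_that("confusion counts at a threshold match direct enumeration", {
  ann <- make_annotations(4)
  # TP scores 80/70/65 on three distinct calls, FPs 60/20
  lab <- make_labeled(c(80, 70, 65), c(60, 20),
                      call_keys = paste0("r1#", 1:3))
  cc <- confusion_at_threshold(lab, ann, 65)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(3, 0, 1, 2))

  # threshold above all scores
  cc_hi <- confusion_at_threshold(lab, ann, 101)
  expect_equal(c(cc_hi$tp, cc_hi$fp, cc_hi$fn, cc_hi$tn), c(0, 0, 4, 2))

  # threshold 0 with one TP per call of a fully-hit set
  ann3 <- make_annotations(3)
  lab3 <- make_labeled(c(50, 40, 30), numeric(0),
                       call_keys = paste0("r1#", 1:3))
  expect_equal(confusion_at_threshold(lab3, ann3, 0)$fn, 0)
})

test_that("point metrics use the true-call denominator and flag undefined values", {
  cc <- structure(list(tp = 9, fp = 1, fn = 0, tn = 0, n_calls = 10),
                  class = "confusion_counts")
  pm <- point_metrics(cc)
  expect_equal(pm$precision, 0.9)

  # 1500 TPs on 1000 calls -> sensitivity 1.5
  cc2 <- structure(list(tp = 1500, fp = 0, fn = 0, tn = 0,
                        n_calls = 1000), class = "confusion_counts")
  expect_equal(point_metrics(cc2)$sensitivity, 1.5)

  cc3 <- structure(list(tp = 0, fp = 0, fn = 2, tn = 1, n_calls = 0),
                   class = "confusion_counts")
  pm3 <- point_metrics(cc3)
  expect_false(pm3$precision_defined)
  expect_false(pm3$sensitivity_defined)
  expect_true(is.na(pm3$precision))
  expect_true(is.na(pm3$sensitivity))
})

test_that("ROC handles the canonical separation cases", {
  # complete separation
  roc <- roc_and_threshold(make_labeled(c(80, 70), 20))
  expect_equal(roc$auroc, 1.0)
  expect_equal(roc$optimal_threshold, 70)

  # indistinguishable score sets
  roc2 <- roc_and_threshold(make_labeled(c(80, 70), c(80, 70)))
  expect_equal(roc2$auroc, 0.5)
  expect_equal(roc2$optimal_j, 0)

  # interleaved: max J = 0.5 at threshold 80
  roc3 <- roc_and_threshold(make_labeled(c(80, 30), 50))
  expect_equal(roc3$optimal_j, 0.5)
  expect_equal(roc3$optimal_threshold, 80)

  # J is tpr + tnr - 1 elementwise, tpr non-increasing in threshold
  expect_equal(roc3$youden_j, roc3$tpr + roc3$tnr - 1)
  expect_true(all(diff(roc3$tpr) >= -1e-12))

  expect_error(roc_and_threshold(make_labeled(c(80), numeric(0))),
               "ROC undefined")
})

test_that("ROC/Youden equals the exhaustive sweep on random instances", {
  set.seed(42)
  for (i in 1:60) {
    n_tp <- sample(1:25, 1)
    n_fp <- sample(1:25, 1)
    tp <- round(stats::runif(n_tp, 0, 100), sample(0:1, 1))
    fp <- round(stats::runif(n_fp, 0, 100), sample(0:1, 1))
    lab <- make_labeled(tp, fp)
    roc <- roc_and_threshold(lab)
    oracle <- oracle_youden(tp, fp)
    expect_equal(roc$optimal_threshold, oracle$threshold)
    expect_equal(roc$optimal_j, oracle$j, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(7)
  tp <- stats::runif(40, 30, 100)
  fp <- stats::runif(35, 0, 70)
  lab <- make_labeled(tp, fp)
  roc <- roc_and_threshold(lab)
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 35)), predictor = c(tp, fp),
    quiet = TRUE, direction = "<"))
  expect_equal(roc$auroc, as.numeric(ref), tolerance = 1e-12)
})

test_that("AUROC grows towards 1 as the TP/FP score gap widens", {
  clip_s <- function(x) pmin(100, pmax(0, x))
  set.seed(8)
  auroc_at_gap <- vapply(c(0, 20, 45), function(gap) {
    tp <- stats::rnorm(60, 50 + gap / 2, 10)
    fp <- stats::rnorm(60, 50 - gap / 2, 10)
    roc_and_threshold(make_labeled(clip_s(tp), clip_s(fp)))$auroc
  }, 0)
  expect_true(all(diff(auroc_at_gap) > 0))
  expect_gt(auroc_at_gap[3], 0.95)
})

test_that("conditional metrics report the paired error rates", {
  ann <- make_annotations(4)
  lab <- make_labeled(c(80, 70, 65), c(60, 20),
                      call_keys = paste0("r1#", 1:3))
  cm <- conditional_metrics(lab, ann, 65)
  expect_equal(cm$precision, 1.0)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$type1_error, 0)
  expect_equal(cm$type2_error, 0.25)

  # perfect recognizer
  ann1 <- make_annotations(2)
  lab1 <- make_labeled(c(90, 85), numeric(0),
                       call_keys = paste0("r1#", 1:2))
  cm1 <- conditional_metrics(lab1, ann1, 0)
  expect_equal(cm1$precision, 1)
  expect_equal(cm1$sensitivity, 1)
})

test_that("per-call mode conserves tp + fn = n_calls at every threshold", {
  set.seed(9)
  ann <- make_annotations(12)
  cfg <- symbolic_match_config(miss_prob = 0.3, extra_hit_prob = 0.5,
                               fp_per_min = 5)
  m <- synth_match_table(cfg, ann, duration_s = 30, seed = 2)
  lab <- label_matches(m, ann, mode = "per-call")
  for (t in c(0, 25, 50, 75, 101)) {
    cc <- confusion_at_threshold(lab, ann, t)
    expect_equal(cc$tp + cc$fn, 12)
  }
})

test_that("symbolic misses drive conditional sensitivity to the miss rate", {
  ann <- make_annotations(600)
  cfg <- symbolic_match_config(miss_prob = 0.5, extra_hit_prob = 0,
                               fp_per_min = 0)
  m <- synth_match_table(cfg, ann, duration_s = 1300, seed = 11)
  lab <- label_matches(m, ann)
  cm <- conditional_metrics(lab, ann, 0)
  sd3 <- 3 * sqrt(600 * 0.25) / 600
  expect_lt(abs(cm$sensitivity - 0.5), sd3)
})

test_that("subsampling penalty reduces to the unpenalized metrics when |TP| <= N", {
  ann <- make_annotations(5)
  lab <- make_labeled(c(90, 80, 70), c(60, 20),
                      call_keys = paste0("r1#", 1:3))
  pen <- subsample_penalty(lab, ann, n_reps = 50, seed = 1)
  expect_false(pen$subsampled)
  expect_equal(pen$penalized_precision, pen$precision)
  expect_equal(pen$penalized_sensitivity, pen$sensitivity)
})

test_that("equal-scored surplus TPs with no FPs give penalized sensitivity exactly 1", {
  # 1000 true calls, 1500 true positives, all scores equal, no FPs:
  # each repetition retains N = 1000 of them, so sensitivity is exactly 1
  ann <- make_annotations(1000)
  lab <- make_labeled(rep(77, 1500), numeric(0),
                      call_keys = paste0("r1#", rep(1:1000, length.out = 1500)))
  pen <- subsample_penalty(lab, ann, n_reps = 20, seed = 3)
  expect_true(pen$subsampled)
  expect_equal(pen$penalized_sensitivity, 1.0)
  expect_equal(pen$sensitivity, 1.5)
})

test_that("penalized metrics converge to the exact subset enumeration mean", {
  # |TP| = 6 in two score strata with FPs between them; N = 4
  tp <- c(90, 88, 86, 40, 38, 36)
  fp <- c(60, 55)
  ann <- make_annotations(4)
  lab <- make_labeled(tp, fp, call_keys = paste0("r1#", c(1:4, 1, 2)))
  oracle <- oracle_penalty(tp, fp, 4)
  pen <- subsample_penalty(lab, ann, n_reps = 4000, seed = 5)
  expect_lt(abs(pen$penalized_precision - oracle$precision), 0.02)
  expect_lt(abs(pen$penalized_sensitivity - oracle$sensitivity), 0.02)
  expect_lte(pen$per_rep_sensitivity_max, 1)
})

test_that("the fixed-threshold penalty variant holds the threshold", {
  ann <- make_annotations(3)
  lab <- make_labeled(c(90, 80, 70, 60), c(50, 20),
                      call_keys = paste0("r1#", c(1, 2, 3, 1)))
  pen <- subsample_penalty(lab, ann, n_reps = 100, seed = 2,
                           recompute_threshold = FALSE, threshold = 65)
  expect_equal(pen$mean_threshold, 65)
  expect_error(subsample_penalty(lab, make_annotations(0)), "N = 0")
})
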