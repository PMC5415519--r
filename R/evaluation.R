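#' Label matches against ground-truth annotations
#'
#' Automates the manual verification step: a match that temporally
#' overlaps any true-call interval (any positive overlap, half-open
#' intervals) is a true positive, otherwise a false positive. In
#' `"per-match"` mode (the default) several matches may claim the same
#' call -- this reproduces conditional sensitivity above one when a
#' recognizer hits several syllables of one call. In `"per-call"` mode
#' matches are assigned one-to-one to calls greedily by descending score,
#' and surplus overlapping matches become false positives.
#'
#' @param matches match data frame (`recording_id`, `start_s`, `end_s`,
#'   `score`, ...).
#' @param annotations annotation data frame.
#' @param mode `"per-match"` or `"per-call"`.
#' @param recording_ids the known universe of recording identifiers
#'   (call-free recordings produce no annotation rows, so they must be
#'   declared here to be distinguishable from unknown recordings).
#'   Defaults to the union of ids seen in both tables.
#' @return The match data frame with `label` set to `"TP"`/`"FP"` and an
#'   added `call_key` column (annotation row key of the overlapped call,
#'   `NA` for FPs).
#' @export
label_matches <- function(matches, annotations,
                          mode = c("per-match", "per-call"),
                          recording_ids = union(matches$recording_id,
                                                annotations$recording_id)) {
  mode <- match.arg(mode)
  unknown <- setdiff(matches$recording_id, recording_ids)
  if (length(unknown) > 0L)
    stop("matches reference unknown recording_id(s): ",
         paste(unknown, collapse = ", "))
  if (nrow(matches) == 0L) {
    matches$label <- character(0)
    matches$call_key <- character(0)
    return(matches)
  }
  ann <- annotations
  ann_key <- if (nrow(ann) > 0)
    paste(ann$recording_id, seq_len(nrow(ann)), sep = "#") else character(0)

  matches$label <- "FP"
  matches$call_key <- NA_character_

  if (mode == "per-match") {
    for (i in seq_len(nrow(matches))) {
      cand <- which(ann$recording_id == matches$recording_id[i] &
                      ann$start_s < matches$end_s[i] &
                      ann$end_s > matches$start_s[i])
      if (length(cand) > 0L) {
        # attach the call with the largest overlap
        ov <- pmin(ann$end_s[cand], matches$end_s[i]) -
          pmax(ann$start_s[cand], matches$start_s[i])
        best <- cand[which.max(ov)]
        matches$label[i] <- "TP"
        matches$call_key[i] <- ann_key[best]
      }
    }
  } else {
    claimed <- logical(nrow(ann))
    ord <- order(-matches$score, matches$start_s)
    for (i in ord) {
      cand <- which(!claimed &
                      ann$recording_id == matches$recording_id[i] &
                      ann$start_s < matches$end_s[i] &
                      ann$end_s > matches$start_s[i])
      if (length(cand) > 0L) {
        ov <- pmin(ann$end_s[cand], matches$end_s[i]) -
          pmax(ann$start_s[cand], matches$start_s[i])
        best <- cand[which.max(ov)]
        claimed[best] <- TRUE
        matches$label[i] <- "TP"
        matches$call_key[i] <- ann_key[best]
      }
    }
  }
  matches
}

#' Confusion counts at a score threshold
#'
#' The four outcomes of a recognizer match at threshold `t`: `tp` and
#' `fp` are verified matches scoring at least `t`; `fn` is the number of
#' annotated calls not overlapped by any retained true positive; `tn` is
#' operationalized as verified false-positive matches scoring below the
#' threshold (the uncountable "sounds that are neither calls nor
#' matches" have no finite representation in open audio).
#'
#' @param labeled output of [label_matches()].
#' @param annotations annotation data frame.
#' @param t score threshold (matches with `score >= t` are retained).
#' @return List of class `"confusion_counts"`: `tp`, `fp`, `fn`, `tn`,
#'   `threshold`, `n_calls`.
#' @export
confusion_at_threshold <- function(labeled, annotations, t) {
  check_verified(labeled)
  n_calls <- nrow(annotations)
  keep <- labeled$score >= t
  tp <- sum(keep & labeled$label == "TP")
  fp <- sum(keep & labeled$label == "FP")
  tn <- sum(!keep & labeled$label == "FP")
  hit_calls <- unique(labeled$call_key[keep & labeled$label == "TP"])
  fn <- max(0L, n_calls - length(hit_calls[!is.na(hit_calls)]))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, threshold = t,
                 n_calls = n_calls),
            class = "confusion_counts")
}

check_verified <- function(labeled) {
  if (nrow(labeled) > 0 && !all(labeled$label %in% c("TP", "FP")))
    stop("matches must be verified (labels TP/FP); run label_matches()")
  if (nrow(labeled) > 0 && is.null(labeled$call_key))
    stop("labeled matches must carry call_key; run label_matches()")
  invisible(labeled)
}

#' Precision and sensitivity from confusion counts
#'
#' Precision = tp / (tp + fp), the probability a retained match is a true
#' call; 1 - precision is the Type I (false discovery) error rate.
#' Sensitivity = tp / n_calls with the denominator counting ALL true
#' calls, detected or not; it may exceed 1 in per-match mode when several
#' hits land on one multi-syllable call. Undefined values (zero
#' denominators) are returned as `NA` with a `defined` flag -- never as a
#' silent 0.
#'
#' @param counts a [confusion_at_threshold()] result.
#' @param n_calls total number of true calls (defaults to the count stored
#'   in `counts`).
#' @return List: `precision`, `sensitivity`, `precision_defined`,
#'   `sensitivity_defined`.
#' @export
point_metrics <- function(counts, n_calls = counts$n_calls) {
  prec_def <- (counts$tp + counts$fp) > 0
  sens_def <- n_calls > 0
  list(precision = if (prec_def) counts$tp / (counts$tp + counts$fp)
       else NA_real_,
       sensitivity = if (sens_def) counts$tp / n_calls else NA_real_,
       precision_defined = prec_def,
       sensitivity_defined = sens_def)
}

# Fast threshold sweep over verified scores. Returns the ROC coordinates
# at every unique observed score used as threshold (descending).
roc_points <- function(tp_scores, fp_scores) {
  thr <- sort(unique(c(tp_scores, fp_scores)), decreasing = TRUE)
  ntp <- length(tp_scores)
  nfp <- length(fp_scores)
  tpr <- vapply(thr, function(t) sum(tp_scores >= t), 0) / ntp
  tnr <- vapply(thr, function(t) sum(fp_scores < t), 0) / nfp
  list(thresholds = thr, tpr = tpr, tnr = tnr)
}

#' ROC curve, AUROC and Youden-optimal threshold
#'
#' Builds the match-level ROC over verified scores: positives are
#' verified TP matches, negatives verified FP matches. At each candidate
#' threshold `t` (the unique observed scores), `tpr = |TP >= t| / |TP|`
#' and `tnr = |FP < t| / |FP|`. AUROC is the trapezoidal integral over
#' `(1 - tnr, tpr)` and the operating threshold maximizes Youden's
#' `J = tpr + tnr - 1`, with ties broken towards the highest threshold by
#' default (favouring precision).
#'
#' @param labeled output of [label_matches()] (at least one TP and one FP
#'   required, otherwise the ROC is undefined and an error is thrown).
#' @param tie_break `"highest"` (default) or `"lowest"` threshold among
#'   the maximizers of J.
#' @return Object of class `"roc_curve"`: `thresholds` (descending),
#'   `tpr`, `tnr`, `fpr`, `youden_j`, `auroc`, `optimal_threshold`,
#'   `optimal_j`.
#' @export
roc_and_threshold <- function(labeled, tie_break = c("highest", "lowest")) {
  tie_break <- match.arg(tie_break)
  check_verified(labeled)
  tp_scores <- labeled$score[labeled$label == "TP"]
  fp_scores <- labeled$score[labeled$label == "FP"]
  roc_from_scores(tp_scores, fp_scores, tie_break)
}

roc_from_scores <- function(tp_scores, fp_scores,
                            tie_break = "highest") {
  if (length(tp_scores) == 0L || length(fp_scores) == 0L)
    stop("ROC undefined: need at least one verified TP and one FP match")
  pts <- roc_points(tp_scores, fp_scores)
  fpr <- 1 - pts$tnr
  # prepend the empty operating point (threshold above all scores)
  x <- c(0, fpr)
  y <- c(0, pts$tpr)
  auroc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  j <- pts$tpr + pts$tnr - 1
  jmax <- max(j)
  maximizers <- pts$thresholds[j >= jmax - 1e-12]
  opt <- if (tie_break == "highest") max(maximizers) else min(maximizers)
  structure(list(thresholds = pts$thresholds, tpr = pts$tpr,
                 tnr = pts$tnr, fpr = fpr, youden_j = j, auroc = auroc,
                 optimal_threshold = opt, optimal_j = jmax,
                 tie_break = tie_break),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "ROC over %d thresholds: AUROC %.3f, Youden J %.3f at threshold %.2f\n",
    length(x$thresholds), x$auroc, x$optimal_j, x$optimal_threshold))
  invisible(x)
}

#' Threshold-conditioned precision and sensitivity
#'
#' Precision and sensitivity conditioned on an operating score threshold
#' (typically the ROC/Youden threshold from [roc_and_threshold()]),
#' reported together with the corresponding error rates: Type I error =
#' 1 - precision, Type II error = 1 - sensitivity.
#'
#' @param labeled output of [label_matches()].
#' @param annotations annotation data frame.
#' @param threshold operating score threshold.
#' @return List of class `"conditional_metrics"`: `threshold`,
#'   `precision`, `sensitivity`, `type1_error`, `type2_error`, plus
#'   defined flags.
#' @export
conditional_metrics <- function(labeled, annotations, threshold) {
  cc <- confusion_at_threshold(labeled, annotations, threshold)
  pm <- point_metrics(cc)
  structure(list(threshold = threshold,
                 precision = pm$precision,
                 sensitivity = pm$sensitivity,
                 type1_error = 1 - pm$precision,
                 type2_error = 1 - pm$sensitivity,
                 precision_defined = pm$precision_defined,
                 sensitivity_defined = pm$sensitivity_defined),
            class = "conditional_metrics")
}

#' @export
print.conditional_metrics <- function(x, ...) {
  cat(sprintf(
    "Conditional metrics at threshold %.2f: precision %.3f, sensitivity %.3f\n",
    x$threshold, x$precision, x$sensitivity))
  invisible(x)
}

#' Multi-syllable subsampling penalty
#'
#' Penalizes recognizers that make several true-positive hits on
#' different syllables of the same call (which otherwise inflates
#' sensitivity above one). Per repetition, if the number of true-positive
#' matches exceeds `N` (the number of annotated calls), a uniform
#' without-replacement sample of `N` true positives is retained (all
#' false positives are kept), the ROC threshold is recomputed on the
#' reduced set, and the conditional metrics are recalculated. The
#' penalized metrics are the means over `n_reps` repetitions; every
#' per-repetition sensitivity is at most 1 by construction. When the ROC
#' is undefined within a repetition (no false positives), a threshold of
#' 0 is used so all retained matches count.
#'
#' @param labeled output of [label_matches()].
#' @param annotations annotation data frame; `N = nrow(annotations)` must
#'   be positive.
#' @param n_reps number of randomizations.
#' @param seed RNG seed.
#' @param recompute_threshold recompute the Youden threshold inside each
#'   repetition (default); if `FALSE`, `threshold` is held fixed.
#' @param threshold fixed threshold for `recompute_threshold = FALSE`.
#' @return Object of class `"penalized_metrics"`: `penalized_precision`,
#'   `penalized_sensitivity`, `mean_threshold`, `n_reps`, plus the
#'   unpenalized `precision`/`sensitivity`/`threshold` of the full match
#'   set for reference.
#' @export
subsample_penalty <- function(labeled, annotations, n_reps = 1000,
                              seed = 1L, recompute_threshold = TRUE,
                              threshold = NULL) {
  check_verified(labeled)
  N <- nrow(annotations)
  if (N == 0L) stop("subsample penalty undefined: no true calls (N = 0)")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!recompute_threshold && is.null(threshold))
    stop("a fixed 'threshold' is required when recompute_threshold = FALSE")

  tp_idx <- which(labeled$label == "TP")
  fp_scores <- labeled$score[labeled$label == "FP"]
  tp_scores_all <- labeled$score[tp_idx]
  n_tp <- length(tp_idx)

  # unpenalized reference metrics on the full set
  full_thr <- if (recompute_threshold && n_tp > 0 && length(fp_scores) > 0)
    roc_from_scores(tp_scores_all, fp_scores)$optimal_threshold
  else if (!recompute_threshold) threshold else 0
  full <- conditional_metrics(labeled, annotations, full_thr)

  set.seed(as.integer(seed))
  prec <- sens <- thr_used <- numeric(n_reps)
  subsampling <- n_tp > N
  for (r in seq_len(n_reps)) {
    tp_s <- if (subsampling)
      tp_scores_all[sample.int(n_tp, N)] else tp_scores_all
    t_r <- if (!recompute_threshold) threshold
    else if (length(tp_s) > 0 && length(fp_scores) > 0)
      roc_from_scores(tp_s, fp_scores)$optimal_threshold
    else 0
    ret_tp <- tp_s >= t_r
    n_ret_tp <- sum(ret_tp)
    n_ret_fp <- sum(fp_scores >= t_r)
    prec[r] <- if (n_ret_tp + n_ret_fp > 0)
      n_ret_tp / (n_ret_tp + n_ret_fp) else NA_real_
    sens[r] <- n_ret_tp / N
    thr_used[r] <- t_r
  }
  structure(list(penalized_precision = mean(prec, na.rm = TRUE),
                 penalized_sensitivity = mean(sens),
                 mean_threshold = mean(thr_used),
                 per_rep_sensitivity_max = max(sens),
                 n_reps = n_reps,
                 precision = full$precision,
                 sensitivity = full$sensitivity,
                 threshold = full_thr,
                 subsampled = subsampling),
            class = "penalized_metrics")
}

#' @export
print.penalized_metrics <- function(x, ...) {
  cat(sprintf(
    "Penalized metrics (%d reps%s): precision %.3f, sensitivity %.3f (raw %.3f / %.3f)\n",
    x$n_reps, if (x$subsampled) "" else ", no subsampling needed",
    x$penalized_precision, x$penalized_sensitivity, x$precision,
    x$sensitivity))
  invisible(x)
}
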