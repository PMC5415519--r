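#' Evaluate one recognizer variable across a grid of settings
#'
#' The local (one-variable-at-a-time) optimization step: each of the nine
#' build variables is evaluated independently across a grid of values
#' while all other variables are held at the base settings. For each
#' value the recognizer is rebuilt, run over the evaluation recordings,
#' its matches labelled against ground truth, and penalized conditional
#' metrics computed. By default matches are pooled across recordings
#' before thresholding (`summary_mode = "pooled"`); the per-recording
#' alternative computes metrics per recording and averages the defined
#' values.
#'
#' @param variable name of the variable to vary (one of
#'   [tunable_variables()]; the fixed band limits are rejected).
#' @param values grid of settings to test (length >= 2).
#' @param base_settings [recognizer_settings()] holding all other
#'   variables constant.
#' @param recordings evaluation recordings (with audio).
#' @param annotations ground-truth annotations for `recordings`.
#' @param train_recordings,train_annotations training data for the
#'   template; default to the evaluation data.
#' @param n_reps randomizations for the subsampling penalty.
#' @param seed RNG seed.
#' @param summary_mode `"pooled"` or `"per-recording"`.
#' @return Object of class `"setting_grid"`: a data frame of per-value
#'   means of (penalized) conditional precision and sensitivity, plus the
#'   grid metadata.
#' @export
evaluate_grid <- function(variable, values, base_settings, recordings,
                          annotations,
                          train_recordings = recordings,
                          train_annotations = annotations,
                          n_reps = 100, seed = 1L,
                          summary_mode = c("pooled", "per-recording")) {
  summary_mode <- match.arg(summary_mode)
  if (!variable %in% tunable_variables())
    stop("'", variable, "' is not tunable; the frequency band limits are ",
         "fixed and excluded from the sensitivity analysis")
  if (length(values) < 2L) stop("a grid needs at least 2 values")
  rec_ids <- vapply(recordings, function(r) r$recording_id, "")
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    s <- set_variable(base_settings, variable, values[i])
    template <- train_recognizer(train_recordings, train_annotations, s)
    matches <- detect_all(recordings, template, s)
    labeled <- label_matches(matches, annotations,
                             recording_ids = rec_ids)
    m <- summarize_labeled(labeled, annotations, rec_ids, n_reps, seed,
                           summary_mode)
    rows[[i]] <- data.frame(variable = variable, value = values[i],
                            precision = m$precision,
                            sensitivity = m$sensitivity,
                            penalized_precision = m$penalized_precision,
                            penalized_sensitivity = m$penalized_sensitivity,
                            threshold = m$threshold,
                            n_matches = nrow(labeled))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(variable = variable, values = values, metrics = out,
                 base_settings = base_settings,
                 summary_mode = summary_mode),
            class = "setting_grid")
}

# Penalized + raw conditional metrics for one labelled match set, either
# pooled or averaged per recording.
summarize_labeled <- function(labeled, annotations, rec_ids, n_reps,
                              seed, summary_mode) {
  no_metrics <- list(precision = NA_real_, sensitivity = NA_real_,
                     penalized_precision = NA_real_,
                     penalized_sensitivity = NA_real_,
                     threshold = NA_real_)
  if (summary_mode == "pooled") {
    if (nrow(annotations) == 0L) return(no_metrics)
    if (nrow(labeled) == 0L) {
      # a setting that detects nothing: sensitivity 0, precision undefined
      no_metrics$sensitivity <- 0
      no_metrics$penalized_sensitivity <- 0
      return(no_metrics)
    }
    p <- subsample_penalty(labeled, annotations, n_reps = n_reps,
                           seed = seed)
    list(precision = p$precision, sensitivity = p$sensitivity,
         penalized_precision = p$penalized_precision,
         penalized_sensitivity = p$penalized_sensitivity,
         threshold = p$threshold)
  } else {
    per <- lapply(rec_ids, function(rid) {
      lab <- labeled[labeled$recording_id == rid, , drop = FALSE]
      ann <- annotations[annotations$recording_id == rid, , drop = FALSE]
      if (nrow(lab) == 0L || nrow(ann) == 0L)
        return(NULL)
      p <- subsample_penalty(lab, ann, n_reps = n_reps, seed = seed)
      c(p$precision, p$sensitivity, p$penalized_precision,
        p$penalized_sensitivity, p$threshold)
    })
    per <- do.call(rbind, Filter(Negate(is.null), per))
    if (is.null(per)) return(no_metrics)
    m <- colMeans(per, na.rm = TRUE)
    list(precision = m[1], sensitivity = m[2],
         penalized_precision = m[3], penalized_sensitivity = m[4],
         threshold = m[5])
  }
}

#' @export
print.setting_grid <- function(x, ...) {
  cat(sprintf("Setting grid for '%s' (%d values, %s summary):\n",
              x$variable, length(x$values), x$summary_mode))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Coefficient of variation of grid metrics
#'
#' CV = sample standard deviation / mean of the per-value conditional
#' precision and sensitivity across a setting grid. The CV measures how
#' strongly a recognizer variable influences each metric; variables with
#' CV >= 0.1 are flagged as sensitive.
#'
#' @param grid a [evaluate_grid()] result.
#' @param use_penalized use penalized metrics (default) or raw ones.
#' @return List: `cv_precision`, `cv_sensitivity`, `sensitive_precision`,
#'   `sensitive_sensitivity` (the CV >= 0.1 flags). A non-positive or
#'   undefined mean yields `NA` (undefined marker).
#' @export
metric_cv <- function(grid, use_penalized = TRUE) {
  stopifnot(inherits(grid, "setting_grid"))
  m <- grid$metrics
  p <- if (use_penalized) m$penalized_precision else m$precision
  s <- if (use_penalized) m$penalized_sensitivity else m$sensitivity
  cv <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L || mean(x) <= 0) return(NA_real_)
    stats::sd(x) / mean(x)
  }
  cvp <- cv(p)
  cvs <- cv(s)
  list(cv_precision = cvp, cv_sensitivity = cvs,
       sensitive_precision = !is.na(cvp) && cvp >= 0.1,
       sensitive_sensitivity = !is.na(cvs) && cvs >= 0.1)
}

#' Rank recognizer variables by metric sensitivity
#'
#' @param grids list of [evaluate_grid()] results (one per variable).
#' @param use_penalized use penalized metrics (default).
#' @return Data frame (one row per variable) with `cv_precision`,
#'   `cv_sensitivity` and the CV >= 0.1 sensitivity flags, sorted by
#'   descending `cv_precision`.
#' @export
sensitivity_ranking <- function(grids, use_penalized = TRUE) {
  rows <- lapply(grids, function(g) {
    cv <- metric_cv(g, use_penalized)
    data.frame(variable = g$variable,
               cv_precision = cv$cv_precision,
               cv_sensitivity = cv$cv_sensitivity,
               sensitive_precision = cv$sensitive_precision,
               sensitive_sensitivity = cv$sensitive_sensitivity)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cv_precision), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative Type I / Type II error cost weights
#'
#' @param w_type1,w_type2 positive relative costs of Type I (false
#'   discovery) and Type II (missed call) errors. The standard monitoring
#'   objectives are (1, 1) balanced, (5, 1) Type-I-averse and (1, 5)
#'   Type-II-averse.
#' @return Object of class `"weight_scheme"`.
#' @export
weight_scheme <- function(w_type1 = 1, w_type2 = 1) {
  if (!is.finite(w_type1) || !is.finite(w_type2) ||
      w_type1 <= 0 || w_type2 <= 0)
    stop("weights must be positive")
  structure(list(w_type1 = as.numeric(w_type1),
                 w_type2 = as.numeric(w_type2)),
            class = "weight_scheme")
}

#' Default weight schemes
#'
#' The three monitoring objectives used for final recognizer selection:
#' equal weights, Type I errors weighted five times Type II, and the
#' reverse.
#' @return Named list of three [weight_scheme()] objects.
#' @export
default_weight_schemes <- function() {
  list(balanced = weight_scheme(1, 1),
       type1 = weight_scheme(5, 1),
       type2 = weight_scheme(1, 5))
}

#' Weighted average error rate
#'
#' `(w1 * (1 - precision) + w2 * (1 - sensitivity)) / (w1 + w2)`.
#' Sensitivity is clipped to `[0, 1]` before computing the Type II error
#' (multi-syllable hits can push raw sensitivity above 1, which would
#' otherwise produce a negative error). Normalizing by `w1 + w2` makes
#' schemes with different total weight comparable.
#'
#' @param precision precision in `[0, 1]` (vectorized).
#' @param sensitivity sensitivity (vectorized; values above 1 are
#'   clipped).
#' @param scheme a [weight_scheme()].
#' @return Weighted error in `[0, 1]`.
#' @export
weighted_error <- function(precision, sensitivity, scheme) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (any(precision < -1e-12 | precision > 1 + 1e-12, na.rm = TRUE))
    stop("precision must be in [0, 1]")
  s <- pmin(1, pmax(0, sensitivity))
  (scheme$w_type1 * (1 - precision) + scheme$w_type2 * (1 - s)) /
    (scheme$w_type1 + scheme$w_type2)
}

#' Select recognizer settings by weighted error
#'
#' For each variable's grid, picks the value minimizing the weighted
#' error of the (penalized) grid metrics under the given cost scheme,
#' breaking ties towards the value closest to the base setting, and
#' assembles the per-variable winners into one settings object. This is
#' local (per-variable) optimization, not a joint search over the full
#' settings space.
#'
#' @param grids list of [evaluate_grid()] results, one per tunable
#'   variable to select over.
#' @param scheme a [weight_scheme()].
#' @param base_settings base [recognizer_settings()]; variables without a
#'   grid keep their base value.
#' @param use_penalized use penalized metrics (default).
#' @return Object of class `"selected_recognizer"`: `settings`, `scheme`,
#'   `weighted_error` (mean of the per-variable minima), `choices`
#'   (per-variable table), `threshold` (`NA` until computed on training
#'   data by [finalize_recognizer()]).
#' @export
select_settings <- function(grids, scheme, base_settings,
                            use_penalized = TRUE) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (length(grids) == 0L) stop("no grids supplied")
  vars <- vapply(grids, function(g) g$variable, "")
  if (anyDuplicated(vars)) stop("duplicate grids for: ",
                                paste(vars[duplicated(vars)], collapse = ", "))
  settings <- base_settings
  choices <- list()
  errs <- numeric(0)
  for (g in grids) {
    m <- g$metrics
    p <- if (use_penalized) m$penalized_precision else m$precision
    s <- if (use_penalized) m$penalized_sensitivity else m$sensitivity
    we <- weighted_error(p, s, scheme)
    if (all(is.na(we)))
      stop("grid for '", g$variable, "' has no defined metrics")
    best <- min(we, na.rm = TRUE)
    cand <- which(!is.na(we) & we <= best + 1e-12)
    # tie-break: value closest to the base setting
    base_val <- as.numeric(base_settings[[g$variable]])
    pick <- cand[which.min(abs(as.numeric(m$value[cand]) - base_val))]
    settings <- set_variable(settings, g$variable, m$value[pick])
    errs <- c(errs, we[pick])
    choices[[g$variable]] <- data.frame(
      variable = g$variable, value = m$value[pick],
      weighted_error = we[pick])
  }
  structure(list(settings = settings, scheme = scheme,
                 weighted_error = mean(errs),
                 choices = do.call(rbind, choices),
                 threshold = NA_real_, threshold_source = "none",
                 template = NULL),
            class = "selected_recognizer")
}

#' Finalize a selected recognizer on training data
#'
#' Rebuilds the template with the selected settings, runs it over the
#' training recordings, and freezes the ROC/Youden operating threshold
#' determined there. The frozen threshold is what [evaluate_transfer()]
#' applies unchanged to new dataset groups.
#'
#' @param selected a [select_settings()] result.
#' @param train_recordings,train_annotations recordings and ground truth
#'   of the training dataset group.
#' @param template_recordings,template_annotations data used to build the
#'   template; default to the training group.
#' @return The `selected_recognizer` with `template`, `threshold`,
#'   `threshold_source = "train"` and train-set metrics filled in.
#' @export
finalize_recognizer <- function(selected, train_recordings,
                                train_annotations,
                                template_recordings = train_recordings,
                                template_annotations = train_annotations) {
  stopifnot(inherits(selected, "selected_recognizer"))
  s <- selected$settings
  template <- train_recognizer(template_recordings, template_annotations, s)
  matches <- detect_all(train_recordings, template, s)
  rec_ids <- vapply(train_recordings, function(r) r$recording_id, "")
  labeled <- label_matches(matches, train_annotations,
                           recording_ids = rec_ids)
  if (any(labeled$label == "TP") && any(labeled$label == "FP")) {
    roc <- roc_and_threshold(labeled)
    thr <- roc$optimal_threshold
    auroc <- roc$auroc
  } else {
    # degenerate training outcome (single match class): no threshold can
    # discriminate, so operate with all matches retained
    thr <- 0
    auroc <- NA_real_
  }
  cm <- conditional_metrics(labeled, train_annotations, thr)
  selected$template <- template
  selected$threshold <- thr
  selected$threshold_source <- "train"
  selected$train_metrics <- cm
  selected$train_auroc <- auroc
  selected
}

#' @export
print.selected_recognizer <- function(x, ...) {
  cat(sprintf(
    "Selected recognizer (weights %g:%g): mean weighted error %.3f\n",
    x$scheme$w_type1, x$scheme$w_type2, x$weighted_error))
  if (!is.na(x$threshold))
    cat(sprintf("  frozen threshold %.2f (source: %s)\n", x$threshold,
                x$threshold_source))
  print(x$choices, row.names = FALSE)
  invisible(x)
}
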