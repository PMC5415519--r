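#' Segment-based signal-to-noise ratio estimate
#'
#' Estimates SNR by randomly selecting two groups of one-second segments
#' from a recording -- one group overlapping annotated calls
#' (signal + noise) and one call-free group (noise only) -- measuring the
#' dB level of each (20 log10 RMS relative to full scale), and
#' subtracting the mean noise dB from the mean signal dB.
#'
#' @param recording a recording object with `samples`.
#' @param annotations annotation rows for this recording (used to
#'   classify segments).
#' @param n segments per group (default 10).
#' @param segment_s segment length in seconds (default 1).
#' @param seed RNG seed.
#' @return Object of class `"snr_estimate"`: `mean_signal_db`,
#'   `mean_noise_db`, `snr_db`, `n_segments_per_group`, `segment_s`.
#' @export
estimate_snr <- function(recording, annotations, n = 10, segment_s = 1,
                         seed = 1L) {
  if (is.null(recording$samples)) stop("recording carries no audio")
  fs <- recording$sample_rate_hz
  L <- round(segment_s * fs)
  n_seg <- floor(length(recording$samples) / L)
  if (n_seg < 2L) stop("recording too short for SNR segments")
  ann <- annotations[annotations$recording_id == recording$recording_id, ,
                     drop = FALSE]
  seg_start <- (seq_len(n_seg) - 1) * segment_s
  has_call <- vapply(seg_start, function(s0)
    nrow(ann) > 0 && any(ann$start_s < s0 + segment_s & ann$end_s > s0),
    logical(1))
  sig_idx <- which(has_call)
  noise_idx <- which(!has_call)
  if (length(sig_idx) < n)
    stop("insufficient call-containing time: ", length(sig_idx),
         " segment(s) available, ", n, " requested")
  if (length(noise_idx) < n)
    stop("insufficient call-free time: ", length(noise_idx),
         " segment(s) available, ", n, " requested")
  set.seed(as.integer(seed))
  sig_sel <- sample(sig_idx, n)
  noise_sel <- sample(noise_idx, n)
  seg_db <- function(i) {
    x <- recording$samples[((i - 1L) * L + 1L):(i * L)]
    20 * log10(max(sqrt(mean(x^2)), 1e-12))
  }
  ms <- mean(vapply(sig_sel, seg_db, 0))
  mn <- mean(vapply(noise_sel, seg_db, 0))
  structure(list(mean_signal_db = ms, mean_noise_db = mn,
                 snr_db = ms - mn, n_segments_per_group = n,
                 segment_s = segment_s),
            class = "snr_estimate")
}

#' @export
print.snr_estimate <- function(x, ...) {
  cat(sprintf("SNR estimate: %.2f dB (signal %.2f dB - noise %.2f dB; %d x %g-s segments per group)\n",
              x$snr_db, x$mean_signal_db, x$mean_noise_db,
              x$n_segments_per_group, x$segment_s))
  invisible(x)
}

#' Bootstrap confidence interval for a mean
#'
#' Bias-corrected and accelerated (BCa) bootstrap CI of the mean of a
#' sample of recording-level metrics, with a percentile fallback when the
#' acceleration is undefined (e.g. a constant sample). Implemented over
#' the boot package.
#'
#' @param values numeric sample (length >= 2).
#' @param n_reps bootstrap replicates.
#' @param method `"bca"` (default) or `"percentile"`.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return Object of class `"bootstrap_ci"`: `point` (sample mean),
#'   `lower`, `upper`, `n_reps`, `method` (the method actually used),
#'   `conf`, `seed`.
#' @export
bootstrap_ci <- function(values, n_reps = 2000,
                         method = c("bca", "percentile"), conf = 0.95,
                         seed = 1L) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("bootstrap CI needs at least 2 values")
  point <- mean(values)
  if (stats::sd(values) == 0)
    return(structure(list(point = point, lower = point, upper = point,
                          n_reps = n_reps, method = "degenerate",
                          conf = conf, seed = seed),
                     class = "bootstrap_ci"))
  set.seed(as.integer(seed))
  b <- boot::boot(values, function(d, i) mean(d[i]), R = n_reps)
  used <- method
  ci <- NULL
  if (method == "bca") {
    ci <- tryCatch({
      out <- suppressWarnings(boot::boot.ci(b, conf = conf, type = "bca"))
      out$bca[1, 4:5]
    }, error = function(e) NULL)
    if (is.null(ci)) used <- "percentile"
  }
  if (is.null(ci)) {
    ci <- tryCatch({
      out <- suppressWarnings(boot::boot.ci(b, conf = conf,
                                            type = "perc"))
      out$percent[1, 4:5]
    }, error = function(e) rep(point, 2))
  }
  structure(list(point = point, lower = unname(ci[1]),
                 upper = unname(ci[2]), n_reps = n_reps, method = used,
                 conf = conf, seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.0f%% %s bootstrap CI: %.4f (%.4f, %.4f), %d reps\n",
              100 * x$conf, x$method, x$point, x$lower, x$upper,
              x$n_reps))
  invisible(x)
}

#' Cumulative detection probability over repeated surveys
#'
#' The probability of detecting a species at least once in `N`
#' independent surveys, each with per-survey detection probability `p`:
#' `1 - (1 - p)^N`. With `p = 0.2` and 25 recordings this is 0.996,
#' which is why automated recorders on a dense schedule escape the
#' low-detectability problem of single manual surveys.
#'
#' @param p per-survey detection probability in \[0, 1\] (vectorized).
#' @param N non-negative integer number of surveys (vectorized).
#' @return Cumulative detection probability.
#' @export
cumulative_detection <- function(p, N) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p must be in [0, 1]")
  if (any(!is.finite(N)) || any(N < 0) || any(N != round(N)))
    stop("N must be a non-negative integer")
  1 - (1 - p)^N
}

#' Evaluate recognizers on transfer dataset groups
#'
#' Applies finalized recognizers -- with their training-derived operating
#' thresholds frozen -- to dataset groups, computing conditional
#' precision and sensitivity per recognizer and group at the frozen
#' threshold (no re-thresholding on test data), plus BCa bootstrap CIs
#' over recording-level metrics. Call-free recordings contribute only to
#' precision; recordings without matches contribute only to sensitivity.
#'
#' @param recognizers named list of [finalize_recognizer()] results; each
#'   must have `threshold_source == "train"` (asserted).
#' @param groups named list of `"dataset_group"` objects (see
#'   [build_dataset_groups()]).
#' @param n_boot bootstrap replicates for the CIs.
#' @param seed RNG seed.
#' @return Data frame: one row per recognizer x group with `precision`,
#'   `sensitivity`, their CI bounds, `threshold`, `n_calls`, `n_matches`.
#' @export
evaluate_transfer <- function(recognizers, groups, n_boot = 2000,
                              seed = 1L) {
  if (is.null(names(recognizers)))
    names(recognizers) <- paste0("recognizer", seq_along(recognizers))
  for (nm in names(recognizers)) {
    r <- recognizers[[nm]]
    stopifnot(inherits(r, "selected_recognizer"))
    if (!identical(r$threshold_source, "train") || is.na(r$threshold))
      stop("recognizer '", nm, "' has no frozen training threshold; ",
           "run finalize_recognizer() on the training group first")
  }
  rows <- list()
  k <- 0L
  for (nm in names(recognizers)) {
    r <- recognizers[[nm]]
    for (gl in names(groups)) {
      g <- groups[[gl]]
      rec_ids <- vapply(g$recordings, function(x) x$recording_id, "")
      matches <- detect_all(g$recordings, r$template, r$settings)
      labeled <- label_matches(matches, g$annotations,
                               recording_ids = rec_ids)
      cm <- conditional_metrics(labeled, g$annotations, r$threshold)
      per <- per_recording_metrics(labeled, g$annotations, rec_ids,
                                   r$threshold)
      k <- k + 1L
      seed_k <- (as.integer(seed) + 7L * k) %% .Machine$integer.max
      pci <- metric_ci(per$precision, n_boot, seed_k)
      sci <- metric_ci(per$sensitivity, n_boot, seed_k + 1L)
      rows[[k]] <- data.frame(
        recognizer = nm, group = gl,
        precision = cm$precision,
        precision_lower = pci[1], precision_upper = pci[2],
        sensitivity = if (nrow(g$annotations) > 0) cm$sensitivity
        else NA_real_,
        sensitivity_lower = sci[1], sensitivity_upper = sci[2],
        threshold = r$threshold,
        n_calls = nrow(g$annotations), n_matches = nrow(labeled))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

per_recording_metrics <- function(labeled, annotations, rec_ids,
                                  threshold) {
  prec <- sens <- rep(NA_real_, length(rec_ids))
  for (i in seq_along(rec_ids)) {
    lab <- labeled[labeled$recording_id == rec_ids[i], , drop = FALSE]
    ann <- annotations[annotations$recording_id == rec_ids[i], ,
                       drop = FALSE]
    cc <- confusion_at_threshold(lab, ann, threshold)
    pm <- point_metrics(cc)
    if (pm$precision_defined) prec[i] <- pm$precision
    if (pm$sensitivity_defined) sens[i] <- pm$sensitivity
  }
  list(precision = prec, sensitivity = sens)
}

metric_ci <- function(values, n_boot, seed) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(c(NA_real_, NA_real_))
  ci <- bootstrap_ci(values, n_reps = n_boot, seed = seed)
  c(ci$lower, ci$upper)
}
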