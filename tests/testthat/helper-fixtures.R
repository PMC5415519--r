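# Shared fixtures for the test suite; everything is generated in code.

# A small, fast scene configuration used by most audio tests.
tiny_scene_config <- function(...) {
  args <- list(n_sites = 2, duration_s = 20, calls_per_recording = 8,
               interferer_rate_per_min = 15, seed = 11)
  override <- list(...)
  args[names(override)] <- override
  do.call(scene_config, args)
}

# A hand-built labeled match table: scores + labels + call keys.
make_labeled <- function(tp_scores, fp_scores, recording_id = "r1",
                         call_keys = NULL) {
  n_tp <- length(tp_scores)
  n_fp <- length(fp_scores)
  if (is.null(call_keys))
    call_keys <- paste0(recording_id, "#", seq_len(n_tp))
  data.frame(
    recording_id = recording_id,
    start_s = seq_len(n_tp + n_fp),
    end_s = seq_len(n_tp + n_fp) + 0.5,
    score = c(tp_scores, fp_scores),
    label = c(rep("TP", n_tp), rep("FP", n_fp)),
    call_key = c(call_keys, rep(NA_character_, n_fp)),
    stringsAsFactors = FALSE)
}

# Annotation rows for n calls on one recording, placed apart.
make_annotations <- function(n, recording_id = "r1", site_id = "s1") {
  if (n == 0)
    return(data.frame(recording_id = character(), start_s = numeric(),
                      end_s = numeric(), n_syllables = integer(),
                      site_id = character(), year = character(),
                      group = character(), stringsAsFactors = FALSE))
  data.frame(recording_id = recording_id,
             start_s = (seq_len(n) - 1) * 2,
             end_s = (seq_len(n) - 1) * 2 + 0.5,
             n_syllables = rep(2L, n), site_id = site_id, year = "Y1",
             group = "train", stringsAsFactors = FALSE)
}

# Independent brute-force Youden sweep used as the ROC oracle.
oracle_youden <- function(tp_scores, fp_scores) {
  thr <- sort(unique(c(tp_scores, fp_scores)), decreasing = TRUE)
  best_j <- -Inf
  best_t <- NA_real_
  for (t in thr) {
    tpr <- mean(tp_scores >= t)
    tnr <- mean(fp_scores < t)
    j <- tpr + tnr - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && t > best_t)) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Exact enumeration oracle for the subsampling penalty: mean conditional
# metrics over every size-N subset of the TP matches.
oracle_penalty <- function(tp_scores, fp_scores, N) {
  subsets <- utils::combn(length(tp_scores), N)
  prec <- sens <- numeric(ncol(subsets))
  for (i in seq_len(ncol(subsets))) {
    tp_s <- tp_scores[subsets[, i]]
    t_i <- if (length(fp_scores) > 0)
      oracle_youden(tp_s, fp_scores)$threshold else 0
    ntp <- sum(tp_s >= t_i)
    nfp <- sum(fp_scores >= t_i)
    prec[i] <- if (ntp + nfp > 0) ntp / (ntp + nfp) else NA_real_
    sens[i] <- ntp / N
  }
  list(precision = mean(prec, na.rm = TRUE), sensitivity = mean(sens))
}
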