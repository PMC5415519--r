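#' Configuration for symbolic (audio-free) scored match tables
#'
#' A fast-path generator for the evaluation layer: instead of running a
#' recognizer over audio, match tables with verified labels are drawn
#' directly from a simple stochastic model of recognizer behaviour. True
#' calls yield a true-positive match unless missed; extra syllable-level
#' hits on the same call occur with `extra_hit_prob` (the mechanism behind
#' conditional sensitivity above one); false positives arrive at
#' `fp_per_min` in call-free time. Default score distributions put
#' true-positive scores well above false-positive scores but with enough
#' overlap that threshold choice matters.
#'
#' @param tp_score_mean,tp_score_sd mean and sd of true-positive scores
#'   (0-100 scale; draws are clipped to that range).
#' @param fp_per_min rate of false-positive matches per minute.
#' @param fp_score_mean,fp_score_sd mean and sd of false-positive scores.
#' @param extra_hit_prob probability that a detected call yields one extra
#'   syllable-level hit.
#' @param miss_prob probability that a true call yields no hit at all.
#' @param seed default RNG seed.
#' @return An object of class `"symbolic_match_config"`.
#' @export
symbolic_match_config <- function(tp_score_mean = 65, tp_score_sd = 12,
                                  fp_per_min = 4,
                                  fp_score_mean = 35, fp_score_sd = 12,
                                  extra_hit_prob = 0.25, miss_prob = 0.25,
                                  seed = 1L) {
  cfg <- list(tp_score_mean = as.numeric(tp_score_mean),
              tp_score_sd = as.numeric(tp_score_sd),
              fp_per_min = as.numeric(fp_per_min),
              fp_score_mean = as.numeric(fp_score_mean),
              fp_score_sd = as.numeric(fp_score_sd),
              extra_hit_prob = as.numeric(extra_hit_prob),
              miss_prob = as.numeric(miss_prob),
              seed = as.integer(seed))
  if (cfg$extra_hit_prob < 0 || cfg$extra_hit_prob > 1)
    stop("extra_hit_prob must be in [0, 1]")
  if (cfg$miss_prob < 0 || cfg$miss_prob > 1)
    stop("miss_prob must be in [0, 1]")
  if (cfg$fp_per_min < 0) stop("fp_per_min must be >= 0")
  if (cfg$tp_score_sd < 0 || cfg$fp_score_sd < 0)
    stop("score sds must be >= 0")
  class(cfg) <- "symbolic_match_config"
  cfg
}

#' Generate a verified match table without audio
#'
#' Draws a scored match table from [symbolic_match_config()] against a
#' ground-truth annotation table. Each non-missed call yields one
#' true-positive match overlapping it (plus, with `extra_hit_prob`, one
#' extra hit on the same call); false positives are placed uniformly in
#' call-free time at `fp_per_min`. Labels are set to `"TP"`/`"FP"`.
#'
#' @param cfg a [symbolic_match_config()].
#' @param annotations annotation data frame (`recording_id`, `start_s`,
#'   `end_s`, `n_syllables`, ...).
#' @param recording_ids recordings to generate matches for (includes
#'   call-free recordings); defaults to the recordings present in
#'   `annotations`.
#' @param duration_s duration of each recording in seconds (scalar or
#'   named vector over `recording_ids`).
#' @param seed RNG seed; output is deterministic given `(cfg, seed)`.
#' @return A match data frame: `recording_id`, `start_s`, `end_s`,
#'   `score`, `label`.
#' @export
synth_match_table <- function(cfg, annotations,
                              recording_ids = unique(annotations$recording_id),
                              duration_s = 300, seed = cfg$seed) {
  stopifnot(inherits(cfg, "symbolic_match_config"))
  set.seed(as.integer(seed))
  if (length(duration_s) == 1L) {
    duration_s <- stats::setNames(rep(duration_s, length(recording_ids)),
                                  recording_ids)
  }
  out <- list()
  for (rid in recording_ids) {
    ann <- annotations[annotations$recording_id == rid, , drop = FALSE]
    dur <- unname(duration_s[rid])
    rows <- list()
    if (nrow(ann) > 0) {
      for (i in seq_len(nrow(ann))) {
        if (stats::runif(1) < cfg$miss_prob) next
        n_hits <- 1L + (stats::runif(1) < cfg$extra_hit_prob)
        for (h in seq_len(n_hits)) {
          # hit interval: the call (or one syllable-sized slice of it)
          if (h == 1L) {
            s0 <- ann$start_s[i]; s1 <- ann$end_s[i]
          } else {
            w <- min(0.08, ann$end_s[i] - ann$start_s[i])
            s0 <- stats::runif(1, ann$start_s[i], ann$end_s[i] - w)
            s1 <- s0 + w
          }
          sc <- clip_score(stats::rnorm(1, cfg$tp_score_mean,
                                        cfg$tp_score_sd))
          rows[[length(rows) + 1L]] <-
            data.frame(recording_id = rid, start_s = s0, end_s = s1,
                       score = sc, label = "TP",
                       stringsAsFactors = FALSE)
        }
      }
    }
    n_fp <- stats::rpois(1, cfg$fp_per_min * dur / 60)
    if (n_fp > 0) {
      placed <- 0L
      guard <- 0L
      while (placed < n_fp && guard < 50L * n_fp) {
        guard <- guard + 1L
        w <- 0.15
        s0 <- stats::runif(1, 0, max(0, dur - w))
        s1 <- s0 + w
        overlaps_call <- nrow(ann) > 0 &&
          any(ann$start_s < s1 & ann$end_s > s0)
        if (overlaps_call) next
        sc <- clip_score(stats::rnorm(1, cfg$fp_score_mean,
                                      cfg$fp_score_sd))
        rows[[length(rows) + 1L]] <-
          data.frame(recording_id = rid, start_s = s0, end_s = s1,
                     score = sc, label = "FP", stringsAsFactors = FALSE)
        placed <- placed + 1L
      }
    }
    if (length(rows) > 0) out[[rid]] <- do.call(rbind, rows)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else empty_matches()
  rownames(res) <- NULL
  res[order(res$recording_id, res$start_s), , drop = FALSE]
}

clip_score <- function(x) pmin(100, pmax(0, x))

empty_matches <- function() {
  data.frame(recording_id = character(), start_s = numeric(),
             end_s = numeric(), score = numeric(), label = character(),
             stringsAsFactors = FALSE)
}
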