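test_that("settings validation enforces the documented invariants", {
  expect_error(recognizer_settings(fft_size = 300), "power of 2")
  expect_error(recognizer_settings(fft_overlap = 1), "\\[0, 1\\)")
  expect_error(recognizer_settings(min_syllables = 0), ">= 1")
  expect_error(recognizer_settings(band_min_hz = 3000,
                                   band_max_hz = 2000), "band")
  expect_length(tunable_variables(), 9)
})

test_that("syllable segmentation merges and rejects as specified", {
  st <- recognizer_settings(max_syllable_gap_ms = 50,
                            max_syllable_ms = 400)
  step <- 0.010
  base <- rep(0, 100)

  # all frames below threshold -> empty
  expect_equal(nrow(segment_syllables(base, st, step)), 0)

  # two bursts 30 ms apart merge into one syllable under a 50 ms gap
  x <- base
  x[c(11:14, 18:21)] <- 20  # 30 ms gap (3 frames)
  seg <- segment_syllables(x, st, step)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_bursts, 2L)

  # same bursts with a 10 ms cap stay separate
  st10 <- recognizer_settings(max_syllable_gap_ms = 10)
  seg2 <- segment_syllables(x, st10, step)
  expect_equal(nrow(seg2), 2)

  # over-long syllables are discarded
  x3 <- base
  x3[11:90] <- 20  # 800 ms burst
  expect_equal(nrow(segment_syllables(x3, st, step)), 0)
})

test_that("syllable count steps from 3 to 1 exactly when the gap setting crosses the true gap", {
  # constructed 3-burst signal with 40 ms bursts and 60 ms true gaps
  step <- 0.010
  x <- rep(0, 120)
  for (k in 0:2) x[(11 + k * 10):(14 + k * 10)] <- 20
  # true gap: 6 below-threshold frames = 60 ms
  counts <- vapply(c(30, 50, 59, 60, 80), function(gap) {
    st <- recognizer_settings(max_syllable_gap_ms = gap,
                              max_syllable_ms = 1000)
    nrow(segment_syllables(x, st, step))
  }, 0L)
  expect_equal(counts, c(3L, 3L, 3L, 1L, 1L))
})

test_that("template training equals the mean of per-call features", {
  cfg <- tiny_scene_config(n_sites = 1, duration_s = 20,
                           calls_per_recording = 6,
                           interferer_rate_per_min = 0)
  sc <- synth_scene(cfg, seed = 8)
  st <- recognizer_settings()
  ann <- sc$annotations

  # mean of one: the template is that call's own feature summary
  t1 <- train_recognizer(sc$recordings, ann[1, ], st)
  expect_equal(t1$n_training_calls, 1)

  # duplicating the call list leaves the template unchanged
  t_all <- train_recognizer(sc$recordings, ann, st)
  t_dup <- train_recognizer(sc$recordings, rbind(ann, ann), st)
  expect_equal(t_all$feature, t_dup$feature, tolerance = 1e-12)

  # two calls: template equals the elementwise average of their features
  ta <- train_recognizer(sc$recordings, ann[1, ], st)
  tb <- train_recognizer(sc$recordings, ann[2, ], st)
  tab <- train_recognizer(sc$recordings, ann[1:2, ], st)
  expect_equal(tab$feature, (ta$feature + tb$feature) / 2,
               tolerance = 1e-12)

  expect_error(train_recognizer(sc$recordings, ann[0, ], st),
               "at least one annotated call")
})

test_that("detection scores are bounded and self-detection is perfect", {
  cfg <- tiny_scene_config(n_sites = 1, duration_s = 10,
                           calls_per_recording = 1,
                           interferer_rate_per_min = 0, snr_db = 30)
  sc <- synth_scene(cfg, seed = 12, ensure_calls = TRUE)
  st <- recognizer_settings()
  # template trained on the first call alone
  tmpl <- train_recognizer(sc$recordings, sc$annotations[1, ], st)
  m <- detect(sc$recordings[[1]], tmpl, st)
  expect_gt(nrow(m), 0)
  expect_true(all(m$score > 0 & m$score <= 100))
  ann1 <- sc$annotations[1, ]
  self <- m$start_s < ann1$end_s & m$end_s > ann1$start_s
  # the training call detects itself with a perfect score
  expect_equal(max(m$score[self]), 100, tolerance = 1e-6)
})

test_that("detection enforces settings fingerprint and sample rate", {
  cfg <- tiny_scene_config(n_sites = 1, duration_s = 8,
                           calls_per_recording = 3)
  sc <- synth_scene(cfg, seed = 13)
  st <- recognizer_settings()
  tmpl <- train_recognizer(sc$recordings, sc$annotations, st)
  st2 <- recognizer_settings(dynamic_range_db = 60)
  expect_error(detect(sc$recordings[[1]], tmpl, st2), "fingerprint")
  rec2 <- sc$recordings[[1]]
  rec2$sample_rate_hz <- 16000
  expect_error(detect(rec2, tmpl, st), "sample rate")
})

test_that("a calibrated scene at high SNR has every call overlapped by a match", {
  cfg <- tiny_scene_config(n_sites = 1, duration_s = 60,
                           calls_per_recording = 20, snr_db = 13,
                           interferer_rate_per_min = 2)
  sc <- synth_scene(cfg, seed = 14)
  st <- recognizer_settings()
  tmpl <- train_recognizer(sc$recordings, sc$annotations, st)
  m <- detect_all(sc$recordings, tmpl, st)
  ann <- sc$annotations
  hit <- vapply(seq_len(nrow(ann)), function(i)
    any(m$recording_id == ann$recording_id[i] &
          m$start_s < ann$end_s[i] & m$end_s > ann$start_s[i]),
    logical(1))
  # overlapping calls can merge into a single match; require near-total
  # coverage of annotated calls
  expect_gte(mean(hit), 0.9)
})

test_that("small gap settings produce per-syllable hits on multi-syllable calls", {
  cfg <- tiny_scene_config(n_sites = 1, duration_s = 30,
                           calls_per_recording = 6,
                           syllable_count_probs = c(0, 0, 0, 1),
                           interferer_rate_per_min = 0)
  sc <- synth_scene(cfg, seed = 15)
  st <- recognizer_settings(max_syllable_gap_ms = 10, min_syllables = 1,
                            max_syllable_ms = 120)
  tmpl <- train_recognizer(sc$recordings, sc$annotations, st)
  m <- detect_all(sc$recordings, tmpl, st)
  lab <- label_matches(m, sc$annotations)
  hits_per_call <- table(lab$call_key[lab$label == "TP"])
  expect_gt(max(hits_per_call), 1)
  expect_lte(max(hits_per_call), 4)
  # conditional sensitivity above one, the multi-syllable phenomenon
  cm <- conditional_metrics(lab, sc$annotations, 0)
  expect_gt(cm$sensitivity, 1)
})

test_that("per-call match scores degrade as SNR decreases", {
  # fixed 4-syllable calls so the only thing changing across levels is
  # noise; score per call = best overlapping match (0 when missed)
  mean_scores <- vapply(c(13, 8, 3), function(snr) {
    scores <- c()
    for (s in 1:6) {
      cfg <- tiny_scene_config(n_sites = 1, duration_s = 20,
                               calls_per_recording = 6, snr_db = snr,
                               syllable_count_probs = c(0, 0, 0, 1),
                               interferer_rate_per_min = 0)
      sc <- synth_scene(cfg, seed = 100 * s + snr)
      st <- recognizer_settings()
      tmpl <- train_recognizer(sc$recordings, sc$annotations, st)
      m <- detect_all(sc$recordings, tmpl, st)
      ann <- sc$annotations
      best <- vapply(seq_len(nrow(ann)), function(i) {
        ov <- m$start_s < ann$end_s[i] & m$end_s > ann$start_s[i]
        if (any(ov)) max(m$score[ov]) else 0
      }, 0)
      scores <- c(scores, best)
    }
    mean(scores)
  }, 0)
  expect_gte(mean_scores[1], mean_scores[2] - 1)
  expect_gte(mean_scores[2], mean_scores[3] - 1)
  expect_gt(mean_scores[1], mean_scores[3])
})
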