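# Number of time columns in every feature summary; fixed so that feature
# matrices from calls of different lengths are comparable.
FEATURE_TIME_BINS <- 16L

# Fixed offset (dB) of the adaptive detection threshold above the
# post-filter median band energy. A documented constant, not a tunable, so
# the tunable set stays at exactly nine variables.
THRESHOLD_OFFSET_DB <- 6

# Compute the processed band-limited spectrogram of a waveform:
# Hann-window STFT -> dB -> band rows -> running-mean background
# subtraction per frequency row -> dynamic-range clamp -> per-frame band
# energy (dB of summed linear power).
processed_spectrogram <- function(samples, fs, settings) {
  s <- settings
  if (length(samples) < s$fft_size)
    samples <- c(samples, numeric(s$fft_size - length(samples)))
  step <- max(1L, round(s$fft_size * (1 - s$fft_overlap)))
  sp <- signal::specgram(samples, n = s$fft_size, Fs = fs,
                         window = signal::hanning(s$fft_size),
                         overlap = s$fft_size - step)
  P <- 20 * log10(pmax(abs(sp$S), 1e-12))
  freqs <- sp$f
  band <- which(freqs >= s$band_min_hz & freqs <= s$band_max_hz)
  if (length(band) < 1L)
    stop("detection band contains no spectrogram rows at this sample rate")
  P <- P[band, , drop = FALSE]
  step_s <- step / fs
  # background filter: subtract running mean over time in each row
  # (window clamped to >= 3 frames so the filter never cancels the signal)
  w <- max(3L, round(s$background_filter_s / step_s))
  P <- P - t(apply(P, 1L, running_mean, w = w))
  # dynamic range clamp relative to the per-recording maximum
  floor_db <- max(P) - s$dynamic_range_db
  P[P < floor_db] <- floor_db
  energy_db <- 10 * log10(colSums(10^(P / 10)))
  list(P = P, energy_db = energy_db, step_s = step_s,
       window_s = s$fft_size / fs, freqs = freqs[band], fs = fs)
}

# Centered running mean with edge shrinkage (partial windows at the ends).
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  w <- min(w, n)
  h1 <- (w - 1L) %/% 2L
  h2 <- w - 1L - h1
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - h1)
  hi <- pmin(n, seq_len(n) + h2)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Segment above-threshold frames into syllables
#'
#' Applies the adaptive detection threshold (median band energy + 6 dB) to
#' a per-frame band energy vector and merges above-threshold runs into
#' syllable intervals. Silent gaps no longer than `max_syllable_gap_ms`
#' are bridged into a single syllable; the number of original bursts each
#' syllable absorbed is retained (`n_bursts`), which is what
#' `min_syllables` counts at the song-assembly stage. Syllables longer
#' than `max_syllable_ms` are discarded.
#'
#' @param band_energy_db numeric vector of per-frame band energy (dB).
#' @param settings a [recognizer_settings()] object.
#' @param step_s frame step in seconds.
#' @param window_s analysis window length in seconds (a frame covers
#'   `[start, start + window_s)`).
#' @param t0 time (s) of the first frame's start.
#' @return Data frame with columns `start_s`, `end_s`, `n_bursts`,
#'   `first_frame`, `last_frame`, sorted and non-overlapping. Empty input
#'   or no frames above threshold gives zero rows.
#' @export
segment_syllables <- function(band_energy_db, settings, step_s,
                              window_s = step_s, t0 = 0) {
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_bursts = integer(), first_frame = integer(),
                      last_frame = integer())
  n <- length(band_energy_db)
  if (n == 0L) return(empty)
  thr <- stats::median(band_energy_db) + THRESHOLD_OFFSET_DB
  above <- band_energy_db > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(first = starts[r$values], last = ends[r$values])
  # bridge gaps <= max_syllable_gap_ms
  merged <- list(runs[1L, ])
  n_bursts <- 1L
  bursts <- integer(0)
  for (i in seq_len(nrow(runs))[-1L]) {
    cur <- merged[[length(merged)]]
    gap_ms <- (runs$first[i] - cur$last - 1L) * step_s * 1000
    if (gap_ms <= settings$max_syllable_gap_ms) {
      cur$last <- runs$last[i]
      merged[[length(merged)]] <- cur
      n_bursts <- n_bursts + 1L
    } else {
      bursts <- c(bursts, n_bursts)
      merged[[length(merged) + 1L]] <- runs[i, ]
      n_bursts <- 1L
    }
  }
  bursts <- c(bursts, n_bursts)
  m <- do.call(rbind, merged)
  out <- data.frame(
    start_s = t0 + (m$first - 1L) * step_s,
    end_s = t0 + (m$last - 1L) * step_s + window_s,
    n_bursts = bursts,
    first_frame = m$first, last_frame = m$last)
  keep <- (out$end_s - out$start_s) * 1000 <= settings$max_syllable_ms
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Assemble syllables into candidate songs: consecutive syllables with
# inter-syllable gaps <= max_syllable_gap_ms, total span <= max_song_ms,
# total burst count >= min_syllables.
assemble_songs <- function(syllables, settings) {
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_syllables = integer(), first_frame = integer(),
                      last_frame = integer())
  if (nrow(syllables) == 0L) return(empty)
  songs <- list()
  cur <- syllables[1L, ]
  cur_n <- syllables$n_bursts[1L]
  for (i in seq_len(nrow(syllables))[-1L]) {
    gap_ms <- (syllables$start_s[i] - cur$end_s) * 1000
    span_ms <- (syllables$end_s[i] - cur$start_s) * 1000
    if (gap_ms <= settings$max_syllable_gap_ms &&
        span_ms <= settings$max_song_ms) {
      cur$end_s <- syllables$end_s[i]
      cur$last_frame <- syllables$last_frame[i]
      cur_n <- cur_n + syllables$n_bursts[i]
    } else {
      songs[[length(songs) + 1L]] <- cbind(cur, n_total = cur_n)
      cur <- syllables[i, ]
      cur_n <- syllables$n_bursts[i]
    }
  }
  songs[[length(songs) + 1L]] <- cbind(cur, n_total = cur_n)
  out <- do.call(rbind, songs)
  keep <- out$n_total >= settings$min_syllables &
    (out$end_s - out$start_s) * 1000 <= settings$max_song_ms
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  data.frame(start_s = out$start_s, end_s = out$end_s,
             n_syllables = as.integer(out$n_total),
             first_frame = out$first_frame, last_frame = out$last_frame)
}

# Resampling of a matrix to (nr x nc); the feature summary compared
# against the template. Downsampling uses block means (a narrow spectral
# line must contribute to its band, not be aliased past by
# point-sampling); upsampling uses linear interpolation.
resample_axis <- function(v, len) {
  n <- length(v)
  if (n == len) return(v)
  if (n == 1L) return(rep(v, len))
  if (n > len) {
    g <- findInterval((seq_len(n) - 0.5) / n,
                      seq(0, 1, length.out = len + 1),
                      rightmost.closed = TRUE)
    as.numeric(tapply(v, g, mean))
  } else {
    stats::approx(seq_len(n), v, n = len)$y
  }
}

resample_matrix <- function(M, nr, nc) {
  M1 <- t(apply(M, 1L, resample_axis, len = nc))
  if (nrow(M) == 1L) M1 <- matrix(M1, nrow = 1L)
  M2 <- apply(M1, 2L, resample_axis, len = nr)
  if (nr == 1L) M2 <- matrix(M2, nrow = 1L)
  M2
}

# Feature summary for a frame range of a processed spectrogram.
extract_feature <- function(ps, first_frame, last_frame, settings) {
  sub <- ps$P[, first_frame:last_frame, drop = FALSE]
  resample_matrix(sub, settings$feature_vector_length, FEATURE_TIME_BINS)
}

# Frame range covering a time interval, trimmed to above-threshold frames
# when any exist (so training features line up with detected songs).
interval_frames <- function(ps, start_s, end_s) {
  nf <- length(ps$energy_db)
  fstart <- (seq_len(nf) - 1L) * ps$step_s
  fend <- fstart + ps$window_s
  inside <- which(fstart < end_s & fend > start_s)
  if (length(inside) == 0L) return(NULL)
  thr <- stats::median(ps$energy_db) + THRESHOLD_OFFSET_DB
  hot <- inside[ps$energy_db[inside] > thr]
  if (length(hot) > 0L) range(hot) else range(inside)
}

#' Train a template recognizer from annotated calls
#'
#' Builds the recognizer model: the elementwise mean, over all annotated
#' training calls, of a fixed-size feature summary (band-limited processed
#' spectrogram resampled to `feature_vector_length` frequency rows by a
#' fixed number of time columns). Candidate sounds are later scored by
#' normalized cross-correlation against this template.
#'
#' @param recordings list of recording objects (as produced by
#'   [synth_scene()] or [read_wav()]) containing the training calls.
#' @param annotations annotation data frame; every row must lie inside its
#'   recording.
#' @param settings a [recognizer_settings()] object.
#' @return An object of class `"recognizer_template"` with elements
#'   `feature` (matrix), `fingerprint`, `n_training_calls`,
#'   `sample_rate_hz` and `settings`.
#' @export
train_recognizer <- function(recordings, annotations, settings) {
  validate_recognizer_settings(settings)
  if (is.null(annotations) || nrow(annotations) == 0L)
    stop("train_recognizer requires at least one annotated call")
  recs <- recording_index(recordings)
  fs <- unique(vapply(recs, function(r) r$sample_rate_hz, 0))
  if (length(fs) != 1L)
    stop("all training recordings must share one sample rate")
  feats <- list()
  for (rid in unique(annotations$recording_id)) {
    rec <- recs[[rid]]
    if (is.null(rec))
      stop("annotation references unknown recording '", rid, "'")
    ann <- annotations[annotations$recording_id == rid, , drop = FALSE]
    if (any(ann$end_s > rec$duration_s + 1e-9) || any(ann$start_s < 0))
      stop("annotation outside recording '", rid, "'")
    ps <- processed_spectrogram(rec$samples, fs, settings)
    for (i in seq_len(nrow(ann))) {
      fr <- interval_frames(ps, ann$start_s[i], ann$end_s[i])
      if (is.null(fr)) next
      feats[[length(feats) + 1L]] <-
        extract_feature(ps, fr[1L], fr[2L], settings)
    }
  }
  if (length(feats) == 0L)
    stop("no training call produced a feature summary")
  template <- Reduce(`+`, feats) / length(feats)
  structure(list(feature = template,
                 fingerprint = settings_fingerprint(settings),
                 n_training_calls = length(feats),
                 sample_rate_hz = fs,
                 settings = settings),
            class = "recognizer_template")
}

#' @export
print.recognizer_template <- function(x, ...) {
  cat(sprintf(
    "Recognizer template: %d x %d feature matrix from %d training call(s) @ %.0f Hz\n",
    nrow(x$feature), ncol(x$feature), x$n_training_calls,
    x$sample_rate_hz))
  invisible(x)
}

#' Detect and score candidate calls in a recording
#'
#' Runs the two-step recognition process: detection (adaptive energy
#' threshold, syllable segmentation, song assembly under the temporal
#' settings) followed by scoring (100 x the non-negative normalized
#' cross-correlation between the candidate's feature summary and the
#' template). Candidates scoring 0 are dropped; all others are returned
#' with `label = "unverified"`.
#'
#' @param recording a recording object with `samples`.
#' @param template a [train_recognizer()] template.
#' @param settings the same [recognizer_settings()] used to build the
#'   template (enforced via the stored fingerprint).
#' @return Match data frame: `recording_id`, `start_s`, `end_s`, `score`
#'   (in `(0, 100]`), `label`.
#' @export
detect <- function(recording, template, settings = template$settings) {
  stopifnot(inherits(template, "recognizer_template"))
  validate_recognizer_settings(settings)
  if (!identical(settings_fingerprint(settings), template$fingerprint))
    stop("settings do not match the template's settings fingerprint")
  if (abs(recording$sample_rate_hz - template$sample_rate_hz) > 1e-9)
    stop("recording sample rate (", recording$sample_rate_hz,
         " Hz) differs from template training data (",
         template$sample_rate_hz, " Hz)")
  ps <- processed_spectrogram(recording$samples, recording$sample_rate_hz,
                              settings)
  syl <- segment_syllables(ps$energy_db, settings, ps$step_s, ps$window_s)
  songs <- assemble_songs(syl, settings)
  if (nrow(songs) == 0L) return(empty_matches())
  score <- vapply(seq_len(nrow(songs)), function(i) {
    feat <- extract_feature(ps, songs$first_frame[i], songs$last_frame[i],
                            settings)
    score_feature(feat, template$feature)
  }, 0)
  out <- data.frame(recording_id = recording$recording_id,
                    start_s = songs$start_s, end_s = songs$end_s,
                    score = score, label = "unverified",
                    stringsAsFactors = FALSE)
  out <- out[out$score > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

score_feature <- function(feat, template) {
  a <- as.vector(feat)
  b <- as.vector(template)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  100 * max(0, stats::cor(a, b))
}

#' Detect over a list of recordings
#'
#' @param recordings list of recording objects.
#' @inheritParams detect
#' @return Combined match data frame.
#' @export
detect_all <- function(recordings, template, settings = template$settings) {
  out <- lapply(recordings, detect, template = template,
                settings = settings)
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_matches()
  rownames(res) <- NULL
  res
}

recording_index <- function(recordings) {
  if (inherits(recordings, "frog_recording"))
    recordings <- list(recordings)
  stats::setNames(recordings,
                  vapply(recordings, function(r) r$recording_id, ""))
}
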