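#' Synthesize an annotated chorus scene
#'
#' Generates mono recordings containing bursts of 1-4 syllable calls on a
#' noise background, together with a ground-truth annotation table that
#' exactly describes the emitted calls. Call dominant frequency is drawn
#' hierarchically: population mean + site effect + recording effect + call
#' effect, each Gaussian with the standard deviations in the config. The
#' background noise gain is calibrated per recording so that the realized
#' segment-based SNR (as measured by [estimate_snr()]) matches
#' `config$snr_db`. Non-target interferers (in-band tonal pulses and
#' out-of-band chirps) are added at `interferer_rate_per_min` and are not
#' annotated.
#'
#' @param config a [scene_config()] object.
#' @param seed integer RNG seed; identical `(config, seed)` give
#'   bit-identical output.
#' @param audio if `FALSE`, only the annotation table and recording
#'   metadata are generated (fast path for symbolic experiments).
#' @param site_ids optional character vector of site identifiers (length
#'   `n_sites`); defaults to `"S1" ... "Sn"`.
#' @param site_effects optional named numeric vector of pre-drawn site
#'   frequency effects (Hz) for the given `site_ids`; used by
#'   [build_dataset_groups()] to keep site identity consistent across
#'   years. Missing sites get fresh draws.
#' @param year_label year identifier attached to all recordings.
#' @param group_label dataset group label attached to all recordings.
#' @param recording_prefix prefix for recording identifiers.
#' @param calls_per_recording_vec optional per-recording override of the
#'   Poisson mean (e.g. zeros for call-free recordings).
#' @param ensure_calls if `TRUE`, recordings with a positive mean draw a
#'   zero-truncated Poisson count, guaranteeing at least one call (used
#'   by [build_dataset_groups()] to honour the with-calls/without-calls
#'   split).
#'
#' @return An object of class `"synthetic_scene"`: a list with elements
#'   `recordings` (list of recording objects with `samples` when
#'   `audio = TRUE`), `annotations` (data frame: `recording_id`,
#'   `start_s`, `end_s`, `n_syllables`, `site_id`, `year`, `group`,
#'   `freq_hz`), `site_effects`, `config`, and `seed`.
#' @export
synth_scene <- function(config, seed = config$seed, audio = TRUE,
                        site_ids = NULL, site_effects = NULL,
                        year_label = "Y1", group_label = "train",
                        recording_prefix = NULL,
                        calls_per_recording_vec = NULL,
                        ensure_calls = FALSE) {
  validate_scene_config(config)
  set.seed(as.integer(seed))

  # infeasible packing: expected total call time must fit the recording
  mean_call_s <- sum(config$syllable_count_probs *
                       call_duration_s(config, 1:4))
  if (config$calls_per_recording * mean_call_s > config$duration_s)
    stop("infeasible packing: expected total call time (",
         round(config$calls_per_recording * mean_call_s, 1),
         " s) exceeds recording duration (", config$duration_s, " s)")
  max_call_s <- call_duration_s(config, 4L)
  if (config$calls_per_recording > 0 && max_call_s > config$duration_s)
    stop("infeasible packing: a single call is longer than the recording")

  if (is.null(site_ids)) site_ids <- paste0("S", seq_len(config$n_sites))
  if (length(site_ids) != config$n_sites)
    stop("site_ids must have length n_sites")
  if (is.null(recording_prefix)) recording_prefix <- group_label

  eff <- stats::rnorm(config$n_sites, 0, config$sd_site_hz)
  names(eff) <- site_ids
  if (!is.null(site_effects)) {
    keep <- intersect(names(site_effects), site_ids)
    eff[keep] <- site_effects[keep]
  }

  n_rec_total <- config$n_sites * config$recordings_per_site
  if (!is.null(calls_per_recording_vec) &&
      length(calls_per_recording_vec) != n_rec_total)
    stop("calls_per_recording_vec must have one entry per recording")

  recordings <- vector("list", n_rec_total)
  ann_list <- vector("list", n_rec_total)
  k <- 0L
  for (s in seq_len(config$n_sites)) {
    for (r in seq_len(config$recordings_per_site)) {
      k <- k + 1L
      rec_id <- sprintf("%s_%s_r%d", recording_prefix, site_ids[s], r)
      lambda <- if (is.null(calls_per_recording_vec))
        config$calls_per_recording else calls_per_recording_vec[k]
      rec_eff <- stats::rnorm(1, 0, config$sd_recording_hz)
      calls <- draw_calls(config, lambda, eff[s] + rec_eff, ensure_calls)
      ann <- if (nrow(calls) == 0) empty_annotations() else
        data.frame(recording_id = rec_id,
                   start_s = calls$start_s, end_s = calls$end_s,
                   n_syllables = calls$n_syllables,
                   site_id = site_ids[s], year = year_label,
                   group = group_label, freq_hz = calls$freq_hz,
                   stringsAsFactors = FALSE)
      samples <- if (audio) render_recording(config, calls) else NULL
      recordings[[k]] <- structure(
        list(recording_id = rec_id, site_id = site_ids[s],
             year_label = year_label, group_label = group_label,
             sample_rate_hz = config$sample_rate_hz,
             duration_s = config$duration_s, samples = samples),
        class = "frog_recording")
      ann_list[[k]] <- ann
    }
  }
  annotations <- do.call(rbind, ann_list)
  if (is.null(annotations)) annotations <- empty_annotations()
  rownames(annotations) <- NULL
  structure(list(recordings = recordings, annotations = annotations,
                 site_effects = eff, config = config,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

empty_annotations <- function() {
  data.frame(recording_id = character(), start_s = numeric(),
             end_s = numeric(), n_syllables = integer(),
             site_id = character(), year = character(),
             group = character(), freq_hz = numeric(),
             stringsAsFactors = FALSE)
}

# Draw call times, syllable counts and frequencies for one recording.
# Calls may overlap each other (a stated recognizer limitation, so the
# simulator does not prevent it); the annotation table keeps one row each.
draw_calls <- function(cfg, lambda, base_freq, ensure_calls = FALSE) {
  n_calls <- if (lambda > 0) stats::rpois(1, lambda) else 0L
  if (ensure_calls && lambda > 0) {
    while (n_calls == 0L) n_calls <- stats::rpois(1, lambda)
  }
  if (n_calls == 0)
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      n_syllables = integer(), freq_hz = numeric()))
  n_syll <- sample.int(4L, n_calls, replace = TRUE,
                       prob = cfg$syllable_count_probs)
  dur <- call_duration_s(cfg, n_syll)
  start <- stats::runif(n_calls, 0, pmax(0, cfg$duration_s - dur))
  freq <- base_freq + cfg$dominant_freq_hz +
    stats::rnorm(n_calls, 0, cfg$sd_call_hz)
  ord <- order(start)
  data.frame(start_s = start[ord], end_s = (start + dur)[ord],
             n_syllables = n_syll[ord], freq_hz = freq[ord])
}

# Raised-cosine enveloped tone pulse.
syllable_pulse <- function(freq_hz, dur_s, fs, phase = 0) {
  n <- max(1L, round(dur_s * fs))
  t <- (seq_len(n) - 1) / fs
  env <- 0.5 * (1 - cos(2 * pi * t / dur_s))
  sin(2 * pi * freq_hz * t + phase) * env
}

# Render signal + interferers + noise, then calibrate the signal gain so
# that the segment-based SNR matches cfg$snr_db in expectation over the
# one-second segment partition that estimate_snr() uses.
render_recording <- function(cfg, calls) {
  fs <- cfg$sample_rate_hz
  n <- round(cfg$duration_s * fs)
  sig <- numeric(n)
  syl_dur <- cfg$syllable_dur_ms / 1000
  syl_gap <- cfg$syllable_gap_ms / 1000
  if (nrow(calls) > 0) {
    for (i in seq_len(nrow(calls))) {
      phase <- stats::runif(1, 0, 2 * pi)
      for (j in seq_len(calls$n_syllables[i])) {
        t0 <- calls$start_s[i] + (j - 1) * (syl_dur + syl_gap)
        pulse <- syllable_pulse(calls$freq_hz[i], syl_dur, fs, phase)
        i0 <- round(t0 * fs) + 1L
        i1 <- min(n, i0 + length(pulse) - 1L)
        if (i0 <= n)
          sig[i0:i1] <- sig[i0:i1] + pulse[seq_len(i1 - i0 + 1L)]
      }
    }
  }

  intf <- numeric(n)
  n_int <- stats::rpois(1, cfg$interferer_rate_per_min * cfg$duration_s / 60)
  if (n_int > 0) {
    for (i in seq_len(n_int)) {
      in_band <- stats::runif(1) < 0.7
      if (in_band) {
        # call-like pulse train at a nearby frequency: 1-3 pulses with a
        # rhythm unlike the target call, so scores fall mid-range
        n_pulse <- sample.int(3L, 1L)
        pdur <- stats::runif(1, 0.05, 0.09)
        pgap <- stats::runif(1, 0.05, 0.09)
        dur <- n_pulse * pdur + (n_pulse - 1) * pgap
        f <- cfg$dominant_freq_hz +
          sample(c(-1, 1), 1) * stats::runif(1, 100, 450)
        ph <- stats::runif(1, 0, 2 * pi)
        m <- round(dur * fs)
        w <- numeric(m)
        for (p in seq_len(n_pulse)) {
          pw <- syllable_pulse(f, pdur, fs, ph)
          j0 <- round((p - 1) * (pdur + pgap) * fs) + 1L
          j1 <- min(m, j0 + length(pw) - 1L)
          w[j0:j1] <- w[j0:j1] + pw[seq_len(j1 - j0 + 1L)]
        }
        t0 <- stats::runif(1, 0, max(0, cfg$duration_s - dur))
      } else {
        dur <- stats::runif(1, 0.08, 0.15)
        t0 <- stats::runif(1, 0, max(0, cfg$duration_s - dur))
        # linear chirp well above the target band
        m <- max(1L, round(dur * fs))
        t <- (seq_len(m) - 1) / fs
        f0 <- 0.32 * fs
        f1 <- 0.42 * fs
        env <- 0.5 * (1 - cos(2 * pi * t / dur))
        w <- sin(2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2)) * env
      }
      # amplitude relative to the (calibrated) call gain: interferers are
      # other species' sounds at loudness comparable to the target calls
      w <- stats::runif(1, 0.5, 0.9) * w
      i0 <- round(t0 * fs) + 1L
      i1 <- min(n, i0 + length(w) - 1L)
      if (i0 <= n) intf[i0:i1] <- intf[i0:i1] + w[seq_len(i1 - i0 + 1L)]
    }
  }

  noise <- if (cfg$noise == "white") stats::rnorm(n) else pink_noise(n)

  g <- calibrate_gain(cfg, sig, intf, noise, calls)
  g * (sig + intf) + noise
}

# 1/f noise via the Kellet IIR approximation, normalized to unit variance.
pink_noise <- function(n) {
  w <- stats::rnorm(n + 2000L)
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  x <- as.numeric(signal::filter(b, a, w))
  x <- x[-seq_len(2000L)]  # drop filter warm-up
  x / stats::sd(x)
}

# Solve for the signal gain g such that
#   mean dB over call-containing 1-s segments
#     - mean dB over call-free 1-s segments  =  cfg$snr_db
# using the realized per-segment energies, over the same one-second
# segment partition the segment SNR estimator uses. Interferers ride on
# the same gain (amplitude relative to the calls) and contribute to both
# segment classes, exactly as the estimator sees them.
calibrate_gain <- function(cfg, sig, intf, noise, calls) {
  if (nrow(calls) == 0 || all(sig == 0)) return(1)
  fs <- cfg$sample_rate_hz
  n_seg <- floor(cfg$duration_s)
  if (n_seg < 1) return(1)
  L <- round(fs)
  seg_start <- (seq_len(n_seg) - 1)
  idx <- function(i) ((seg_start[i] * L) + 1L):min(length(sig), (seg_start[i] + 1) * L)
  E_sig <- vapply(seq_len(n_seg), function(i)
    sum((sig[idx(i)] + intf[idx(i)])^2), 0)
  E_noise <- vapply(seq_len(n_seg), function(i) sum(noise[idx(i)]^2), 0)
  E_int <- vapply(seq_len(n_seg), function(i) sum(intf[idx(i)]^2), 0)
  has_call <- vapply(seq_len(n_seg), function(i) {
    s0 <- seg_start[i]; s1 <- s0 + 1
    any(calls$start_s < s1 & calls$end_s > s0)
  }, logical(1))
  if (!any(has_call)) return(1)
  f <- function(log_g) {
    g <- exp(log_g)
    sig_db <- mean(10 * log10((g^2 * E_sig[has_call] +
                                 E_noise[has_call]) / L))
    noise_db <- if (any(!has_call))
      mean(10 * log10((g^2 * E_int[!has_call] +
                         E_noise[!has_call]) / L)) else 0
    (sig_db - noise_db) - cfg$snr_db
  }
  root <- stats::uniroot(f, lower = log(1e-5), upper = log(1e6),
                         tol = 1e-10, extendInt = "upX")
  exp(root$root)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d recording(s), %d annotated call(s)\n",
              length(x$recordings), nrow(x$annotations)))
  cat(sprintf("  group '%s', target SNR %.1f dB, audio: %s\n",
              x$recordings[[1]]$group_label, x$config$snr_db,
              !is.null(x$recordings[[1]]$samples)))
  invisible(x)
}

#' @export
print.frog_recording <- function(x, ...) {
  cat(sprintf("Recording %s (site %s, %s): %.0f s @ %.0f Hz%s\n",
              x$recording_id, x$site_id, x$year_label, x$duration_s,
              x$sample_rate_hz,
              if (is.null(x$samples)) " [no audio]" else ""))
  invisible(x)
}
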