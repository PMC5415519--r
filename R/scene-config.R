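#' Configuration for a synthetic chorus scene
#'
#' Builds and validates the parameter set that drives [synth_scene()]. The
#' defaults describe the study conditions the rest of the package assumes:
#' five-minute mono recordings, calls of 1-4 nearly identical syllables, and
#' hierarchical variation of call dominant frequency at three levels --
#' among sites, among recordings within a site, and among calls within a
#' recording -- with more variability among sites than within a recording.
#'
#' @param n_sites number of sites to simulate.
#' @param recordings_per_site recordings generated at each site.
#' @param duration_s duration of each recording in seconds.
#' @param sample_rate_hz sampling rate in Hz. Must exceed
#'   `2 * (dominant_freq_hz + 3 * sd_site_hz)` so that site-shifted calls
#'   stay below Nyquist.
#' @param calls_per_recording mean of the Poisson distribution of call
#'   counts per recording.
#' @param syllable_count_probs probability vector over syllable counts
#'   1, 2, 3, 4; must sum to 1.
#' @param dominant_freq_hz population mean dominant frequency of the call
#'   (Hz).
#' @param sd_site_hz,sd_recording_hz,sd_call_hz hierarchical standard
#'   deviations (Hz) of the call frequency at the among-site,
#'   among-recording and within-recording (call) levels.
#' @param syllable_dur_ms mean syllable duration (ms).
#' @param syllable_gap_ms gap between syllables within a call (ms).
#' @param snr_db target segment-based signal-to-noise ratio in dB, defined
#'   exactly as [estimate_snr()] measures it (mean dB of call-containing
#'   one-second segments minus mean dB of call-free segments).
#' @param interferer_rate_per_min rate of non-target interfering sounds
#'   (tonal pulses and chirps) per minute; these create false-positive
#'   opportunities for the recognizer.
#' @param noise background noise model: `"white"` (Gaussian) or `"pink"`
#'   (1/f).
#' @param seed default RNG seed used when `synth_scene()` is called without
#'   one.
#'
#' @return An object of class `"scene_config"` (a validated list).
#' @seealso [synth_scene()], [build_dataset_groups()]
#' @export
scene_config <- function(n_sites = 8,
                         recordings_per_site = 1,
                         duration_s = 300,
                         sample_rate_hz = 8000,
                         calls_per_recording = 70,
                         syllable_count_probs = c(0.25, 0.25, 0.25, 0.25),
                         dominant_freq_hz = 1200,
                         sd_site_hz = 60,
                         sd_recording_hz = 25,
                         sd_call_hz = 15,
                         syllable_dur_ms = 40,
                         syllable_gap_ms = 30,
                         snr_db = 13.3,
                         interferer_rate_per_min = 2,
                         noise = c("white", "pink"),
                         seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(
    n_sites = as.integer(n_sites),
    recordings_per_site = as.integer(recordings_per_site),
    duration_s = as.numeric(duration_s),
    sample_rate_hz = as.numeric(sample_rate_hz),
    calls_per_recording = as.numeric(calls_per_recording),
    syllable_count_probs = as.numeric(syllable_count_probs),
    dominant_freq_hz = as.numeric(dominant_freq_hz),
    sd_site_hz = as.numeric(sd_site_hz),
    sd_recording_hz = as.numeric(sd_recording_hz),
    sd_call_hz = as.numeric(sd_call_hz),
    syllable_dur_ms = as.numeric(syllable_dur_ms),
    syllable_gap_ms = as.numeric(syllable_gap_ms),
    snr_db = as.numeric(snr_db),
    interferer_rate_per_min = as.numeric(interferer_rate_per_min),
    noise = noise,
    seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  if (cfg$n_sites < 1L) stop("n_sites must be >= 1")
  if (cfg$recordings_per_site < 1L) stop("recordings_per_site must be >= 1")
  nonneg <- c("duration_s", "calls_per_recording", "sd_site_hz",
              "sd_recording_hz", "sd_call_hz", "syllable_dur_ms",
              "syllable_gap_ms", "interferer_rate_per_min")
  for (f in nonneg) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("'%s' must be a non-negative number", f))
  }
  if (cfg$duration_s <= 0) stop("duration_s must be > 0")
  if (cfg$syllable_dur_ms <= 0) stop("syllable_dur_ms must be > 0")
  p <- cfg$syllable_count_probs
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("syllable_count_probs must be 4 non-negative values summing to 1")
  if (cfg$sample_rate_hz <= 2 * (cfg$dominant_freq_hz + 3 * cfg$sd_site_hz))
    stop("sample_rate_hz must exceed 2 * (dominant_freq_hz + 3 * sd_site_hz)")
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic chorus scene configuration\n")
  cat(sprintf("  %d site(s) x %d recording(s), %.0f s @ %.0f Hz\n",
              x$n_sites, x$recordings_per_site, x$duration_s,
              x$sample_rate_hz))
  cat(sprintf("  calls/recording (Poisson mean): %.1f, target SNR %.1f dB (%s noise)\n",
              x$calls_per_recording, x$snr_db, x$noise))
  cat(sprintf("  dominant freq %.0f Hz (sd site/recording/call = %.0f/%.0f/%.0f Hz)\n",
              x$dominant_freq_hz, x$sd_site_hz, x$sd_recording_hz,
              x$sd_call_hz))
  invisible(x)
}

# Total duration (s) of a call with k syllables under this config.
call_duration_s <- function(cfg, k) {
  (k * cfg$syllable_dur_ms + (k - 1) * cfg$syllable_gap_ms) / 1000
}
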