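#' Recognizer build settings
#'
#' The nine tunable build variables of the spectrogram template recognizer,
#' plus the fixed detection frequency band. The band limits are excluded
#' from tuning because the frequency range of most animal signals is
#' consistent and can be fixed beforehand; all other variables are
#' candidates for the one-variable-at-a-time sensitivity analysis in
#' [evaluate_grid()].
#'
#' @param fft_size FFT window length in samples (power of two). Sets the
#'   spectral/temporal resolution trade-off.
#' @param fft_overlap fractional window overlap in `[0, 1)` (the frame
#'   "resolution" variable); frame step is `fft_size * (1 - fft_overlap)`.
#' @param background_filter_s length (s) of the per-frequency running-mean
#'   background estimate subtracted from the spectrogram before detection.
#' @param dynamic_range_db dB span retained below the per-recording
#'   spectrogram maximum; values further down are clamped to the floor.
#' @param max_syllable_ms maximum syllable duration (ms); longer segments
#'   are discarded.
#' @param max_syllable_gap_ms maximum silent gap (ms) bridged when merging
#'   above-threshold frames into syllables and syllables into songs.
#' @param max_song_ms maximum total candidate song span (ms).
#' @param min_syllables minimum number of syllable bursts a candidate must
#'   contain.
#' @param feature_vector_length number of frequency rows in the feature
#'   summary compared against the template.
#' @param band_min_hz,band_max_hz fixed detection band (Hz); must satisfy
#'   `0 < band_min_hz < band_max_hz` and lie below Nyquist at detect time.
#' @return An object of class `"recognizer_settings"`.
#' @export
recognizer_settings <- function(fft_size = 256,
                                fft_overlap = 0.5,
                                background_filter_s = 1,
                                dynamic_range_db = 50,
                                max_syllable_ms = 400,
                                max_syllable_gap_ms = 50,
                                max_song_ms = 1000,
                                min_syllables = 1,
                                feature_vector_length = 4,
                                band_min_hz = 600,
                                band_max_hz = 2000) {
  s <- list(fft_size = as.integer(fft_size),
            fft_overlap = as.numeric(fft_overlap),
            background_filter_s = as.numeric(background_filter_s),
            dynamic_range_db = as.numeric(dynamic_range_db),
            max_syllable_ms = as.numeric(max_syllable_ms),
            max_syllable_gap_ms = as.numeric(max_syllable_gap_ms),
            max_song_ms = as.numeric(max_song_ms),
            min_syllables = as.integer(min_syllables),
            feature_vector_length = as.integer(feature_vector_length),
            band_min_hz = as.numeric(band_min_hz),
            band_max_hz = as.numeric(band_max_hz))
  class(s) <- "recognizer_settings"
  validate_recognizer_settings(s)
  s
}

#' The nine tunable recognizer variables
#'
#' Names of the build variables eligible for grid evaluation; the fixed
#' band limits (`band_min_hz`, `band_max_hz`) are deliberately excluded.
#' @return Character vector of length nine.
#' @export
tunable_variables <- function() {
  c("fft_size", "fft_overlap", "background_filter_s", "dynamic_range_db",
    "max_syllable_ms", "max_syllable_gap_ms", "max_song_ms",
    "min_syllables", "feature_vector_length")
}

validate_recognizer_settings <- function(s) {
  stopifnot(inherits(s, "recognizer_settings"))
  if (s$fft_size < 2L || bitwAnd(s$fft_size, s$fft_size - 1L) != 0L)
    stop("fft_size must be a power of 2")
  if (s$fft_overlap < 0 || s$fft_overlap >= 1)
    stop("fft_overlap must be in [0, 1)")
  for (f in c("background_filter_s", "dynamic_range_db", "max_syllable_ms",
              "max_syllable_gap_ms", "max_song_ms")) {
    if (is.na(s[[f]]) || s[[f]] <= 0)
      stop(sprintf("'%s' must be > 0", f))
  }
  if (s$min_syllables < 1L) stop("min_syllables must be >= 1")
  if (s$feature_vector_length < 1L)
    stop("feature_vector_length must be >= 1")
  if (s$band_min_hz <= 0 || s$band_min_hz >= s$band_max_hz)
    stop("band must satisfy 0 < band_min_hz < band_max_hz")
  invisible(s)
}

#' @export
print.recognizer_settings <- function(x, ...) {
  cat("Recognizer settings (nine tunables + fixed band):\n")
  for (v in tunable_variables())
    cat(sprintf("  %-22s %s\n", v, format(x[[v]])))
  cat(sprintf("  band                   %.0f-%.0f Hz (fixed)\n",
              x$band_min_hz, x$band_max_hz))
  invisible(x)
}

# Short deterministic fingerprint of a settings object, stored in the
# template so detect() can verify the settings it is given.
settings_fingerprint <- function(s) {
  paste(vapply(s[sort(names(unclass(s)))], function(v)
    format(v, digits = 12), ""), collapse = "|")
}

# Replace one field, revalidating.
set_variable <- function(settings, variable, value) {
  if (!variable %in% tunable_variables())
    stop("'", variable, "' is not a tunable recognizer variable; ",
         "the frequency band is fixed and excluded from tuning")
  settings[[variable]] <- if (variable %in%
                              c("fft_size", "min_syllables",
                                "feature_vector_length"))
    as.integer(value) else as.numeric(value)
  validate_recognizer_settings(settings)
  settings
}
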