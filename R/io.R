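#' Read and write annotation tables
#'
#' Annotation tables are tab-separated with columns `recording_id`,
#' `start_s`, `end_s`, `n_syllables`, `site_id`, `year`, `group` (times
#' written at microsecond precision; write-then-read reproduces values
#' exactly at that precision). Rows are validated on read: a missing
#' column or a non-positive duration is rejected with the offending row
#' number.
#'
#' @param path file path.
#' @return Data frame of annotations, sorted by recording and start time.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = NA)
  required <- c("recording_id", "start_s", "end_s", "n_syllables",
                "site_id", "year", "group")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) > 0) {
    bad <- which(!(tab$end_s > tab$start_s))
    if (length(bad) > 0L)
      stop("annotation row ", bad[1],
           ": end_s must be greater than start_s")
    bad_syll <- which(tab$n_syllables < 1 | tab$n_syllables > 4)
    if (length(bad_syll) > 0L)
      stop("annotation row ", bad_syll[1],
           ": n_syllables must be between 1 and 4")
    tab <- tab[order(tab$recording_id, tab$start_s), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' @rdname read_annotations
#' @param calls annotation data frame.
#' @export
write_annotations <- function(calls, path) {
  required <- c("recording_id", "start_s", "end_s", "n_syllables",
                "site_id", "year", "group")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0L)
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- calls[required]
  out$start_s <- sprintf("%.6f", out$start_s)
  out$end_s <- sprintf("%.6f", out$end_s)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write scored match tables
#'
#' Match tables are tab-separated with columns `recording_id`, `start_s`,
#' `end_s`, `score`, `label`.
#'
#' @param path file path.
#' @return Data frame of matches.
#' @export
read_matches <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("recording_id", "start_s", "end_s", "score", "label")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop("match table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) > 0) {
    bad <- which(!(tab$end_s > tab$start_s))
    if (length(bad) > 0L)
      stop("match row ", bad[1], ": end_s must be greater than start_s")
    bad_score <- which(tab$score < 0 | tab$score > 100)
    if (length(bad_score) > 0L)
      stop("match row ", bad_score[1], ": score must be in [0, 100]")
  }
  tab
}

#' @rdname read_matches
#' @param matches match data frame.
#' @export
write_matches <- function(matches, path) {
  required <- c("recording_id", "start_s", "end_s", "score", "label")
  missing_cols <- setdiff(required, names(matches))
  if (length(missing_cols) > 0L)
    stop("match table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- matches[required]
  out$start_s <- sprintf("%.6f", out$start_s)
  out$end_s <- sprintf("%.6f", out$end_s)
  out$score <- sprintf("%.6f", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write mono PCM-16 WAV files
#'
#' Minimal RIFF/WAVE support for the package's audio interchange:
#' 16-bit PCM, single channel. `write_wav` scales the float waveform by
#' `scale` (default: peak-normalize to 0.9 full scale) before
#' quantizing.
#'
#' @param path file path.
#' @param recording_id identifier for the returned recording object;
#'   defaults to the file name without extension.
#' @return `read_wav` returns a recording object (`recording_id`,
#'   `sample_rate_hz`, `duration_s`, `samples` in \[-1, 1\]).
#' @export
read_wav <- function(path, recording_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little",
                     signed = FALSE)
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little",
                      signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt chunk")
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
      if (channels != 1L) stop("only mono WAV is supported")
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE) / 32768
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (is.null(recording_id))
    recording_id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  structure(list(recording_id = recording_id, site_id = NA_character_,
                 year_label = NA_character_, group_label = NA_character_,
                 sample_rate_hz = fs, duration_s = length(samples) / fs,
                 samples = samples),
            class = "frog_recording")
}

#' @rdname read_wav
#' @param recording a recording object with float `samples`.
#' @param scale multiplier applied before quantization; `NULL` (default)
#'   peak-normalizes to 0.9.
#' @export
write_wav <- function(recording, path, scale = NULL) {
  x <- recording$samples
  if (is.null(x)) stop("recording carries no audio")
  if (is.null(scale)) {
    peak <- max(abs(x), 1e-12)
    scale <- 0.9 / peak
  }
  q <- as.integer(pmax(-32768, pmin(32767, round(x * scale * 32767))))
  fs <- as.integer(recording$sample_rate_hz)
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Save and load a finalized recognizer as plain text
#'
#' Persists a [finalize_recognizer()] result as a directory holding a
#' YAML header (settings, scheme, threshold, provenance) and a TSV of the
#' template feature matrix.
#'
#' @param recognizer a `"selected_recognizer"` with a template.
#' @param dir directory to write (created if needed).
#' @export
save_recognizer <- function(recognizer, dir) {
  stopifnot(inherits(recognizer, "selected_recognizer"))
  if (is.null(recognizer$template)) stop("recognizer has no template")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    settings = unclass(recognizer$settings),
    scheme = unclass(recognizer$scheme),
    threshold = recognizer$threshold,
    threshold_source = recognizer$threshold_source,
    weighted_error = recognizer$weighted_error,
    n_training_calls = recognizer$template$n_training_calls,
    sample_rate_hz = recognizer$template$sample_rate_hz)
  yaml::write_yaml(header, file.path(dir, "recognizer.yml"))
  utils::write.table(recognizer$template$feature,
                     file.path(dir, "template.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname save_recognizer
#' @return `load_recognizer` returns the `"selected_recognizer"`.
#' @export
load_recognizer <- function(dir) {
  header <- yaml::read_yaml(file.path(dir, "recognizer.yml"))
  settings <- do.call(recognizer_settings, header$settings)
  feature <- as.matrix(utils::read.table(file.path(dir, "template.tsv"),
                                         sep = "\t"))
  dimnames(feature) <- NULL
  template <- structure(
    list(feature = feature,
         fingerprint = settings_fingerprint(settings),
         n_training_calls = header$n_training_calls,
         sample_rate_hz = header$sample_rate_hz,
         settings = settings),
    class = "recognizer_template")
  structure(list(settings = settings,
                 scheme = do.call(weight_scheme, header$scheme),
                 weighted_error = header$weighted_error,
                 choices = NULL,
                 threshold = header$threshold,
                 threshold_source = header$threshold_source,
                 template = template),
            class = "selected_recognizer")
}
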