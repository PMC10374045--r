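#' Read a PCM WAV file
#'
#' Reads a 16-bit PCM WAV file into a numeric waveform scaled to `[-1, 1]`.
#' Only mono files are accepted unless `downmix = TRUE`, in which case a
#' multi-channel file is averaged down to one channel.
#'
#' @param path Path to a `.wav` file.
#' @param downmix Average channels of a multi-channel file instead of
#'   erroring. Default `FALSE`.
#'
#' @return A list with elements `waveform` (numeric vector in `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path, downmix = FALSE) {
  if (!file.exists(path)) {
    stop("WAV file does not exist: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("Not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("Not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("Malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    stop("Unsupported WAV encoding (need 16-bit PCM): ", path, call. = FALSE)
  }
  samples <- readBin(data_raw, "integer", n = length(data_raw) / 2L,
                     size = 2, signed = TRUE, endian = "little")
  if (fmt$n_channels > 1L) {
    if (!downmix) {
      stop("Multi-channel WAV; pass downmix = TRUE to average channels.",
           call. = FALSE)
    }
    samples <- colMeans(matrix(samples, nrow = fmt$n_channels))
  }
  list(waveform = samples / 32768, sample_rate = fmt$sample_rate)
}

#' Write a mono PCM WAV file
#'
#' Writes a numeric waveform (values in `[-1, 1]`) as 16-bit PCM mono.
#' Values are quantized with rounding so that `write_wav()` followed by
#' [read_wav()] reproduces already-quantized samples exactly.
#'
#' @param waveform Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param sample_rate Sampling rate in Hz (e.g. 44100 or 48000).
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  stopifnot(is.numeric(waveform), length(waveform) > 0,
            is.numeric(sample_rate), sample_rate > 0)
  pcm <- as.integer(pmax(-32768, pmin(32767, round(waveform * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a Raven-style selection table
#'
#' Parses a tab-delimited selection table with at least "Begin Time (s)" and
#' "End Time (s)" columns (the dialect written by Raven); "Low Freq (Hz)" and
#' "High Freq (Hz)" are kept when present and extra columns are ignored.
#'
#' @param path Path to a tab-delimited selection table.
#'
#' @return A tibble with one row per selection: `begin_s`, `end_s`, `low_hz`,
#'   `high_hz` (frequency bounds `NA` when absent from the table).
#' @export
read_selection_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cols <- names(raw)
  find_col <- function(pattern) {
    hit <- grep(pattern, cols, ignore.case = TRUE)
    if (length(hit)) hit[[1]] else NA_integer_
  }
  bi <- find_col("^begin time")
  ei <- find_col("^end time")
  if (is.na(bi) || is.na(ei)) {
    stop("Selection table must contain 'Begin Time (s)' and 'End Time (s)' columns.",
         call. = FALSE)
  }
  li <- find_col("^low freq")
  hi <- find_col("^high freq")
  out <- tibble::tibble(
    begin_s = as.numeric(raw[[bi]]),
    end_s = as.numeric(raw[[ei]]),
    low_hz = if (!is.na(li)) as.numeric(raw[[li]]) else NA_real_,
    high_hz = if (!is.na(hi)) as.numeric(raw[[hi]]) else NA_real_
  )
  bad <- which(!(out$begin_s < out$end_s))
  if (length(bad)) {
    stop("Selection table rows with end <= begin: row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_f <- which(!is.na(out$low_hz) & !is.na(out$high_hz) &
                   out$low_hz >= out$high_hz)
  if (length(bad_f)) {
    stop("Selection table rows with high_hz <= low_hz: row(s) ",
         paste(bad_f, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a call dataset's audio to WAV files
#'
#' Writes each call's clip to `<dir>/<call_id>.wav` and returns the metadata
#' table (waveform column dropped) with a `wav_path` column, suitable for
#' [readr::write_csv()].
#'
#' @param calls A call tibble from [generate_population()].
#' @param dir Output directory (created if needed).
#'
#' @return Metadata tibble with `wav_path`.
#' @export
write_call_wavs <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(calls$call_id, ".wav"))
  purrr::walk2(calls$waveform, paths,
               ~ write_wav(.x, calls$sample_rate[[1]], .y))
  out <- dplyr::select(calls, -"waveform")
  out$wav_path <- paths
  out
}

#' Read a call dataset from a metadata table with WAV paths
#'
#' Inverse of [write_call_wavs()]: reads each `wav_path` back into the
#' `waveform` list-column.
#'
#' @param metadata Tibble with a `wav_path` column (and any identity columns).
#'
#' @return Call tibble with a `waveform` list-column and `sample_rate`.
#' @export
read_call_dataset <- function(metadata) {
  clips <- purrr::map(metadata$wav_path, read_wav)
  metadata$waveform <- purrr::map(clips, "waveform")
  metadata$sample_rate <- purrr::map_dbl(clips, "sample_rate")
  metadata
}
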