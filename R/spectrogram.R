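#' Compute a bandpassed dB spectrogram
#'
#' Short-time Fourier transform with a Hanning window; defaults follow the
#' pipeline's SPCC convention (window length 378 samples, 90% window overlap,
#' bandpass 0.5-9 kHz). Magnitudes are dB re the spectrogram peak, floored at
#' `floor_db` so silent cells cannot dominate downstream correlations.
#'
#' @param waveform Numeric waveform.
#' @param sample_rate Sampling rate (Hz).
#' @param window_len Window length in samples (default 378).
#' @param overlap Window overlap as a fraction in `[0, 1)` (default 0.9,
#'   i.e. hop 38 samples at the default window). Ignored when
#'   `overlap_samples` is given.
#' @param overlap_samples Literal overlap in samples (e.g. 90, hop 288); an
#'   alternative reading of toolkit conventions, off by default.
#' @param bandpass Frequency band kept, Hz (default `c(500, 9000)`).
#' @param floor_db Floor in dB relative to the peak (default -60).
#'
#' @return A `spectrogram`: list with `mag_db` (bins x frames), `freq_hz`,
#'   `time_s`, and `params`.
#' @export
compute_spectrogram <- function(waveform, sample_rate,
                                window_len = 378, overlap = 0.9,
                                overlap_samples = NULL,
                                bandpass = c(500, 9000), floor_db = -60) {
  n <- length(waveform)
  if (n < window_len) {
    stop("Waveform shorter than one analysis window (", window_len,
         " samples).", call. = FALSE)
  }
  hop <- if (!is.null(overlap_samples)) {
    window_len - as.integer(overlap_samples)
  } else {
    stopifnot(overlap >= 0, overlap < 1)
    window_len - as.integer(round(overlap * window_len))
  }
  if (hop < 1) stop("Overlap leaves no hop.", call. = FALSE)
  starts <- seq(1L, n - window_len + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, window_len - 1) / (window_len - 1))
  frames <- vapply(starts, function(s) {
    waveform[s:(s + window_len - 1L)] * w
  }, numeric(window_len))
  spec <- stats::mvfft(frames)
  n_bins <- floor(window_len / 2) + 1L
  mag <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  freq <- (seq_len(n_bins) - 1) * sample_rate / window_len
  keep <- freq >= bandpass[1] & freq <= bandpass[2]
  mag <- mag[keep, , drop = FALSE]
  freq <- freq[keep]
  peak <- max(mag)
  mag_db <- if (peak > 0) {
    pmax(20 * log10(pmax(mag, .Machine$double.xmin) / peak), floor_db)
  } else {
    matrix(floor_db, nrow(mag), ncol(mag))
  }
  structure(list(
    mag_db = mag_db,
    freq_hz = freq,
    time_s = (starts - 1 + window_len / 2) / sample_rate,
    params = list(window_len = window_len, hop = hop,
                  window = "hanning", bandpass = bandpass,
                  sample_rate = sample_rate, floor_db = floor_db)
  ), class = "spectrogram")
}

#' Dominant-frequency contour of a spectrogram
#'
#' Per-frame frequency of maximum magnitude (Hz).
#'
#' @param spec A `spectrogram`.
#' @return Numeric vector, one value per frame.
#' @export
dominant_contour <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  spec$freq_hz[apply(spec$mag_db, 2, which.max)]
}

same_spec_params <- function(a, b) {
  pa <- a$params
  pb <- b$params
  identical(pa[c("window_len", "hop", "window", "bandpass", "sample_rate")],
            pb[c("window_len", "hop", "window", "bandpass", "sample_rate")]) &&
    length(a$freq_hz) == length(b$freq_hz) &&
    max(abs(a$freq_hz - b$freq_hz)) < 1e-9
}

#' Spectrographic cross-correlation of two calls
#'
#' The shorter spectrogram slides along the longer in single-frame steps;
#' at each full-overlap lag the Pearson correlation of co-occurring dB cells
#' is computed and the maximum over lags, floored at 0, is returned.
#' Symmetric; `spcc_pair(A, A) == 1`.
#'
#' @param a,b `spectrogram` objects computed with identical parameters.
#'
#' @return Similarity in `[0, 1]`.
#' @export
spcc_pair <- function(a, b) {
  stopifnot(inherits(a, "spectrogram"), inherits(b, "spectrogram"))
  if (!same_spec_params(a, b)) {
    stop("Spectrograms were computed with different parameters or axes.",
         call. = FALSE)
  }
  spcc_max_cor_cpp(a$mag_db, b$mag_db)
}

#' Pairwise SPCC similarity matrix
#'
#' Trims each call to its selection extent (`begin_s`/`end_s` when present),
#' computes spectrograms with shared parameters, and fills the symmetric
#' pairwise similarity matrix with [spcc_pair()].
#'
#' @param calls Call tibble (`call_id`, `waveform`, `sample_rate`, optional
#'   `begin_s`/`end_s`).
#' @inheritParams compute_spectrogram
#'
#' @return A [similarity_matrix()] with method `"SPCC"`.
#' @export
spcc_matrix <- function(calls, window_len = 378, overlap = 0.9,
                        overlap_samples = NULL, bandpass = c(500, 9000),
                        floor_db = -60) {
  n <- nrow(calls)
  stopifnot(n >= 1)
  if (length(unique(calls$sample_rate)) != 1) {
    stop("All calls must share one sample rate for a common frequency axis.",
         call. = FALSE)
  }
  specs <- purrr::pmap(
    list(calls$waveform, calls$sample_rate,
         if ("begin_s" %in% names(calls)) calls$begin_s else
           rep(0, n),
         if ("end_s" %in% names(calls)) calls$end_s else
           purrr::map_dbl(calls$waveform, length) / calls$sample_rate),
    function(w, sr, b, e) {
      i0 <- max(1L, floor(b * sr) + 1L)
      i1 <- min(length(w), ceiling(e * sr))
      compute_spectrogram(w[i0:i1], sr, window_len = window_len,
                          overlap = overlap,
                          overlap_samples = overlap_samples,
                          bandpass = bandpass, floor_db = floor_db)
    }
  )
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        v <- tryCatch(spcc_pair(specs[[i]], specs[[j]]), error = function(e) {
          stop("SPCC failed for pair (", calls$call_id[i], ", ",
               calls$call_id[j], "): ", conditionMessage(e), call. = FALSE)
        })
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  similarity_matrix(m, method = "SPCC", call_ids = calls$call_id)
}
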