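#' Estimate the signal-to-noise ratio of a selected call
#'
#' SNR is the linear RMS ratio between the call extent and flanking
#' noise-only margins: a call "7 times louder than background noise" scores
#' 7. Margins of `noise_margin_s` seconds are taken immediately before and
#' after the selection; when only one side has enough audio, that side alone
#' is used. The estimate is invariant to global amplitude scaling.
#'
#' @param waveform Numeric waveform.
#' @param sample_rate Sampling rate (Hz).
#' @param begin_s,end_s Call extent within the waveform (s).
#' @param noise_margin_s Margin length per side (s), default 0.1.
#'
#' @return Linear SNR (dimensionless, >= 0).
#' @export
estimate_snr <- function(waveform, sample_rate, begin_s, end_s,
                         noise_margin_s = 0.1) {
  stopifnot(begin_s >= 0, end_s > begin_s, noise_margin_s > 0)
  n <- length(waveform)
  i0 <- max(1L, floor(begin_s * sample_rate) + 1L)
  i1 <- min(n, ceiling(end_s * sample_rate))
  if (i1 <= i0) stop("Selection outside waveform.", call. = FALSE)
  m <- round(noise_margin_s * sample_rate)
  pre <- if (i0 - m >= 1) waveform[(i0 - m):(i0 - 1L)] else numeric(0)
  post <- if (i1 + m <= n) waveform[(i1 + 1L):(i1 + m)] else numeric(0)
  if (!length(pre) && !length(post)) {
    stop("No noise margin of ", noise_margin_s,
         " s available on either side of the selection.", call. = FALSE)
  }
  rms <- function(x) sqrt(mean(x^2))
  noise <- if (length(pre) && length(post)) {
    mean(c(rms(pre), rms(post)))
  } else {
    rms(c(pre, post))
  }
  if (noise == 0) {
    stop("Noise margins are pure silence; SNR undefined.", call. = FALSE)
  }
  rms(waveform[i0:i1]) / noise
}

#' Convert a linear SNR to decibels
#'
#' @param snr Linear RMS ratio.
#' @return SNR in dB (`20 * log10(snr)`).
#' @export
snr_to_db <- function(snr) 20 * log10(snr)

#' Quality-control filter on signal-to-noise ratio
#'
#' Retains calls whose measured SNR is at least `min_snr` (inclusive; the
#' default cut-off of 7 keeps calls at least 7 times louder than background
#' noise). Calls carrying a logical `overlap_flag` column set to `TRUE`
#' (manually flagged overlapping sounds) are rejected regardless of SNR.
#' Filtering is idempotent.
#'
#' @param calls Call tibble with `waveform`, `sample_rate`, `begin_s`,
#'   `end_s` columns.
#' @param min_snr Minimum linear SNR (default 7).
#' @param noise_margin_s Margin length for [estimate_snr()].
#'
#' @return A list with `retained` (call tibble, plus measured `snr` column)
#'   and `rejected` (call_id, snr, reason).
#' @export
qc_filter <- function(calls, min_snr = 7, noise_margin_s = 0.1) {
  if (nrow(calls) == 0) {
    return(list(
      retained = dplyr::mutate(calls, snr = numeric(0)),
      rejected = tibble::tibble(call_id = character(), snr = numeric(),
                                reason = character())
    ))
  }
  snr <- purrr::pmap_dbl(
    list(calls$waveform, calls$sample_rate, calls$begin_s, calls$end_s),
    function(w, sr, b, e) estimate_snr(w, sr, b, e, noise_margin_s)
  )
  overlap <- if ("overlap_flag" %in% names(calls)) {
    isTRUE_vec <- calls$overlap_flag %in% TRUE
    isTRUE_vec
  } else {
    rep(FALSE, nrow(calls))
  }
  keep <- snr >= min_snr & !overlap
  out <- calls
  out$snr <- snr
  reason <- ifelse(overlap, "overlapping sound flagged",
                   sprintf("snr %.3g below %.3g", snr, min_snr))
  list(
    retained = out[keep, , drop = FALSE],
    rejected = tibble::tibble(
      call_id = calls$call_id[!keep],
      snr = snr[!keep],
      reason = reason[!keep]
    )
  )
}
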