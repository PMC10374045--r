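moment_skew <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

moment_kurt <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}

#' Spectral acoustic features of one call
#'
#' Deterministic named feature vector from the call's bandpassed
#' spectrogram: duration; aggregate-spectrum statistics (peak, mean, median
#' frequency, frequency quartiles and IQR, spectral entropy); dominant-
#' frequency contour summaries (mean, min, max, range, least-squares slope,
#' modulation index); and spectrogram texture statistics standing in for
#' image-derived measurements (energy moments and contrast of the dB
#' matrix). Single-frame spectrograms yield defined values (slopes and
#' modulation 0).
#'
#' @param waveform Numeric waveform (already trimmed to the call extent).
#' @param sample_rate Sampling rate (Hz).
#' @inheritParams compute_spectrogram
#'
#' @return Named numeric vector.
#' @export
extract_spectral_features <- function(waveform, sample_rate,
                                      window_len = 378, overlap = 0.9,
                                      bandpass = c(500, 9000)) {
  spec <- compute_spectrogram(waveform, sample_rate, window_len = window_len,
                              overlap = overlap, bandpass = bandpass)
  pow <- 10^(spec$mag_db / 10)           # linear power, peak-normalized
  agg <- rowMeans(pow)
  agg <- agg / sum(agg)
  f <- spec$freq_hz
  cdf <- cumsum(agg)
  q_at <- function(p) f[which(cdf >= p)[1]]
  entropy <- -sum(agg * log(agg + 1e-300)) / log(length(agg))
  contour <- dominant_contour(spec)
  n_fr <- length(contour)
  tt <- spec$time_s
  slope <- if (n_fr > 1) stats::cov(tt, contour) / stats::var(tt) else 0
  mod_index <- if (n_fr > 1 && diff(range(contour)) > 0) {
    sum(abs(diff(contour))) / diff(range(contour))
  } else 0
  db <- spec$mag_db
  row_energy <- rowMeans(db)
  col_energy <- colMeans(db)
  c(
    duration_s = length(waveform) / sample_rate,
    peak_freq = f[which.max(agg)],
    mean_freq = sum(f * agg),
    median_freq = q_at(0.5),
    freq_q25 = q_at(0.25),
    freq_q75 = q_at(0.75),
    freq_iqr = q_at(0.75) - q_at(0.25),
    spectral_entropy = entropy,
    contour_mean = mean(contour),
    contour_min = min(contour),
    contour_max = max(contour),
    contour_range = diff(range(contour)),
    contour_slope = slope,
    contour_modulation = mod_index,
    tex_db_mean = mean(db),
    tex_db_sd = stats::sd(as.vector(db)),
    tex_db_skew = moment_skew(as.vector(db)),
    tex_row_energy_sd = stats::sd(row_energy),
    tex_col_energy_sd = if (n_fr > 1) stats::sd(col_energy) else 0,
    tex_contrast = mean(abs(db - mean(db)))
  )
}

mel_from_hz <- function(f) 2595 * log10(1 + f / 700)
hz_from_mel <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_bins, sample_rate, window_len, n_mel,
                           f_lo = 500, f_hi = 9000) {
  mel_pts <- seq(mel_from_hz(f_lo), mel_from_hz(f_hi), length.out = n_mel + 2)
  hz_pts <- hz_from_mel(mel_pts)
  freq <- (seq_len(n_bins) - 1) * sample_rate / window_len
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- hz_pts[m]; mid <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freq - lo) / (mid - lo)
    down <- (hi - freq) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Descriptive statistics of Mel-frequency cepstral coefficients
#'
#' Frames the call, computes log mel-filterbank energies and a DCT-II to get
#' cepstra, drops the 0th (overall-level) coefficient so the features are
#' exactly invariant to global amplitude scaling, and summarizes each
#' retained coefficient track and its first difference with mean, variance,
#' skewness and kurtosis.
#'
#' @param waveform Numeric waveform (trimmed to the call extent).
#' @param sample_rate Sampling rate (Hz).
#' @param n_mfcc Number of cepstral coefficients kept (default 12,
#'   coefficients 1..12).
#' @param n_mel Number of mel filters (default 26).
#' @param window_len,overlap Framing parameters as in
#'   [compute_spectrogram()].
#'
#' @return Named numeric vector (`n_mfcc * 8` values).
#' @export
extract_mfcc_stats <- function(waveform, sample_rate, n_mfcc = 12,
                               n_mel = 26, window_len = 378, overlap = 0.9) {
  n <- length(waveform)
  if (n < window_len) {
    stop("Call too short for one MFCC analysis frame.", call. = FALSE)
  }
  hop <- window_len - as.integer(round(overlap * window_len))
  starts <- seq(1L, n - window_len + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, window_len - 1) / (window_len - 1))
  frames <- vapply(starts, function(s) waveform[s:(s + window_len - 1L)] * w,
                   numeric(window_len))
  n_bins <- floor(window_len / 2) + 1L
  pow <- Mod(stats::mvfft(frames))[seq_len(n_bins), , drop = FALSE]^2
  fb <- mel_filterbank(n_bins, sample_rate, window_len, n_mel)
  mel_e <- log(fb %*% pow + 1e-12)
  # DCT-II along the mel axis; coefficient 0 (row of the basis with k = 0)
  # absorbs overall level and is dropped.
  k <- seq_len(n_mfcc)
  basis <- sqrt(2 / n_mel) *
    cos(outer(k, (seq_len(n_mel) - 0.5), function(kk, mm) pi * kk * mm / n_mel))
  cep <- basis %*% mel_e                     # n_mfcc x frames
  stats_of <- function(x) c(mean = mean(x), var = stats::var(x),
                            skew = moment_skew(x), kurt = moment_kurt(x))
  out <- numeric(0)
  for (ci in seq_len(n_mfcc)) {
    track <- cep[ci, ]
    if (length(track) < 2) track <- c(track, track)
    s1 <- stats_of(track)
    s2 <- stats_of(diff(track))
    names(s1) <- paste0("mfcc", ci, "_", names(s1))
    names(s2) <- paste0("mfcc", ci, "_d_", names(s2))
    out <- c(out, s1, s2)
  }
  out
}

#' Dynamic-time-warping distance between two frequency contours
#'
#' Classic DTW dynamic program with absolute-difference local cost
#' (symmetric steps), total path cost normalized by the summed contour
#' lengths. Symmetric, and zero iff the contours are identical.
#'
#' @param contour_a,contour_b Numeric dominant-frequency contours (Hz).
#'
#' @return Non-negative distance (Hz, length-normalized).
#' @export
dtw_contour_distance <- function(contour_a, contour_b) {
  na <- length(contour_a)
  nb <- length(contour_b)
  if (na == 0 || nb == 0) stop("Empty contour.", call. = FALSE)
  dtw_cost_cpp(contour_a, contour_b) / (na + nb)
}

#' Assemble the acoustic feature table for a call dataset
#'
#' One row per call: spectral features, MFCC descriptive statistics, and
#' (optionally, via [add_embedding_features()]) low-dimensional embedding
#' coordinates of SPCC and DTW-distance matrices. Deterministic:
#' re-extraction reproduces the table exactly.
#'
#' @param calls Call tibble.
#' @param n_mfcc Number of cepstral coefficients.
#' @inheritParams compute_spectrogram
#'
#' @return Tibble with `call_id` plus numeric feature columns.
#' @export
call_feature_table <- function(calls, n_mfcc = 12, window_len = 378,
                               overlap = 0.9, bandpass = c(500, 9000)) {
  trim <- function(w, sr, b, e) {
    i0 <- max(1L, floor(b * sr) + 1L)
    i1 <- min(length(w), ceiling(e * sr))
    w[i0:i1]
  }
  n <- nrow(calls)
  b <- if ("begin_s" %in% names(calls)) calls$begin_s else rep(0, n)
  e <- if ("end_s" %in% names(calls)) calls$end_s else
    purrr::map_dbl(calls$waveform, length) / calls$sample_rate
  feats <- purrr::map(seq_len(n), function(i) {
    w <- trim(calls$waveform[[i]], calls$sample_rate[[i]], b[[i]], e[[i]])
    sr <- calls$sample_rate[[i]]
    c(extract_spectral_features(w, sr, window_len = window_len,
                                overlap = overlap, bandpass = bandpass),
      extract_mfcc_stats(w, sr, n_mfcc = n_mfcc, window_len = window_len,
                         overlap = overlap))
  })
  out <- tibble::as_tibble(do.call(rbind, feats))
  dplyr::bind_cols(tibble::tibble(call_id = calls$call_id), out)
}

#' Pairwise DTW distance matrix of dominant-frequency contours
#'
#' @param calls Call tibble.
#' @inheritParams compute_spectrogram
#'
#' @return Symmetric distance matrix with call-id dimnames.
#' @export
dtw_distance_matrix <- function(calls, window_len = 378, overlap = 0.9,
                                bandpass = c(500, 9000)) {
  n <- nrow(calls)
  b <- if ("begin_s" %in% names(calls)) calls$begin_s else rep(0, n)
  e <- if ("end_s" %in% names(calls)) calls$end_s else
    purrr::map_dbl(calls$waveform, length) / calls$sample_rate
  contours <- purrr::map(seq_len(n), function(i) {
    sr <- calls$sample_rate[[i]]
    i0 <- max(1L, floor(b[[i]] * sr) + 1L)
    i1 <- min(length(calls$waveform[[i]]), ceiling(e[[i]] * sr))
    dominant_contour(compute_spectrogram(calls$waveform[[i]][i0:i1], sr,
                                         window_len = window_len,
                                         overlap = overlap,
                                         bandpass = bandpass))
  })
  m <- matrix(0, n, n, dimnames = list(calls$call_id, calls$call_id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        d <- dtw_contour_distance(contours[[i]], contours[[j]])
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  m
}

#' Append embedding coordinates as features
#'
#' Embeds a similarity (or distance) matrix with [nmds_embed()] and joins
#' the `k` coordinate columns onto the feature table.
#'
#' @param features Feature tibble with `call_id`.
#' @param m A [similarity_matrix()] or symmetric distance matrix over the
#'   same calls.
#' @param k Embedding dimensionality (default 2).
#' @param prefix Column-name prefix (e.g. `"spcc_mds"`).
#' @param seed Seed for the embedding restarts.
#'
#' @return Feature tibble with `k` extra columns.
#' @export
add_embedding_features <- function(features, m, k = 2, prefix = "mds",
                                   seed = 1) {
  emb <- nmds_embed(m, k = k, seed = seed)
  coords <- emb$coords
  names(coords)[-1] <- paste0(prefix, seq_len(k))
  dplyr::left_join(features, coords, by = "call_id")
}
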