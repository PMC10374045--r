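#' Configuration for a synthetic call population
#'
#' Describes a nested population (regions > sites > individuals) of
#' frequency-modulated, chirp-like contact calls with controllable acoustic
#' convergence at each social scale. Convergence is planted causally: each
#' individual's frequency-contour template is a weighted blend of an
#' individual-unique perturbation, its site's template, and its region's
#' template, so ground truth about where identity information lives is known
#' by construction.
#'
#' @param n_regions,n_sites_per_region,n_individuals_per_site Counts (>= 0).
#' @param calls_per_individual Integer count or length-2 range; per-individual
#'   call counts are drawn uniformly from the range.
#' @param signature_strength Scale (Hz) of each individual's unique contour
#'   perturbation; larger values give stronger individual vocal signatures.
#' @param site_weight,region_weight Blending weights in `[0, 1]` pulling
#'   individual templates toward the site and region templates
#'   (`site_weight + region_weight <= 1`).
#' @param call_jitter Within-individual call-to-call contour noise (Hz).
#' @param snr_db Target signal-to-noise ratio in dB (RMS over the call extent
#'   vs the noise-only margins).
#' @param sample_rate Sampling rate in Hz.
#' @param duration_range Length-2 range of call durations (s).
#' @param n_control_points Number of contour control points (5-9 typical).
#' @param group_spread Scale (Hz) of site/region template perturbations
#'   around the species-mean contour.
#' @param pad_s Noise-only margin synthesized on each side of the call (s).
#' @param range_label Label stored in the metadata (e.g. species or range).
#' @param year Year stored in the metadata.
#' @param seed Integer seed; identical configurations generate identical
#'   datasets.
#'
#' @return A `population_config` list.
#' @export
population_config <- function(n_regions = 1,
                              n_sites_per_region = 3,
                              n_individuals_per_site = 4,
                              calls_per_individual = c(4, 25),
                              signature_strength = 600,
                              site_weight = 0,
                              region_weight = 0,
                              call_jitter = 150,
                              snr_db = 24,
                              sample_rate = 44100,
                              duration_range = c(0.1, 0.4),
                              n_control_points = 7,
                              group_spread = 800,
                              pad_s = 0.15,
                              range_label = "synthetic",
                              year = 2019L,
                              seed = 1L) {
  counts <- c(n_regions, n_sites_per_region, n_individuals_per_site)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("Counts must be non-negative integers.", call. = FALSE)
  }
  if (length(calls_per_individual) == 1) {
    calls_per_individual <- rep(calls_per_individual, 2)
  }
  stopifnot(length(calls_per_individual) == 2,
            calls_per_individual[1] >= 1,
            calls_per_individual[1] <= calls_per_individual[2])
  if (site_weight < 0 || site_weight > 1 || region_weight < 0 ||
      region_weight > 1 || site_weight + region_weight > 1 + 1e-12) {
    stop("site_weight and region_weight must lie in [0, 1] with sum <= 1.",
         call. = FALSE)
  }
  stopifnot(signature_strength >= 0, call_jitter >= 0,
            is.finite(snr_db), sample_rate > 0,
            length(duration_range) == 2,
            duration_range[1] > 0, duration_range[1] <= duration_range[2],
            n_control_points >= 3, group_spread >= 0, pad_s >= 0)
  structure(list(
    n_regions = as.integer(n_regions),
    n_sites_per_region = as.integer(n_sites_per_region),
    n_individuals_per_site = as.integer(n_individuals_per_site),
    calls_per_individual = as.integer(calls_per_individual),
    signature_strength = signature_strength,
    site_weight = site_weight,
    region_weight = region_weight,
    call_jitter = call_jitter,
    snr_db = snr_db,
    sample_rate = sample_rate,
    duration_range = duration_range,
    n_control_points = as.integer(n_control_points),
    group_spread = group_spread,
    pad_s = pad_s,
    range_label = range_label,
    year = as.integer(year),
    seed = as.integer(seed)
  ), class = "population_config")
}

# Frequency band the whole pipeline assumes; templates are clamped so that
# call-level jitter cannot push instantaneous frequency out of the analysis
# bandpass (500-9000 Hz).
.freq_band <- c(500, 9000)
.template_band <- c(900, 8600)

contour_template <- function(freq_hz, duration_s, n_points = length(freq_hz)) {
  stopifnot(length(freq_hz) >= 3, duration_s > 0)
  freq_hz <- pmin(pmax(freq_hz, .template_band[1]), .template_band[2])
  list(
    rel_time = seq(0, 1, length.out = length(freq_hz)),
    freq_hz = freq_hz,
    duration_s = duration_s
  )
}

#' Build the region/site/individual template hierarchy
#'
#' Draws a species-mean frequency contour, independent site and region
#' template perturbations, and an individual-unique perturbation per bird,
#' then blends: `(1 - w_site - w_region) * individual + w_site * site +
#' w_region * region` on control-point frequencies and on call duration
#' (social learning is assumed to shape the whole call, so durations
#' converge with the same weights as contours). With `site_weight = 1`
#' every individual at a site reproduces the site template exactly; with
#' both weights zero, individual templates are independent draws whose
#' spread is set by `signature_strength`.
#'
#' @param config A [population_config()].
#'
#' @return A list with tibbles `region`, `site`, and `individual`; each row
#'   carries a `template` list-column (control-point contour + duration).
#' @export
make_templates <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n_cp <- config$n_control_points
  base_freq <- stats::runif(1, 2800, 4200)
  shape <- stats::rnorm(n_cp, 0, 1)
  mean_contour <- base_freq + 900 * shape

  w_site <- config$site_weight
  w_region <- config$region_weight
  w_ind <- 1 - w_site - w_region

  regions <- list()
  sites <- list()
  individuals <- list()
  dur_draw <- function() stats::runif(1, config$duration_range[1],
                                      config$duration_range[2])
  for (r in seq_len(config$n_regions)) {
    region_id <- sprintf("R%d", r)
    f_region <- mean_contour + stats::rnorm(n_cp, 0, config$group_spread)
    d_region <- dur_draw()
    regions[[length(regions) + 1]] <- tibble::tibble(
      region_id = region_id,
      template = list(contour_template(f_region, d_region))
    )
    for (s in seq_len(config$n_sites_per_region)) {
      site_id <- sprintf("%s_S%d", region_id, s)
      f_site <- mean_contour + stats::rnorm(n_cp, 0, config$group_spread)
      d_site <- dur_draw()
      sites[[length(sites) + 1]] <- tibble::tibble(
        region_id = region_id, site_id = site_id,
        template = list(contour_template(f_site, d_site))
      )
      for (i in seq_len(config$n_individuals_per_site)) {
        individual_id <- sprintf("%s_I%02d", site_id, i)
        f_unique <- mean_contour +
          stats::rnorm(n_cp, 0, config$signature_strength)
        f_blend <- w_ind * f_unique + w_site * f_site + w_region * f_region
        dur <- w_ind * dur_draw() + w_site * d_site + w_region * d_region
        individuals[[length(individuals) + 1]] <- tibble::tibble(
          region_id = region_id, site_id = site_id,
          individual_id = individual_id,
          template = list(contour_template(f_blend, dur))
        )
      }
    }
  }
  empty <- function(...) tibble::tibble(..., template = list())
  list(
    region = if (length(regions)) dplyr::bind_rows(regions) else
      empty(region_id = character()),
    site = if (length(sites)) dplyr::bind_rows(sites) else
      empty(region_id = character(), site_id = character()),
    individual = if (length(individuals)) dplyr::bind_rows(individuals) else
      empty(region_id = character(), site_id = character(),
            individual_id = character())
  )
}

#' Synthesize one call from a contour template
#'
#' Produces a tonal waveform whose instantaneous frequency follows a
#' monotone-cubic interpolation of the (optionally jittered) control points,
#' with raised-cosine fade-in/out, peak normalized to -3 dBFS, white Gaussian
#' background noise at the requested SNR, and noise-only margins of `pad_s`
#' seconds on each side so the SNR can be re-estimated from the clip itself.
#' Consumes the R random number stream (jitter, then noise).
#'
#' @param template Contour template from [make_templates()].
#' @param call_jitter Per-control-point frequency jitter (Hz).
#' @param snr_db Target SNR in dB (call-extent RMS over noise RMS).
#' @param sample_rate Sampling rate (Hz).
#' @param pad_s Noise-only margin on each side (s).
#'
#' @return A list: `waveform`, `sample_rate`, `begin_s`, `end_s` (call extent
#'   within the clip).
#' @export
synthesize_call <- function(template, call_jitter = 0, snr_db = 24,
                            sample_rate = 44100, pad_s = 0.15) {
  if (!is.finite(snr_db)) stop("snr_db must be finite.", call. = FALSE)
  stopifnot(call_jitter >= 0, sample_rate > 0)
  freqs <- template$freq_hz +
    if (call_jitter > 0) stats::rnorm(length(template$freq_hz), 0, call_jitter)
    else 0
  freqs <- pmin(pmax(freqs, .freq_band[1] + 50), .freq_band[2] - 50)
  n <- max(2L, round(template$duration_s * sample_rate))
  t_rel <- seq(0, 1, length.out = n)
  f_inst <- stats::splinefun(template$rel_time, freqs,
                             method = "monoH.FC")(t_rel)
  f_inst <- pmin(pmax(f_inst, .freq_band[1] + 50), .freq_band[2] - 50)
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  tone <- sin(phase)
  # raised-cosine fades over 10% of the call on each side (>= 5 ms)
  n_fade <- max(round(0.005 * sample_rate), round(0.1 * n))
  n_fade <- min(n_fade, floor(n / 2))
  if (n_fade > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_fade) / n_fade))
    tone[seq_len(n_fade)] <- tone[seq_len(n_fade)] * ramp
    tone[n - n_fade + seq_len(n_fade)] <- tone[n - n_fade + seq_len(n_fade)] *
      rev(ramp)
  }
  tone <- tone / max(abs(tone)) * 10^(-3 / 20)
  sig_rms <- sqrt(mean(tone^2))
  noise_sd <- sig_rms / 10^(snr_db / 20)
  n_pad <- round(pad_s * sample_rate)
  clip <- c(numeric(n_pad), tone, numeric(n_pad))
  clip <- clip + stats::rnorm(length(clip), 0, noise_sd)
  list(
    waveform = clip,
    sample_rate = sample_rate,
    begin_s = n_pad / sample_rate,
    end_s = (n_pad + n) / sample_rate
  )
}

#' Generate a synthetic call population
#'
#' Builds the template hierarchy for `config`, draws per-individual call
#' counts, and synthesizes every call. Each individual belongs to exactly one
#' site; the individual-scale dataset (repeatedly sampled, known individuals)
#' and the site-scale dataset (one call per unmarked individual per site) are
#' derived from the output with [individual_scale_subset()] and
#' [site_scale_subset()].
#'
#' @param config A [population_config()].
#'
#' @return A tibble with one row per call: `call_id`, `individual_id`,
#'   `site_id`, `region_id`, `range_label`, `year`, `begin_s`, `end_s`,
#'   `sample_rate`, and a `waveform` list-column. The generating config is
#'   attached as attribute `"config"`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  templates <- make_templates(config)  # also seeds the RNG
  ind <- templates$individual
  if (nrow(ind) == 0) {
    out <- tibble::tibble(
      call_id = character(), individual_id = character(),
      site_id = character(), region_id = character(),
      range_label = character(), year = integer(),
      begin_s = numeric(), end_s = numeric(), sample_rate = numeric(),
      waveform = list()
    )
    attr(out, "config") <- config
    return(out)
  }
  rows <- vector("list", nrow(ind))
  for (j in seq_len(nrow(ind))) {
    lo <- config$calls_per_individual[1]
    hi <- config$calls_per_individual[2]
    n_calls <- if (lo == hi) lo else sample(seq(lo, hi), 1)
    calls <- vector("list", n_calls)
    for (k in seq_len(n_calls)) {
      calls[[k]] <- synthesize_call(
        ind$template[[j]], call_jitter = config$call_jitter,
        snr_db = config$snr_db, sample_rate = config$sample_rate,
        pad_s = config$pad_s
      )
    }
    rows[[j]] <- tibble::tibble(
      call_id = sprintf("%s_C%02d", ind$individual_id[[j]], seq_len(n_calls)),
      individual_id = ind$individual_id[[j]],
      site_id = ind$site_id[[j]],
      region_id = ind$region_id[[j]],
      range_label = config$range_label,
      year = config$year,
      begin_s = purrr::map_dbl(calls, "begin_s"),
      end_s = purrr::map_dbl(calls, "end_s"),
      sample_rate = config$sample_rate,
      waveform = purrr::map(calls, "waveform")
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  out
}

#' Individual-scale subset of a call dataset
#'
#' Keeps calls of individuals sampled at least `min_calls` times (repeatedly
#' sampled, known individuals), the dataset used to quantify individual
#' vocal signatures.
#'
#' @param calls Call tibble.
#' @param min_calls Minimum calls per individual (default 2).
#'
#' @return Filtered call tibble.
#' @export
individual_scale_subset <- function(calls, min_calls = 2) {
  keep <- dplyr::add_count(calls, .data$individual_id, name = ".n_calls")
  out <- dplyr::filter(keep, .data$.n_calls >= min_calls)
  dplyr::select(out, -".n_calls")
}

#' Site-scale subset of a call dataset
#'
#' One call per individual per site, with individual identity masked
#' (`individual_id` set to `NA`, the true identity kept in
#' `true_individual_id`), emulating a survey of unmarked birds producing a
#' single call each.
#'
#' @param calls Call tibble.
#'
#' @return Call tibble with one row per (site, individual), identity masked.
#' @export
site_scale_subset <- function(calls) {
  out <- dplyr::slice_min(
    dplyr::group_by(calls, .data$site_id, .data$individual_id),
    order_by = .data$call_id, n = 1, with_ties = FALSE
  )
  out <- dplyr::ungroup(out)
  out$true_individual_id <- out$individual_id
  out$individual_id <- NA_character_
  dplyr::arrange(out, .data$call_id)
}
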