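test_that("config validation rejects impossible weights and counts", {
  expect_error(population_config(site_weight = 0.7, region_weight = 0.5),
               "sum <= 1")
  expect_error(population_config(n_regions = -1), "non-negative")
  expect_silent(population_config(site_weight = 1, region_weight = 0))
})

test_that("template blending: site_weight 1 collapses individuals onto the site template", {
  cfg <- population_config(n_sites_per_region = 2, n_individuals_per_site = 3,
                           site_weight = 1, signature_strength = 500,
                           seed = 3)
  tpl <- make_templates(cfg)
  for (s in tpl$site$site_id) {
    site_f <- tpl$site$template[[which(tpl$site$site_id == s)]]$freq_hz
    for (i in which(tpl$individual$site_id == s)) {
      expect_equal(tpl$individual$template[[i]]$freq_hz, site_f)
    }
  }
})

test_that("pairwise template distance grows with signature strength", {
  mean_dist <- function(sigma) {
    d <- numeric(0)
    for (seed in 1:5) {
      cfg <- population_config(n_sites_per_region = 1,
                               n_individuals_per_site = 6,
                               signature_strength = sigma, seed = seed)
      tpl <- make_templates(cfg)
      f <- do.call(rbind, lapply(tpl$individual$template, `[[`, "freq_hz"))
      d <- c(d, as.vector(stats::dist(f)))
    }
    mean(d)
  }
  expect_gt(mean_dist(800), mean_dist(100))
})

test_that("identical seeds give identical hierarchies and identical datasets", {
  cfg <- population_config(n_sites_per_region = 2, n_individuals_per_site = 2,
                           calls_per_individual = c(4, 8),
                           sample_rate = 22050, seed = 17)
  t1 <- make_templates(cfg)
  t2 <- make_templates(cfg)
  expect_identical(t1, t2)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$waveform, p2$waveform)
  expect_identical(p1$call_id, p2$call_id)
})

test_that("zero counts yield an empty hierarchy and empty population", {
  cfg <- population_config(n_individuals_per_site = 0)
  expect_equal(nrow(make_templates(cfg)$individual), 0)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 0)
})

test_that("synthesized contour tracks the template within one frequency bin", {
  cfg <- population_config(seed = 8, sample_rate = 22050,
                           duration_range = c(0.3, 0.3))
  tpl <- make_templates(cfg)$individual$template[[1]]
  set.seed(1)
  call <- synthesize_call(tpl, call_jitter = 0, snr_db = 60,
                          sample_rate = 22050)
  sr <- 22050
  i0 <- floor(call$begin_s * sr) + 1
  i1 <- ceiling(call$end_s * sr)
  spec <- compute_spectrogram(call$waveform[i0:i1], sr)
  contour <- dominant_contour(spec)
  # compare at interior frames (fades dominate the edges)
  interior <- seq(ceiling(length(contour) * 0.15),
                  floor(length(contour) * 0.85))
  t_rel <- (interior - 0.5) / length(contour)
  expected <- stats::splinefun(tpl$rel_time, tpl$freq_hz,
                               method = "monoH.FC")(t_rel)
  bin_hz <- sr / 378
  expect_lt(stats::median(abs(contour[interior] - expected)), bin_hz)
})

test_that("same template, zero jitter and same noise seed reproduce the waveform", {
  cfg <- population_config(seed = 5, sample_rate = 22050)
  tpl <- make_templates(cfg)$individual$template[[1]]
  set.seed(11)
  c1 <- synthesize_call(tpl, call_jitter = 0, snr_db = 20, sample_rate = 22050)
  set.seed(11)
  c2 <- synthesize_call(tpl, call_jitter = 0, snr_db = 20, sample_rate = 22050)
  expect_identical(c1$waveform, c2$waveform)
})

test_that("requested SNR is recovered from the synthesized clip", {
  cfg <- population_config(seed = 5, sample_rate = 22050,
                           duration_range = c(0.25, 0.25))
  tpl <- make_templates(cfg)$individual$template[[1]]
  set.seed(2)
  call <- synthesize_call(tpl, call_jitter = 0, snr_db = snr_to_db(14),
                          sample_rate = 22050)
  est <- estimate_snr(call$waveform, 22050, call$begin_s, call$end_s)
  expect_lt(abs(est - 14) / 14, 0.05)
})

test_that("per-individual call counts respect the configured range", {
  cfg <- population_config(n_sites_per_region = 2, n_individuals_per_site = 3,
                           calls_per_individual = c(4, 25),
                           duration_range = c(0.1, 0.12),
                           sample_rate = 22050, seed = 21)
  pop <- generate_population(cfg)
  counts <- table(pop$individual_id)
  expect_true(all(counts >= 4 & counts <= 25))
})

test_that("strong signatures give higher within- than among-individual SPCC", {
  pop <- small_pop()
  sm <- small_spcc()
  part <- partition_similarities(sm, pop, "individual")
  expect_gt(mean(part$within$value), mean(part$among$value))
})

test_that("within-site similarity does not decrease as site_weight rises", {
  site_sim <- function(w) {
    vals <- numeric(0)
    for (seed in 1:5) {
      cfg <- population_config(n_sites_per_region = 2,
                               n_individuals_per_site = 3,
                               calls_per_individual = 1,
                               signature_strength = 700, site_weight = w,
                               duration_range = c(0.15, 0.25),
                               sample_rate = 22050, seed = seed)
      pop <- generate_population(cfg)
      sm <- spcc_matrix(pop)
      part <- partition_similarities(sm, dplyr::mutate(pop,
                                                       individual_id = NULL),
                                     "site")
      vals <- c(vals, part$within$value)
    }
    mean(vals)
  }
  expect_gte(site_sim(0.9), site_sim(0))
})

test_that("generated contours stay inside the analysis bandpass", {
  pop <- small_pop()
  for (i in seq_len(nrow(pop))) {
    tplset <- make_templates(attr(pop, "config"))
    freqs <- unlist(lapply(tplset$individual$template, `[[`, "freq_hz"))
    expect_true(all(freqs >= 500 & freqs <= 9000))
  }
})

test_that("site-scale subset keeps one masked call per individual per site", {
  pop <- small_pop()
  site <- site_scale_subset(pop)
  expect_true(all(is.na(site$individual_id)))
  expect_equal(nrow(site),
               nrow(dplyr::distinct(pop, site_id, individual_id)))
  expect_false(any(duplicated(site$true_individual_id)))
})
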