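planted_duplicate_site <- function(seed) {
  # one call per bird for 5 unique birds, except one bird sampled twice
  cfg <- population_config(n_sites_per_region = 1, n_individuals_per_site = 6,
                           calls_per_individual = 2, signature_strength = 900,
                           call_jitter = 80, sample_rate = 22050, seed = seed)
  pop <- generate_population(cfg)
  keep <- !duplicated(pop$individual_id) | pop$individual_id == "R1_S1_I01"
  pop[keep, ]
}

test_that("a planted within-site duplicate is flagged together in most seeds", {
  hits <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    site <- planted_duplicate_site(seed)
    sm <- spcc_matrix(site)
    res <- flag_repeats_gmm(sm, seed = 1)
    dup <- res$assignment[site$individual_id == "R1_S1_I01", ]
    if (nrow(dup) == 2 && dup$cluster[1] == dup$cluster[2] &&
        all(dup$flagged)) {
      hits <- hits + 1L
    }
  }
  # the full 20-seed recovery-rate criterion lives in the acceptance suite
  expect_gte(hits / n_seeds, 0.8)
})

test_that("mutually dissimilar calls produce singleton clusters and no flags", {
  site <- planted_duplicate_site(3)
  site <- site[!duplicated(site$individual_id), ]   # drop the duplicate
  sm <- spcc_matrix(site)
  res <- flag_repeats_gmm(sm, seed = 1)
  expect_false(any(res$assignment$flagged))
  expect_equal(length(unique(res$assignment$cluster)), nrow(site))
})

test_that("single-call sites yield no flags", {
  site <- planted_duplicate_site(1)[1, ]
  sm <- spcc_matrix(site)
  res <- flag_repeats_gmm(sm, seed = 1)
  expect_false(any(res$assignment$flagged))
})

test_that("filtering keeps one call per flagged cluster and is idempotent", {
  site <- planted_duplicate_site(2)
  sm <- spcc_matrix(site)
  asn <- flag_repeats(site, sm, seed = 1)
  filt <- filter_dataset(site, asn)
  n_flagged_clusters <- nrow(dplyr::distinct(asn[asn$flagged, ],
                                             site_id, cluster))
  n_flagged_calls <- sum(asn$flagged)
  expect_equal(nrow(filt), nrow(site) - (n_flagged_calls -
                                           n_flagged_clusters))
  expect_equal(attr(filt, "dataset_variant"), "clustering-filtered")
  # never empties a site
  expect_true(all(unique(site$site_id) %in% filt$site_id))
  # idempotent on its own output
  again <- filter_dataset(filt, asn)
  expect_equal(again$call_id, filt$call_id)
  # no flags anywhere -> identity
  none <- asn
  none$flagged <- FALSE
  expect_equal(filter_dataset(site, none)$call_id, site$call_id)
  expect_error(filter_dataset(site, asn, keep_rule = "centroid"))
})

test_that("medoid keep rule retains the most central flagged call", {
  site <- planted_duplicate_site(2)
  sm <- spcc_matrix(site)
  asn <- flag_repeats(site, sm, seed = 1)
  filt <- filter_dataset(site, asn, keep_rule = "medoid", sim = sm)
  expect_equal(nrow(filt), nrow(filter_dataset(site, asn)))
})

test_that("repeat-sampling statistics aggregate flags per group", {
  asn <- tibble::tibble(
    call_id = paste0("c", 1:8),
    site_id = rep("s1", 8),
    cluster = c(1, 1, 1, 2, 2, 3, 4, 5),
    flagged = c(rep(TRUE, 5), rep(FALSE, 3))
  )
  st <- repeat_sampling_stats(asn)
  expect_equal(st$repeated_individuals_mean, 2)
  expect_equal(st$calls_per_repeat_mean, 2.5)

  # no flags -> zeros with zero SE
  none <- dplyr::mutate(asn, flagged = FALSE)
  st0 <- repeat_sampling_stats(none)
  expect_equal(st0$repeated_individuals_mean, 0)
  expect_equal(st0$calls_per_repeat_mean, 0)
  expect_equal(st0$calls_per_repeat_se, 0)
})

test_that("groups with more planted duplication report more calls per repeat", {
  make_group <- function(dup_inds, n_calls, seed, site) {
    cfg <- population_config(n_sites_per_region = 1,
                             n_individuals_per_site = 6,
                             calls_per_individual = n_calls,
                             signature_strength = 900, call_jitter = 80,
                             sample_rate = 22050, seed = seed)
    pop <- generate_population(cfg)
    keep_all <- unique(pop$individual_id)[seq_len(dup_inds)]
    pop <- pop[!duplicated(pop$individual_id) |
                 pop$individual_id %in% keep_all, ]
    pop$site_id <- site
    pop$call_id <- paste0(site, "_", pop$call_id)
    pop
  }
  low <- make_group(1, n_calls = 2, seed = 4, site = "low_site")
  high <- make_group(3, n_calls = 4, seed = 5, site = "high_site")
  calls <- dplyr::bind_rows(low, high)
  sm <- spcc_matrix(calls)
  asn <- flag_repeats(calls, sm, seed = 1)
  st <- repeat_sampling_stats(
    asn, tibble::tibble(site_id = c("low_site", "high_site"),
                        group = c("low", "high"))
  )
  expect_gt(st$calls_per_repeat_mean[st$group == "high"] + 1e-9,
            st$calls_per_repeat_mean[st$group == "low"])
})
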