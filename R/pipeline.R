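#' Configuration for an end-to-end convergence experiment
#'
#' Bundles the dataset source (a [population_config()] or an existing call
#' tibble), the social scales, similarity methods and dataset variants to
#' test, and the resampling/bootstrap/Mantel settings.
#'
#' @param population A [population_config()] (ignored when `calls` given).
#' @param calls Optional pre-built call tibble.
#' @param scales Social scales to test (subset of individual/site/region).
#' @param methods Similarity methods: `"spcc"`, `"rf"`, or both.
#' @param variants Site-scale dataset variants: `"full"`,
#'   `"clustering-filtered"`.
#' @param n_iter,n_categories,n_per_class,n_bins [emd_convergence()]
#'   settings.
#' @param ratio_k,ratio_iter [bootstrap_similarity_ratio()] settings.
#' @param mantel_perm Mantel permutations (0 skips Mantel tests).
#' @param exclude_same_site,within_region Partition constraints (see
#'   [partition_similarities()]).
#' @param min_snr QC threshold (linear SNR).
#' @param select_features Run shadow-feature selection before training
#'   (slower; default `FALSE` uses all features).
#' @param seed Master seed; stage seeds are derived from it.
#'
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(population = population_config(),
                              calls = NULL,
                              scales = c("individual", "site"),
                              methods = c("spcc", "rf"),
                              variants = c("full", "clustering-filtered"),
                              n_iter = 100, n_categories = 4,
                              n_per_class = 100, n_bins = 16,
                              ratio_k = 5, ratio_iter = 200,
                              mantel_perm = 0,
                              exclude_same_site = FALSE,
                              within_region = FALSE,
                              min_snr = 7,
                              select_features = FALSE,
                              seed = 1) {
  stopifnot(all(scales %in% c("individual", "site", "region")),
            all(methods %in% c("spcc", "rf")),
            all(variants %in% c("full", "clustering-filtered")),
            length(methods) >= 1)
  structure(as.list(environment()), class = "experiment_config")
}

derive_seed <- function(seed, offset) (seed * 97L + offset) %% 2000000000L

#' Run a full hierarchical-mapping experiment
#'
#' Simulates (or takes) a call dataset, applies SNR quality control,
#' derives the individual-scale and site-scale datasets, computes SPCC
#' (and, when requested, random-forest proximity) similarity, builds the
#' duplicate-filtered site-scale variant, and quantifies convergence at
#' each requested social scale with the resampled Earth Mover's Distance
#' statistic, bootstrap similarity ratios, and (optionally) Mantel tests.
#' The report names the winning scale (maximum mean EMD) per method and
#' variant and the ratio between scale means. Fully seed-deterministic.
#'
#' @param config An [experiment_config()].
#'
#' @return A `comparison_report`: list with `results` tibble, `winning`
#'   tibble, `classifier` (when RF was run), `datasets`, and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  calls <- config$calls %||% generate_population(config$population)
  qc <- qc_filter(calls, min_snr = config$min_snr)
  calls <- qc$retained

  ind_calls <- individual_scale_subset(calls, min_calls = 2)
  site_calls <- site_scale_subset(calls)
  datasets <- list(individual = ind_calls, site = site_calls)

  # one joint SPCC pass over the union of both datasets: similarity
  # sub-matrices and (for the forest) embedding features all derive from it,
  # so coordinates are comparable across training, validation and site calls
  audio_cols <- c("call_id", "waveform", "sample_rate", "begin_s", "end_s")
  all_calls <- dplyr::distinct(
    dplyr::bind_rows(ind_calls[audio_cols], site_calls[audio_cols]),
    .data$call_id, .keep_all = TRUE
  )
  sm_all <- spcc_matrix(all_calls)
  sub_sim <- function(ids, method = "SPCC") {
    similarity_matrix(unclass(sm_all)[ids, ids, drop = FALSE],
                      method = method, call_ids = ids)
  }

  mats <- list()
  classifier <- NULL
  validation <- NULL

  if ("spcc" %in% config$methods) {
    if ("individual" %in% config$scales) {
      mats[["SPCC.individual"]] <- sub_sim(ind_calls$call_id)
    }
    mats[["SPCC.site"]] <- sub_sim(site_calls$call_id)
  }
  if ("rf" %in% config$methods) {
    seed_rf <- derive_seed(config$seed, 11L)
    feats_all <- call_feature_table(all_calls)
    dm_all <- dtw_distance_matrix(all_calls)
    feats_all <- add_embedding_features(feats_all, sm_all, k = 2,
                                        prefix = "spcc_mds", seed = seed_rf)
    feats_all <- add_embedding_features(feats_all, dm_all, k = 2,
                                        prefix = "dtw_mds", seed = seed_rf)
    ft_of <- function(ids) feats_all[match(ids, feats_all$call_id), ]
    inds <- unique(ind_calls$individual_id)
    set.seed(seed_rf)
    train_ids <- sort(sample(inds, ceiling(length(inds) / 2)))
    holdout_ids <- setdiff(inds, train_ids)
    train_rows <- ind_calls$call_id[ind_calls$individual_id %in% train_ids]
    holdout_rows <- ind_calls$call_id[
      ind_calls$individual_id %in% holdout_ids]
    sel <- NULL
    if (config$select_features) {
      sel <- select_features(
        ft_of(train_rows),
        ind_calls$individual_id[match(train_rows, ind_calls$call_id)],
        seed = seed_rf
      )
    }
    classifier <- train_individual_classifier(
      ft_of(train_rows),
      ind_calls$individual_id[match(train_rows, ind_calls$call_id)],
      selected = sel, seed = seed_rf
    )
    prox_holdout <- proximity_matrix(classifier, ft_of(holdout_rows))
    validation <- validate_by_clustering(
      prox_holdout,
      ind_calls$individual_id[match(holdout_rows, ind_calls$call_id)],
      training_ids = train_ids, seed = seed_rf
    )
    if ("individual" %in% config$scales) {
      mats[["RF-proximity.individual"]] <- prox_holdout
    }
    mats[["RF-proximity.site"]] <-
      proximity_matrix(classifier, ft_of(site_calls$call_id))
  }

  # duplicate-filtered site-scale variant
  site_variants <- list(full = site_calls)
  assignments <- NULL
  if ("clustering-filtered" %in% config$variants) {
    base_mat <- mats[[paste0(
      if ("spcc" %in% config$methods) "SPCC" else "RF-proximity", ".site")]]
    assignments <- flag_repeats(site_calls, base_mat,
                                seed = derive_seed(config$seed, 23L))
    site_variants[["clustering-filtered"]] <-
      filter_dataset(site_calls, assignments)
  }

  rows <- list()
  for (method in config$methods) {
    mtag <- if (method == "spcc") "SPCC" else "RF-proximity"
    for (scale in config$scales) {
      data_key <- if (scale == "individual") "individual" else "site"
      mat <- mats[[paste0(mtag, ".", data_key)]]
      if (is.null(mat)) next
      variants <- if (data_key == "site") names(site_variants) else "full"
      for (variant in variants) {
        dset <- if (data_key == "site") site_variants[[variant]] else
          datasets$individual
        ids <- intersect(rownames(mat), dset$call_id)
        mat_v <- similarity_matrix(unclass(mat)[ids, ids, drop = FALSE],
                                   method = mtag, call_ids = ids)
        md <- dset
        if (scale %in% c("site", "region")) {
          # unmarked birds: identity is unknown at these scales
          md$individual_id <- NULL
        }
        part <- partition_similarities(
          mat_v, md, scale,
          exclude_same_site = config$exclude_same_site,
          within_region = config$within_region
        )
        seed_s <- derive_seed(config$seed,
                              29L + match(scale, c("individual", "site",
                                                   "region")) +
                                10L * match(variant, names(site_variants)) +
                                100L * match(method, config$methods))
        emd <- emd_convergence_from_partition(
          part, n_iter = config$n_iter, n_categories = config$n_categories,
          n_per_class = config$n_per_class, n_bins = config$n_bins,
          seed = seed_s, method = mtag
        )
        ratio <- bootstrap_similarity_ratio(
          part$within$value, part$among$value, k = config$ratio_k,
          n_iter = config$ratio_iter, seed = seed_s
        )
        mr <- mp <- NA_real_
        if (config$mantel_perm > 0) {
          memb <- membership_matrix(md, scale, call_ids = rownames(mat_v))
          mt <- mantel_test(mat_v, memb, n_perm = config$mantel_perm,
                            seed = seed_s, exact = FALSE)
          mr <- mt$r
          mp <- mt$p
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = dset$range_label[[1]], scale = scale, method = mtag,
          variant = variant, n_calls = nrow(mat_v),
          emd_mean = emd$mean, emd_ci_low = emd$ci_low,
          emd_ci_high = emd$ci_high, ratio_mean = ratio$mean_ratio,
          mantel_r = mr, mantel_p = mp
        )
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  # the individual-scale cell (computed on the repeatedly-sampled dataset,
  # variant "full") is the shared reference when ranking scales within each
  # site-scale dataset variant
  winning <- purrr::map_dfr(
    split(results, list(results$group, results$method, results$variant),
          drop = TRUE),
    function(cell) {
      cand <- results[results$group == cell$group[[1]] &
                        results$method == cell$method[[1]] &
                        (results$scale == "individual" |
                           results$variant == cell$variant[[1]]), ]
      cand <- dplyr::distinct(cand, .data$scale, .keep_all = TRUE)
      tibble::tibble(
        group = cell$group[[1]], method = cell$method[[1]],
        variant = cell$variant[[1]],
        winning_scale = cand$scale[which.max(cand$emd_mean)],
        emd_scale_ratio = max(cand$emd_mean) /
          min(cand$emd_mean[cand$emd_mean > 0])
      )
    }
  )
  structure(list(
    results = results, winning = winning, classifier = classifier,
    validation = validation, assignments = assignments,
    datasets = c(datasets, list(site_variants = site_variants)),
    matrices = mats, config = config
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$results, ...)
  cat("Winning scale per method/variant:\n")
  print(x$winning, ...)
  invisible(x)
}

#' Compare convergence across groups (e.g. years or cities)
#'
#' Collects one scale/method/variant cell from several reports into a trend
#' table, with the individual-scale mean EMD of each report as a reference
#' line (the individual-signature baseline).
#'
#' @param reports Named list of `comparison_report` objects (names =
#'   groups, e.g. years).
#' @param scale,method,variant Which cell to compare.
#'
#' @return Tibble: `group`, `emd_mean`, `emd_ci_low`, `emd_ci_high`,
#'   `reference_individual_emd`.
#' @export
compare_over_groups <- function(reports, scale = "site", method = "SPCC",
                                variant = "full") {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  purrr::map_dfr(names(reports), function(g) {
    res <- reports[[g]]$results
    cell <- res[res$scale == scale & res$method == method &
                  res$variant == variant, ]
    if (nrow(cell) == 0) {
      stop("Report '", g, "' has no ", scale, "/", method, "/", variant,
           " cell.", call. = FALSE)
    }
    ref <- res[res$scale == "individual", ]
    tibble::tibble(
      group = g,
      emd_mean = cell$emd_mean[[1]],
      emd_ci_low = cell$emd_ci_low[[1]],
      emd_ci_high = cell$emd_ci_high[[1]],
      reference_individual_emd = if (nrow(ref)) ref$emd_mean[[1]] else
        NA_real_
    )
  })
}

#' Balanced within/among similarity subsamples for species comparison
#'
#' For each named comparison partition (one per species/range and scale),
#' draws `n_categories` categories and then `n_values` within- and
#' among-category similarity values without replacement, so that every
#' species and scale is represented with equal sampling depth before
#' computing bootstrap similarity ratios or density curves. Errors name the
#' limiting partition when a quota cannot be met.
#'
#' @param partitions Named list of `comparison_partition` objects.
#' @param n_categories Categories per partition (default 4).
#' @param n_values Values per within/among set (default 20).
#' @param seed Integer seed.
#'
#' @return Named list of lists with `within` and `among` numeric vectors of
#'   length `n_values`.
#' @export
subsample_for_species_comparison <- function(partitions, n_categories = 4,
                                             n_values = 20, seed = 1) {
  stopifnot(!is.null(names(partitions)))
  set.seed(seed)
  purrr::imap(partitions, function(part, name) {
    stopifnot(inherits(part, "comparison_partition"))
    eligible <- unique(part$within$category)
    if (length(eligible) < n_categories) {
      stop("Partition '", name, "' (", part$scale, " scale) has only ",
           length(eligible), " categories; quota is ", n_categories, ".",
           call. = FALSE)
    }
    cats <- sample(eligible, n_categories)
    w_pool <- part$within$value[part$within$category %in% cats]
    a_pool <- part$among$value[part$among$cat_a %in% cats |
                                 part$among$cat_b %in% cats]
    if (length(w_pool) < n_values || length(a_pool) < n_values) {
      stop("Partition '", name, "' (", part$scale, " scale) cannot meet the ",
           "quota of ", n_values, " values (pools: ", length(w_pool),
           " within, ", length(a_pool), " among).", call. = FALSE)
    }
    list(within = sample(w_pool, n_values), among = sample(a_pool, n_values))
  })
}
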