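#' Flag likely repeated sampling within one site by GMM clustering
#'
#' Embeds the site's similarity sub-matrix in 2-D with classical (metric)
#' multidimensional scaling (1-D for two calls), fits Gaussian mixtures with
#' 1..`max_components` components, picks the number of components by BIC
#' (ties broken toward fewer components), and flags clusters of two or more
#' calls as putative repeated sampling of one unmarked individual. Metric
#' scaling is used here (rather than the non-metric embedding of the
#' acoustic-space module) because detecting near-identical calls depends on
#' the magnitude of similarity, which rank-only embeddings can distort at
#' small site sizes.
#'
#' @param sim [similarity_matrix()] restricted to one site's calls.
#' @param max_components Cap on mixture components (default: number of
#'   calls).
#' @param seed Integer seed.
#'
#' @return A list: `assignment` tibble (`call_id`, `cluster`, `flagged`) and
#'   `bic` tibble (`G`, `bic`).
#' @export
flag_repeats_gmm <- function(sim, max_components = NULL, seed = 1) {
  n <- nrow(sim)
  ids <- rownames(sim)
  if (n < 2) {
    return(list(
      assignment = tibble::tibble(call_id = ids,
                                  cluster = rep(1L, n),
                                  flagged = rep(FALSE, n)),
      bic = tibble::tibble(G = integer(), bic = numeric())
    ))
  }
  if (n == 2) {
    xy <- matrix(c(0, 1 - unclass(sim)[1, 2]), ncol = 1)
  } else {
    d <- 1 - unclass(sim)
    diag(d) <- 0
    xy <- stats::cmdscale(stats::as.dist(d), k = 2)
    if (ncol(xy) < 2) xy <- cbind(xy, matrix(0, n, 2 - ncol(xy)))
  }
  g_max <- min(max_components %||% n, n)
  set.seed(seed)
  bics <- numeric(0)
  fits <- list()
  for (g in seq_len(g_max)) {
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(xy, G = g,
                                      prior = mclust::priorControl(),
                                      verbose = FALSE)),
      error = function(e) NULL
    )
    if (is.null(fit) || is.na(fit$bic)) next
    bics <- c(bics, stats::setNames(as.numeric(fit$bic), g))
    fits[[as.character(g)]] <- fit
  }
  if (!length(bics)) {
    # clustering failed entirely: treat every call as its own individual
    cls <- seq_len(n)
  } else {
    best_g <- as.integer(names(bics)[which(bics >= max(bics) - 1e-8)][1])
    cls <- fits[[as.character(best_g)]]$classification
  }
  sizes <- table(cls)
  flagged_clusters <- as.integer(names(sizes)[sizes >= 2])
  list(
    assignment = tibble::tibble(
      call_id = ids,
      cluster = as.integer(cls),
      flagged = as.integer(cls) %in% flagged_clusters
    ),
    bic = tibble::tibble(G = as.integer(names(bics)), bic = unname(bics))
  )
}

#' Flag repeated sampling across all sites of a dataset
#'
#' Applies [flag_repeats_gmm()] site by site on the corresponding
#' sub-matrices of a full similarity matrix.
#'
#' @param calls Call tibble (site-scale dataset).
#' @param sim [similarity_matrix()] over the same calls.
#' @inheritParams flag_repeats_gmm
#'
#' @return Assignment tibble: `call_id`, `site_id`, `cluster`, `flagged`.
#' @export
flag_repeats <- function(calls, sim, max_components = NULL, seed = 1) {
  purrr::map_dfr(split(calls$call_id, calls$site_id), function(ids) {
    sub <- unclass(sim)[ids, ids, drop = FALSE]
    sub <- similarity_matrix(sub, method = attr(sim, "method"),
                             call_ids = ids)
    res <- flag_repeats_gmm(sub, max_components = max_components,
                            seed = seed)
    res$assignment
  }, .id = "site_id")[, c("call_id", "site_id", "cluster", "flagged")]
}

#' Filter a dataset down to one call per flagged cluster
#'
#' Within each flagged cluster exactly one call is retained: the first by
#' call id (`keep_rule = "first"`, deterministic default) or the cluster
#' medoid (highest mean within-cluster similarity; requires `sim`).
#' Unflagged calls are untouched, so the filter is idempotent and never
#' removes the last call of a site.
#'
#' @param calls Call tibble.
#' @param assignments Assignment tibble from [flag_repeats()] (or an
#'   externally supplied table in the same format, e.g. from visual
#'   classification).
#' @param keep_rule `"first"` or `"medoid"`.
#' @param sim Similarity matrix (needed for `"medoid"`).
#' @param variant_label Dataset-version tag recorded on the result.
#'
#' @return Filtered call tibble with attribute `dataset_variant`.
#' @export
filter_dataset <- function(calls, assignments,
                           keep_rule = c("first", "medoid"), sim = NULL,
                           variant_label = "clustering-filtered") {
  keep_rule <- match.arg(keep_rule)
  joined <- dplyr::left_join(calls, assignments,
                             by = intersect(c("call_id", "site_id"),
                                            names(assignments)))
  joined$flagged[is.na(joined$flagged)] <- FALSE
  drop_ids <- character(0)
  flagged <- joined[joined$flagged, , drop = FALSE]
  if (nrow(flagged)) {
    groups <- split(flagged$call_id,
                    paste(flagged$site_id, flagged$cluster, sep = "\r"))
    for (ids in groups) {
      if (length(ids) < 2) next
      keep <- if (keep_rule == "first") {
        sort(ids)[1]
      } else {
        if (is.null(sim)) {
          stop("keep_rule = 'medoid' requires the similarity matrix.",
               call. = FALSE)
        }
        sub <- unclass(sim)[ids, ids, drop = FALSE]
        ids[which.max(rowMeans(sub))]
      }
      drop_ids <- c(drop_ids, setdiff(ids, keep))
    }
  }
  out <- calls[!calls$call_id %in% drop_ids, , drop = FALSE]
  attr(out, "dataset_variant") <- variant_label
  out
}

#' Repeat-sampling summary statistics
#'
#' Per group (e.g. range or species): mean and standard error across sites
#' of the number of flagged repeated individuals per site, and mean and SE
#' of the number of calls attributed to each repeated individual. Groups
#' without any flags report zeros.
#'
#' @param assignments Assignment tibble from [flag_repeats()].
#' @param groups Optional tibble (`site_id`, `group`) mapping sites to
#'   groups; default one group `"all"`.
#'
#' @return Tibble: `group`, `n_sites`, `repeated_individuals_mean`/`_se`,
#'   `calls_per_repeat_mean`/`_se`.
#' @export
repeat_sampling_stats <- function(assignments, groups = NULL) {
  if (is.null(groups)) {
    groups <- tibble::tibble(site_id = unique(assignments$site_id),
                             group = "all")
  }
  a <- dplyr::left_join(assignments, groups, by = "site_id")
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  purrr::map_dfr(split(a, a$group), function(g) {
    per_site <- purrr::map_dfr(split(g, g$site_id), function(s) {
      fl <- s[s$flagged, , drop = FALSE]
      sizes <- if (nrow(fl)) as.integer(table(fl$cluster)) else integer(0)
      tibble::tibble(n_repeated = length(sizes),
                     sizes = list(sizes))
    })
    cluster_sizes <- unlist(per_site$sizes)
    tibble::tibble(
      group = g$group[[1]],
      n_sites = nrow(per_site),
      repeated_individuals_mean = mean(per_site$n_repeated),
      repeated_individuals_se = se(per_site$n_repeated),
      calls_per_repeat_mean = if (length(cluster_sizes))
        mean(cluster_sizes) else 0,
      calls_per_repeat_se = if (length(cluster_sizes))
        se(cluster_sizes) else 0
    )
  })
}
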