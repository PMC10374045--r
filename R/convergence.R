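scale_column <- function(scale) {
  switch(scale,
         individual = "individual_id",
         site = "site_id",
         region = "region_id",
         stop("Unknown social scale: ", scale, call. = FALSE))
}

#' Partition pairwise similarities into within/among sets at a social scale
#'
#' Every unordered call pair is counted once: pairs sharing the category at
#' the requested scale go to the `within` set, pairs differing go to the
#' `among` set. Calls without a category label at that scale are dropped.
#' Optional constraints: `exclude_same_site` restricts among-individual
#' pairs to individuals from different sites (controls for shared site
#' membership); `within_region` restricts among-category pairs at the
#' individual and site scales to same-region pairs (controls geographic
#' breadth when comparing species with regional dialects).
#'
#' @param sim A [similarity_matrix()].
#' @param metadata Call tibble with `call_id` and the identity columns.
#' @param scale `"individual"`, `"site"`, or `"region"`.
#' @param exclude_same_site Restrict among-individual pairs to different
#'   sites (individual scale only).
#' @param within_region Restrict among pairs to the same region (individual
#'   and site scales only).
#'
#' @return A `comparison_partition`: list with tibbles `within` (`value`,
#'   `category`) and `among` (`value`, `cat_a`, `cat_b`), the scale, and a
#'   constraint log.
#' @export
partition_similarities <- function(sim, metadata, scale,
                                   exclude_same_site = FALSE,
                                   within_region = FALSE) {
  stopifnot(inherits(sim, "similarity_matrix"))
  ids <- rownames(sim)
  ord <- match(ids, metadata$call_id)
  if (anyNA(ord)) stop("Metadata missing calls present in the matrix.",
                       call. = FALSE)
  md <- metadata[ord, ]
  col <- scale_column(scale)
  if (!col %in% names(md)) {
    stop("Metadata has no '", col, "' column for the ", scale, " scale.",
         call. = FALSE)
  }
  lab <- as.character(md[[col]])
  site <- if ("site_id" %in% names(md)) as.character(md$site_id) else lab
  region <- if ("region_id" %in% names(md)) as.character(md$region_id) else
    rep("all", nrow(md))
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  ok <- !is.na(lab[i]) & !is.na(lab[j])
  same <- ok & lab[i] == lab[j]
  among_ok <- ok & lab[i] != lab[j]
  constraints <- character(0)
  if (exclude_same_site && scale == "individual") {
    among_ok <- among_ok & site[i] != site[j]
    constraints <- c(constraints, "among-individual pairs restricted to different sites")
  }
  if (within_region && scale != "region") {
    among_ok <- among_ok & region[i] == region[j]
    constraints <- c(constraints, "among pairs restricted to the same region")
  }
  vals <- unclass(sim)[idx]
  within <- tibble::tibble(value = vals[same], category = lab[i][same])
  among <- tibble::tibble(value = vals[among_ok],
                          cat_a = lab[i][among_ok], cat_b = lab[j][among_ok])
  cats <- sort(unique(stats::na.omit(lab)))
  lonely <- setdiff(cats, unique(within$category))
  if (length(lonely)) {
    warning(length(lonely), " categor", if (length(lonely) == 1) "y" else "ies",
            " at the ", scale,
            " scale contributed no within-category comparisons (single call).",
            call. = FALSE)
  }
  structure(list(scale = scale, within = within, among = among,
                 categories = cats, constraints = constraints),
            class = "comparison_partition")
}

#' Histogram-based Earth Mover's Distance between two value sets
#'
#' Bins each set into `n_bins` equal-width bins on the domain, normalizes
#' each histogram to unit mass, and computes the 1-D Earth Mover's Distance
#' on bin centers, which on a shared grid reduces to
#' `sum(|CDF_within - CDF_among|) * bin_width`. On the unit domain the
#' result lies in `[0, (n_bins - 1) / n_bins]`; larger values mean the two
#' distributions need more work to transform into each other, i.e. stronger
#' separation of within- from among-category similarity.
#'
#' @param within,among Non-empty numeric vectors inside `domain`.
#' @param n_bins Number of histogram bins (default 16).
#' @param domain Closed interval holding all values (default `c(0, 1)`).
#'
#' @return Non-negative scalar.
#' @export
histogram_emd <- function(within, among, n_bins = 16, domain = c(0, 1)) {
  if (!length(within) || !length(among)) {
    stop("Both value sets must be non-empty.", call. = FALSE)
  }
  if (any(within < domain[1] | within > domain[2]) ||
      any(among < domain[1] | among > domain[2])) {
    stop("Values outside the stated domain.", call. = FALSE)
  }
  width <- (domain[2] - domain[1]) / n_bins
  bin_of <- function(x) pmin(n_bins, floor((x - domain[1]) / width) + 1L)
  pw <- tabulate(bin_of(within), n_bins) / length(within)
  pa <- tabulate(bin_of(among), n_bins) / length(among)
  sum(abs(cumsum(pw - pa))) * width
}

#' Resampled Earth Mover's Distance convergence statistic at one scale
#'
#' Balanced resampling routine: in each of `n_iter`
#' iterations, `n_categories` categories are drawn at random, then
#' `n_per_class` within-category and `n_per_class` among-category similarity
#' values involving those categories are drawn without replacement and their
#' [histogram_emd()] is computed. Balancing sample sizes this way makes EMD
#' values comparable across social scales with very different numbers of
#' pairwise comparisons. Reported as the mean with a percentile 95% CI over
#' iterations; seed-deterministic.
#'
#' @inheritParams partition_similarities
#' @param n_iter Resampling iterations (default 100).
#' @param n_categories Categories subsampled per iteration (default 4).
#' @param n_per_class Values drawn from each of the within and among pools
#'   per iteration (default 100).
#' @param n_bins Histogram bins (default 16).
#' @param seed Integer seed.
#'
#' @return An `emd_result`: list with `mean`, `ci_low`, `ci_high`,
#'   per-iteration `values`, and the resampling settings.
#' @export
emd_convergence <- function(sim, metadata, scale, n_iter = 100,
                            n_categories = 4, n_per_class = 100,
                            n_bins = 16, exclude_same_site = FALSE,
                            within_region = FALSE, seed = 1) {
  part <- partition_similarities(sim, metadata, scale,
                                 exclude_same_site = exclude_same_site,
                                 within_region = within_region)
  emd_convergence_from_partition(part, n_iter = n_iter,
                                 n_categories = n_categories,
                                 n_per_class = n_per_class, n_bins = n_bins,
                                 seed = seed,
                                 method = attr(sim, "method"))
}

#' @rdname emd_convergence
#' @param part A `comparison_partition`.
#' @param method Method tag recorded in the result.
#' @export
emd_convergence_from_partition <- function(part, n_iter = 100,
                                           n_categories = 4,
                                           n_per_class = 100, n_bins = 16,
                                           seed = 1, method = NA_character_) {
  stopifnot(inherits(part, "comparison_partition"))
  eligible <- unique(part$within$category)
  if (length(eligible) < n_categories) {
    stop("Only ", length(eligible), " categories with within-category values",
         " at the ", part$scale, " scale; need n_categories = ", n_categories,
         ".", call. = FALSE)
  }
  if (nrow(part$among) == 0) {
    stop("Among-category value set is empty at the ", part$scale, " scale.",
         call. = FALSE)
  }
  set.seed(seed)
  vals <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    cats <- sample(eligible, n_categories)
    w_pool <- part$within$value[part$within$category %in% cats]
    a_pool <- part$among$value[part$among$cat_a %in% cats |
                                 part$among$cat_b %in% cats]
    if (length(w_pool) < n_per_class || length(a_pool) < n_per_class) {
      stop("Subsample size n_per_class = ", n_per_class,
           " unsatisfiable at the ", part$scale, " scale (pools: ",
           length(w_pool), " within, ", length(a_pool), " among).",
           call. = FALSE)
    }
    w <- sample(w_pool, n_per_class)
    a <- sample(a_pool, n_per_class)
    vals[it] <- histogram_emd(w, a, n_bins = n_bins)
  }
  ci <- unname(stats::quantile(vals, c(0.025, 0.975)))
  structure(list(
    scale = part$scale, method = method,
    mean = mean(vals), ci_low = ci[1], ci_high = ci[2],
    n_iter = n_iter, n_bins = n_bins, n_categories = n_categories,
    n_per_class = n_per_class, values = vals, seed = seed,
    constraints = part$constraints
  ), class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat(sprintf(
    "<emd_result: %s scale, %s similarity>\n  mean EMD %.4f (95%% CI %.4f-%.4f), %d iterations, %d bins\n",
    x$scale, x$method, x$mean, x$ci_low, x$ci_high, x$n_iter, x$n_bins))
  invisible(x)
}

#' Earth Mover's Distance across a grid of bin numbers
#'
#' Repeats [emd_convergence()] for each bin count (same seed, so only the
#' binning varies) to check that conclusions do not hinge on the histogram
#' resolution; the 16-bin row is flagged as the headline calculation.
#'
#' @inheritParams emd_convergence
#' @param bin_grid Integer vector of bin counts (default 6 values incl. 16).
#'
#' @return Tibble: `n_bins`, `mean`, `ci_low`, `ci_high`, `headline`.
#' @export
bin_sensitivity <- function(sim, metadata, scale,
                            bin_grid = c(4, 8, 16, 24, 32, 64),
                            n_iter = 100, n_categories = 4, n_per_class = 100,
                            exclude_same_site = FALSE, within_region = FALSE,
                            seed = 1) {
  part <- partition_similarities(sim, metadata, scale,
                                 exclude_same_site = exclude_same_site,
                                 within_region = within_region)
  purrr::map_dfr(bin_grid, function(nb) {
    r <- emd_convergence_from_partition(part, n_iter = n_iter,
                                        n_categories = n_categories,
                                        n_per_class = n_per_class,
                                        n_bins = nb, seed = seed,
                                        method = attr(sim, "method"))
    tibble::tibble(n_bins = nb, mean = r$mean, ci_low = r$ci_low,
                   ci_high = r$ci_high, headline = nb == 16)
  })
}

#' Bootstrap similarity ratios
#'
#' Per iteration, draws `k` within-category and `k` among-category
#' similarity values with replacement and forms `k` ratios by element-wise
#' division, for `k * n_iter` total ratios (the defaults 5 and 200 give
#' 1000). Ratios near 1 indicate weak convergence; ratios increasingly
#' greater than 1 indicate within-category similarity exceeding
#' among-category similarity. A zero denominator is redrawn and the event
#' counted.
#'
#' @param within,among Non-empty numeric similarity vectors.
#' @param k Values drawn per set per iteration (default 5).
#' @param n_iter Bootstrap iterations (default 200).
#' @param seed Integer seed.
#'
#' @return A `ratio_result`: list with `ratios`, `mean_ratio`, `k`,
#'   `n_iter`, `n_redraws`.
#' @export
bootstrap_similarity_ratio <- function(within, among, k = 5, n_iter = 200,
                                       seed = 1) {
  if (!length(within) || !length(among)) {
    stop("Both value sets must be non-empty.", call. = FALSE)
  }
  if (all(among == 0)) {
    stop("All among-category values are zero; ratios undefined.",
         call. = FALSE)
  }
  set.seed(seed)
  ratios <- numeric(k * n_iter)
  n_redraws <- 0L
  for (it in seq_len(n_iter)) {
    num <- sample(within, k, replace = TRUE)
    den <- sample(among, k, replace = TRUE)
    while (any(den == 0)) {
      zero <- den == 0
      den[zero] <- sample(among, sum(zero), replace = TRUE)
      n_redraws <- n_redraws + sum(zero)
    }
    ratios[(it - 1) * k + seq_len(k)] <- num / den
  }
  structure(list(ratios = ratios, mean_ratio = mean(ratios), k = k,
                 n_iter = n_iter, n_redraws = n_redraws, seed = seed),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf(
    "<ratio_result: %d ratios (%d x %d), mean %.3f>\n",
    length(x$ratios), x$n_iter, x$k, x$mean_ratio))
  invisible(x)
}

#' Binary same-category membership matrix
#'
#' @param metadata Call tibble.
#' @param scale Social scale (see [partition_similarities()]).
#' @param call_ids Order of calls (default metadata order).
#'
#' @return Symmetric 0/1 matrix (1 = same category) with unit diagonal.
#' @export
membership_matrix <- function(metadata, scale, call_ids = metadata$call_id) {
  md <- metadata[match(call_ids, metadata$call_id), ]
  lab <- as.character(md[[scale_column(scale)]])
  if (anyNA(lab)) {
    stop("All calls need a category label at the ", scale, " scale.",
         call. = FALSE)
  }
  m <- outer(lab, lab, `==`) * 1
  dimnames(m) <- list(call_ids, call_ids)
  m
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Mantel permutation test of similarity against category membership
#'
#' Correlates the off-diagonal upper triangles of an acoustic similarity
#' matrix and a binary same-category membership matrix, building the null by
#' jointly permuting the rows and columns of the membership matrix.
#' One-sided (greater), since acoustic convergence predicts a positive
#' matrix correlation; the sampled p-value uses the add-one convention
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`. For `n <= 7` objects (or
#' `exact = TRUE`) all permutations are enumerated and the p-value is exact.
#'
#' @param sim A [similarity_matrix()].
#' @param membership Binary symmetric matrix in the same call order (e.g.
#'   from [membership_matrix()]).
#' @param n_perm Number of sampled permutations (default 999).
#' @param seed Integer seed.
#' @param exact Force (or forbid) full enumeration; default `NULL`
#'   enumerates when `n <= 7`.
#'
#' @return A `mantel_result`: list with `r`, `p`, `n_perm`, `exact`.
#' @export
mantel_test <- function(sim, membership, n_perm = 999, seed = 1,
                        exact = NULL) {
  stopifnot(nrow(sim) == nrow(membership), ncol(sim) == ncol(membership))
  n <- nrow(sim)
  ut <- upper.tri(sim)
  x <- unclass(sim)[ut]
  y0 <- membership
  if (stats::sd(x) == 0 || stats::sd(membership[ut]) == 0) {
    stop("Constant off-diagonal values; Mantel r undefined.", call. = FALSE)
  }
  r_of <- function(perm) {
    stats::cor(x, y0[perm, perm][ut])
  }
  r_obs <- r_of(seq_len(n))
  if (is.null(exact)) exact <- n <= 7
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, r_of, numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(i) r_of(sample.int(n)),
                     numeric(1))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result: r = %.4f, p = %.4g (%s, %d permutations)>\n",
              x$r, x$p, if (x$exact) "exact" else "sampled", x$n_perm))
  invisible(x)
}
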