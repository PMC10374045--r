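feature_matrix <- function(features) {
  x <- dplyr::select(features, -dplyr::any_of("call_id"))
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  if (anyNA(x)) stop("Feature table contains missing values.", call. = FALSE)
  as.data.frame(x)
}

#' Shadow-feature selection of informative acoustic features
#'
#' Boruta-style procedure: in each round, a permuted (shadow) copy of every
#' feature is appended, a random forest is fit, and a real feature scores a
#' hit when its impurity importance exceeds the maximum shadow importance.
#' Features whose hit count is significantly above the coin-flip null
#' (one-sided binomial at 5%) are retained. If no feature survives (e.g.
#' shuffled labels), the procedure falls back to the top `fallback_k`
#' features by mean importance, with a warning.
#'
#' @param features Feature tibble (optionally with `call_id`).
#' @param labels Class label per row (individual identity).
#' @param n_rounds Shadow rounds (default 20).
#' @param num_trees Trees per round (default 300).
#' @param fallback_k Features kept by the fallback (default 10).
#' @param seed Integer seed.
#'
#' @return Character vector of retained feature names, with attributes
#'   `hits` (per-feature hit counts) and `fallback` (logical).
#' @export
select_features <- function(features, labels, n_rounds = 20,
                            num_trees = 300, fallback_k = 10, seed = 1) {
  x <- feature_matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels), nlevels(labels) >= 2)
  p <- ncol(x)
  hits <- stats::setNames(integer(p), names(x))
  imp_sum <- stats::setNames(numeric(p), names(x))
  set.seed(seed)
  for (round in seq_len(n_rounds)) {
    shadow <- as.data.frame(lapply(x, sample))
    names(shadow) <- paste0(".shadow_", names(x))
    df <- cbind(x, shadow)
    df$.class <- labels
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = df,
      num.trees = num_trees, importance = "impurity",
      seed = seed * 1000 + round
    )
    imp <- fit$variable.importance
    real <- imp[names(x)]
    thr <- max(imp[names(shadow)])
    hits <- hits + (real > thr)
    imp_sum <- imp_sum + real
  }
  # retained iff hits are significantly above the coin-flip null
  # (one-sided binomial at 5%), the usual shadow-feature decision rule
  thr_hits <- stats::qbinom(0.95, n_rounds, 0.5) + 1
  selected <- names(hits)[hits >= thr_hits]
  fallback <- FALSE
  if (!length(selected)) {
    warning("Shadow-feature selection rejected all features; ",
            "falling back to the top ", fallback_k, " by mean importance.",
            call. = FALSE)
    selected <- names(sort(imp_sum, decreasing = TRUE))[
      seq_len(min(fallback_k, p))]
    fallback <- TRUE
  }
  structure(selected, hits = hits, fallback = fallback)
}

#' Train a random-forest individual classifier
#'
#' Fits a random forest classifying calls back to repeatedly sampled
#' individuals. Accuracy is reported from out-of-bag predictions with an
#' exact binomial (Clopper-Pearson) 95% CI, plus per-class balanced
#' accuracy (mean of sensitivity and specificity).
#'
#' @param features Feature tibble (optionally with `call_id`).
#' @param labels Individual identity per row.
#' @param selected Optional character vector of feature names to use (e.g.
#'   from [select_features()]); default all.
#' @param num_trees Number of trees (default 500).
#' @param seed Integer seed.
#'
#' @return A `call_classifier`: list with the fitted `model`, `features`
#'   used, `accuracy` (%), `accuracy_ci` (%), `balanced_accuracy` tibble,
#'   `levels`, `seed`.
#' @export
train_individual_classifier <- function(features, labels, selected = NULL,
                                        num_trees = 500, seed = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("Need at least 2 individuals.", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("Every individual needs at least 2 calls for training; short: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  x <- feature_matrix(features)
  if (!is.null(selected)) {
    missing <- setdiff(selected, names(x))
    if (length(missing)) {
      stop("Selected features absent from table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- x[, selected, drop = FALSE]
  }
  df <- x
  df$.class <- labels
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, importance = "impurity", seed = seed
  )
  oob <- fit$predictions
  ok <- !is.na(oob)
  n_ok <- sum(ok)
  n_correct <- sum(oob[ok] == labels[ok])
  ci <- as.numeric(stats::binom.test(n_correct, n_ok)$conf.int)
  bal <- purrr::map_dfr(levels(labels), function(cl) {
    tp <- sum(ok & oob == cl & labels == cl)
    fn <- sum(ok & oob != cl & labels == cl)
    tn <- sum(ok & oob != cl & labels != cl)
    fp <- sum(ok & oob == cl & labels != cl)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    tibble::tibble(individual = cl, n_calls = sum(labels == cl),
                   sensitivity = sens, specificity = spec,
                   balanced_accuracy = 100 * (sens + spec) / 2)
  })
  structure(list(
    model = fit,
    features = names(x),
    accuracy = 100 * n_correct / n_ok,
    accuracy_ci = 100 * ci,
    balanced_accuracy = bal,
    levels = levels(labels),
    num_trees = num_trees,
    seed = seed
  ), class = "call_classifier")
}

#' @export
print.call_classifier <- function(x, ...) {
  cat(sprintf(
    "<call_classifier: %d individuals, %d features, %d trees>\n  accuracy %.2f%% (95%% CI %.2f-%.2f%%)\n",
    length(x$levels), length(x$features), x$num_trees,
    x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2]))
  invisible(x)
}

#' Random-forest proximity similarity matrix
#'
#' Runs calls down the persisted forest and computes proximity(i, j) = the
#' fraction of trees in which calls i and j land in the same terminal node,
#' a supervised similarity in `[0, 1]` with unit diagonal.
#'
#' @param classifier A `call_classifier`.
#' @param features Feature tibble containing the classifier's features (and
#'   `call_id` for the matrix index).
#'
#' @return A [similarity_matrix()] with method `"RF-proximity"`.
#' @export
proximity_matrix <- function(classifier, features) {
  stopifnot(inherits(classifier, "call_classifier"))
  x <- feature_matrix(features)
  missing <- setdiff(classifier$features, names(x))
  if (length(missing)) {
    stop("Feature table lacks model features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[, classifier$features, drop = FALSE]
  nodes <- stats::predict(classifier$model, data = x,
                          type = "terminalNodes")$predictions
  n <- nrow(nodes)
  n_trees <- ncol(nodes)
  m <- matrix(0, n, n)
  for (t in seq_len(n_trees)) {
    m <- m + outer(nodes[, t], nodes[, t], `==`)
  }
  m <- m / n_trees
  ids <- if ("call_id" %in% names(features)) features$call_id else
    as.character(seq_len(n))
  similarity_matrix(m, method = "RF-proximity", call_ids = ids)
}

#' Validate a classifier by clustering held-out individuals
#'
#' Embeds the holdout proximity matrix in 2-D, fits Gaussian mixture models
#' with 1 to `n_individuals + 2` components, selects the number of
#' components by BIC, and reports agreement between the clustering and true
#' holdout identity as the adjusted Rand index. Holdout individuals must be
#' disjoint from the training individuals (the caller's pipeline hygiene;
#' asserted when training ids are supplied).
#'
#' @param proximity [similarity_matrix()] over holdout calls.
#' @param labels True holdout identity per call (matrix order).
#' @param training_ids Optional character vector of training individual ids
#'   used to assert train/validation disjointness.
#' @param seed Integer seed.
#'
#' @return A list: `ari`, `clusters` tibble, `n_components`, `bic`.
#' @export
validate_by_clustering <- function(proximity, labels, training_ids = NULL,
                                   seed = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("Need at least 2 holdout individuals.", call. = FALSE)
  }
  if (!is.null(training_ids) && length(intersect(labels, training_ids))) {
    stop("Holdout individuals overlap the training individuals: ",
         paste(intersect(labels, training_ids), collapse = ", "),
         call. = FALSE)
  }
  n_ind <- length(unique(labels))
  emb <- nmds_embed(proximity, k = 2, seed = seed)
  xy <- as.matrix(emb$coords[, c("dim1", "dim2")])
  if (nrow(unique(xy)) == 1) {
    warning("All holdout calls are identical in proximity; single cluster, ",
            "ARI reported as 0 by convention.", call. = FALSE)
    return(list(ari = 0,
                clusters = tibble::tibble(call_id = emb$coords$call_id,
                                          cluster = 1L, truth = labels),
                n_components = 1L, bic = NA_real_))
  }
  set.seed(seed)
  fit <- suppressWarnings(
    mclust::Mclust(xy, G = seq_len(n_ind + 2),
                   prior = mclust::priorControl(), verbose = FALSE)
  )
  ari <- mclust::adjustedRandIndex(fit$classification, labels)
  list(
    ari = ari,
    clusters = tibble::tibble(call_id = emb$coords$call_id,
                              cluster = fit$classification, truth = labels),
    n_components = fit$G,
    bic = as.numeric(fit$bic)
  )
}
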