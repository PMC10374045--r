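#' Tidy an EMD convergence result into per-iteration values
#'
#' @param x An `emd_result`.
#' @param ... Unused.
#' @return Tibble: `iteration`, `emd`, `scale`, `method`.
#' @export
tidy.emd_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$values), emd = x$values,
                 scale = x$scale, method = x$method)
}

#' One-row summary of an EMD convergence result
#'
#' @param x An `emd_result`.
#' @param ... Unused.
#' @return Tibble with mean, CI and resampling settings.
#' @export
glance.emd_result <- function(x, ...) {
  tibble::tibble(scale = x$scale, method = x$method, emd_mean = x$mean,
                 ci_low = x$ci_low, ci_high = x$ci_high, n_iter = x$n_iter,
                 n_bins = x$n_bins, n_categories = x$n_categories,
                 n_per_class = x$n_per_class)
}

#' Tidy a bootstrap ratio result into per-draw ratios
#'
#' @param x A `ratio_result`.
#' @param ... Unused.
#' @return Tibble: `iteration`, `draw`, `ratio`.
#' @export
tidy.ratio_result <- function(x, ...) {
  tibble::tibble(
    iteration = rep(seq_len(x$n_iter), each = x$k),
    draw = rep(seq_len(x$k), x$n_iter),
    ratio = x$ratios
  )
}

#' One-row summary of a bootstrap ratio result
#'
#' @param x A `ratio_result`.
#' @param ... Unused.
#' @return Tibble with the mean ratio and settings.
#' @export
glance.ratio_result <- function(x, ...) {
  tibble::tibble(mean_ratio = x$mean_ratio, n_ratios = length(x$ratios),
                 k = x$k, n_iter = x$n_iter, n_redraws = x$n_redraws)
}

#' Tidy a classifier into per-individual performance
#'
#' @param x A `call_classifier`.
#' @param ... Unused.
#' @return The per-class balanced accuracy tibble.
#' @export
tidy.call_classifier <- function(x, ...) x$balanced_accuracy

#' One-row summary of a classifier
#'
#' @param x A `call_classifier`.
#' @param ... Unused.
#' @return Tibble with accuracy, CI and model size.
#' @export
glance.call_classifier <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, ci_low = x$accuracy_ci[1],
                 ci_high = x$accuracy_ci[2],
                 n_individuals = length(x$levels),
                 n_features = length(x$features), num_trees = x$num_trees)
}

#' Tidy an acoustic embedding into coordinates
#'
#' @param x An `acoustic_embedding`.
#' @param ... Unused.
#' @return The coordinate tibble (`call_id`, `dim1..dimk`).
#' @export
tidy.acoustic_embedding <- function(x, ...) x$coords

#' One-row summary of an acoustic embedding
#'
#' @param x An `acoustic_embedding`.
#' @param ... Unused.
#' @return Tibble with stress and settings.
#' @export
glance.acoustic_embedding <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, restarts = x$restarts,
                 n_calls = nrow(x$coords), method = x$method)
}

#' Tidy a Mantel test result
#'
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `n_perm`, `exact`.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(statistic = x$r, p.value = x$p, n_perm = x$n_perm,
                 exact = x$exact)
}
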