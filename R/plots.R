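#' Plot calls in acoustic space
#'
#' Scatter plot of a 2-D embedding, optionally colored by a category label
#' (individual, site, region) with convex hull outlines per category.
#'
#' @param object An `acoustic_embedding`.
#' @param labels Optional category label per call.
#' @param hulls Draw convex hulls per category (default `TRUE` when labels
#'   are given).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.acoustic_embedding <- function(object, labels = NULL,
                                        hulls = !is.null(labels), ...) {
  df <- object$coords
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
      ggplot2::geom_point(alpha = 0.8)
  } else {
    df$category <- as.character(labels)
    g <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data$category)) +
      ggplot2::geom_point(alpha = 0.8)
    if (hulls) {
      hull_df <- dplyr::slice(
        dplyr::group_by(df, .data$category),
        grDevices::chull(.data$dim1, .data$dim2)
      )
      g <- g + ggplot2::geom_polygon(
        data = hull_df,
        ggplot2::aes(fill = .data$category), alpha = 0.15,
        show.legend = FALSE
      )
    }
    g
  }
  p +
    ggplot2::labs(
      x = "MDS dimension 1", y = "MDS dimension 2",
      subtitle = sprintf("%s similarity, stress = %.3f",
                         object$method, object$stress)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the resampled EMD distribution at one scale
#'
#' Histogram of the per-iteration Earth Mover's Distance values with the
#' mean and 95% CI marked.
#'
#' @param object An `emd_result`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.emd_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$emd)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "red") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        colour = "red", linetype = 2) +
    ggplot2::labs(
      x = "Earth Mover's Distance", y = "Iterations",
      subtitle = sprintf("%s scale, %s similarity: mean %.3f (%.3f-%.3f)",
                         object$scale, object$method, object$mean,
                         object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Plot convergence across social scales
#'
#' Dot-and-error-bar plot of mean EMD with 95% CI per scale, method and
#' dataset variant — the hierarchical mapping profile of a report.
#'
#' @param report A `comparison_report` from [run_experiment()].
#'
#' @return A ggplot object.
#' @export
plot_convergence_profile <- function(report) {
  df <- report$results
  ggplot2::ggplot(df, ggplot2::aes(.data$scale, .data$emd_mean,
                                   colour = .data$method,
                                   shape = .data$variant)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$emd_ci_low, ymax = .data$emd_ci_high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(x = "Social scale", y = "Earth Mover's Distance",
                  colour = "Similarity", shape = "Dataset") +
    ggplot2::theme_minimal()
}
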