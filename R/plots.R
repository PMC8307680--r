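# ggplot2 visualisations for the pipeline's result types.

#' Plot an unsupervised embedding
#'
#' Scatter of the 2-D NMDS coordinates coloured by group, annotated with the
#' mean group silhouette.
#'
#' @param object An `embedding_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.embedding_result <- function(object, ...) {
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      title = "Unsupervised 2-D embedding (NMDS)",
      subtitle = sprintf("stress %.3f; mean group silhouette %.3f",
                         object$stress, object$silhouette),
      x = "NMDS1", y = "NMDS2", colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated classification metrics
#'
#' Fold-aggregated means with confidence intervals for accuracy and AUC in
#' the training and test sets.
#'
#' @param object A `cv_report`.
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, metrics = c("accuracy", "auc"), ...) {
  df <- filter(object$summary, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$mean,
                                   colour = .data$set)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(~ .data$metric) +
    ggplot2::labs(title = "Cross-validated classification performance",
                  x = NULL, y = "mean (CI over folds)") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot lipid-class composition
#'
#' Mean relative contribution of each lipid class to the total lipid
#' concentration, by group.
#'
#' @param class_composition Output of [aggregate_classes()].
#' @return A ggplot.
#' @export
plot_class_composition <- function(class_composition) {
  df <- class_composition |>
    group_by(.data$group, .data$class) |>
    summarise(mean_share = mean(.data$share_pct), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_share,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "Lipid-class composition",
                  x = NULL, y = "mean share of total lipid (%)", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a feature ranking with its elbow
#'
#' Selection frequencies along the ranked list, with the elbow cutoff marked.
#'
#' @param object A `feature_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_ranking <- function(object, ...) {
  ggplot2::ggplot(object$ranking,
                  ggplot2::aes(x = .data$rank, y = .data$frequency)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rank <= object$elbow)) +
    ggplot2::geom_vline(xintercept = object$elbow + 0.5, linetype = "dashed") +
    ggplot2::labs(title = "MRCV feature ranking",
                  x = "rank", y = "selection frequency",
                  colour = "in final set") +
    ggplot2::theme_minimal()
}
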