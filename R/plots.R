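#' Cluster composition bar plot
#'
#' Per-cluster bar of the cell fractions contributed by each subject group
#' -- the display used to spot a disease-associated cluster by eye.
#'
#' @param clusters a `cgps_clusters`.
#' @return A ggplot object.
#' @export
plot_cluster_composition <- function(clusters) {
  stopifnot(inherits(clusters, "cgps_clusters"))
  ggplot2::ggplot(clusters$composition,
                  ggplot2::aes(x = factor(.data$cluster), y = .data$fraction,
                               fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Cluster", y = "Fraction of cluster cells",
                  fill = "Group") +
    ggplot2::theme_minimal()
}

#' @method autoplot cgps_clusters
#' @export
autoplot.cgps_clusters <- function(object, ...) plot_cluster_composition(object)

#' cGPS strip plot by group or outcome
#'
#' Jittered per-subject scores with the decision threshold as a dashed
#' line.
#'
#' @param records cGPS record table from [cgps_records()] or a monitoring
#'   result's `records`.
#' @param by unquoted column to group the x-axis by (default `group`).
#' @param threshold optional threshold line.
#' @return A ggplot object.
#' @export
plot_score_strip <- function(records, by = group, threshold = NULL) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = factor(dplyr::pull(records, {{ by }})),
                                    y = .data$score)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8,
                         colour = "#c0392b") +
    ggplot2::labs(x = NULL, y = "cGPS") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "navy")
  }
  p
}

#' Validation AUC by combination class
#'
#' Scatter of stage-2 AUC per screened marker combination, grouped by
#' subset size -- the display used to pick the minimal high-AUC panel.
#'
#' @param combo_table tibble from [combo_summary()] or a discovery
#'   result's `combo_table`.
#' @param auc_cutoff stage-2 cutoff line.
#' @return A ggplot object.
#' @export
plot_combo_auc <- function(combo_table, auc_cutoff = 0.9) {
  dat <- filter(combo_table, !is.na(.data$validation_auc))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$combo_class,
                                    y = .data$validation_auc)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = auc_cutoff, linetype = "dashed",
                        colour = "navy") +
    ggplot2::labs(x = "Combination class", y = "Validation AUC") +
    ggplot2::theme_minimal()
}
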