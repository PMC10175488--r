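#' Plot a PCoA ordination
#'
#' @param object A `pcoa_ord` from [pcoa_ordination()].
#' @param labels Optional vector or tibble (`sample`, label column) used to
#'   color points, e.g. ICST assignments or host groups.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      lab_col <- setdiff(names(labels), "sample")[1]
      df$label <- labels[[lab_col]][match(df$sample, labels$sample)]
    } else {
      df$label <- labels
    }
  }
  pct <- round(100 * object$explained[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  p <- if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$label), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::labs(x = paste0("PCoA axis 1 (", pct[1], "%)"),
                  y = paste0("PCoA axis 2 (", pct[2], "%)"),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the silhouette trace of an enzymatic-profile model
#'
#' @param object An `ep_model` from [cluster_profiles()].
#' @param ... Unused.
#' @return A ggplot object showing mean silhouette width against candidate
#'   k, with the selected k marked.
#' @method autoplot ep_model
#' @export
autoplot.ep_model <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters (k)",
                  y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Stacked-bar view of ICST composition by host group
#'
#' @param object An `icst_model` from [fit_icsts()].
#' @param metadata Tibble with `sample` and `group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot icst_model
#' @export
autoplot.icst_model <- function(object, metadata = NULL, ...) {
  df <- object$assignments
  if (!is.null(metadata)) {
    df$group <- metadata$group[match(df$sample, metadata$sample)]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$icst,
                                          fill = .data$group)) +
      ggplot2::geom_bar(position = "stack")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$icst)) +
      ggplot2::geom_bar()
  }
  p +
    ggplot2::labs(x = NULL, y = "samples", fill = "host group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a PS multiplicity distribution table
#'
#' @param mult Tibble from [ps_multiplicity_table()].
#' @return A ggplot object: stacked multiplicity bins per species, faceted
#'   by group.
#' @export
plot_multiplicity <- function(mult) {
  long <- tidyr::pivot_longer(mult,
                              dplyr::starts_with("p", ignore.case = FALSE) &
                                dplyr::matches("^p[0-9]+$"),
                              names_to = "multiplicity",
                              values_to = "percent")
  long$multiplicity <- sub("^p", "", long$multiplicity)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$percent,
                                     fill = .data$multiplicity)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$group) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of group samples",
                  fill = "PS count") +
    ggplot2::theme_minimal()
}
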