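#' Plot methods for mesoniche results
#'
#' `autoplot()` methods give quick ggplot2 views of each result type:
#' ordination scatter for NMDS, biplot arrows for constrained
#' ordinations, distance-to-centroid boxplots for dispersion tests, call
#' counts for eco-region classifications, and module size/sign summaries
#' for network partitions.
#'
#' @param object a result object.
#' @param groups optional per-sample grouping for colouring NMDS points.
#' @param ... unused.
#' @return a ggplot.
#' @name mesoniche-plots
NULL

#' @rdname mesoniche-plots
#' @export
autoplot.nmds_result <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (!is.null(groups)) df$group <- as.character(groups)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::labs(caption = paste0("stress = ", signif(object$stress, 3))) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' @rdname mesoniche-plots
#' @export
autoplot.ordination_result <- function(object, groups = NULL, ...) {
  sites <- as_tibble(object$site_scores, rownames = "sample_id")
  bp <- as_tibble(object$biplot_scores, rownames = "variable")
  ax <- colnames(object$site_scores)[1:2]
  scl <- max(abs(sites[[ax[1]]]), abs(sites[[ax[2]]]))
  if (!is.null(groups)) sites$group <- as.character(groups)
  p <- ggplot2::ggplot(sites, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]]))
  p <- if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  p +
    ggplot2::geom_segment(data = bp,
                          ggplot2::aes(x = 0, y = 0,
                                       xend = .data[[ax[1]]] * scl,
                                       yend = .data[[ax[2]]] * scl),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "grey30") +
    ggplot2::geom_text(data = bp,
                       ggplot2::aes(x = .data[[ax[1]]] * scl * 1.08,
                                    y = .data[[ax[2]]] * scl * 1.08,
                                    label = .data$variable), size = 3) +
    ggplot2::labs(caption = paste0("constrained: ",
                                   round(100 * object$constrained_proportion, 1), "%")) +
    ggplot2::theme_minimal()
}

#' @rdname mesoniche-plots
#' @export
autoplot.dispersion_result <- function(object, ...) {
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$group, y = .data$dist_to_centroid)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "distance to group centroid",
                  caption = paste0("F = ", signif(object$F_disp, 3),
                                   ", p = ", signif(object$p_perm, 3))) +
    ggplot2::theme_minimal()
}

#' @rdname mesoniche-plots
#' @export
autoplot.ecoregion_calls <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$call)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "eco-region call", y = "OTUs") +
    ggplot2::theme_minimal()
}

#' @rdname mesoniche-plots
#' @export
autoplot.module_partition <- function(object, ...) {
  df <- object$summaries |>
    tidyr::pivot_longer(c("positive_edges", "negative_edges"),
                        names_to = "sign", values_to = "edges")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$module), y = .data$edges,
                                   fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "module",
                  caption = paste0("Q = ", round(object$Q, 3))) +
    ggplot2::theme_minimal()
}
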