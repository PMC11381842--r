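#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a Holm-filtered correlation matrix
#'
#' Tiles the lipid-by-ROI Pearson correlations, blanking pairs that do not
#' survive the Holm correction (when the result has been filtered).
#'
#' @param object A `correlation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_result <- function(object, ...) {
  tb <- tidy(object)
  if ("significant" %in% names(tb)) {
    tb$r[!tb$significant] <- NA_real_
  }
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$roi, y = .data$lipid,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", limits = c(-1, 1),
                                  na.value = "grey95") +
    ggplot2::labs(
      title = sprintf("Lipid-%s correlations (Holm-filtered)",
                      object$modality),
      x = NULL, y = NULL, fill = "r"
    ) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}

#' Beanplot-style display of significant correlations per tract
#'
#' Violin of the Holm-significant correlation values of each tract, the
#' per-tract view of whether lipid associations are predominantly positive
#' or negative.
#'
#' @param summary_tb Output of [roi_sign_summary()].
#' @param min_n Only tracts with at least this many significant lipids are
#'   shown (default 1).
#' @return A ggplot object.
#' @export
plot_sign_summary <- function(summary_tb, min_n = 1) {
  tb <- summary_tb[summary_tb$n_sig >= min_n, ]
  if (nrow(tb) == 0) stop("no tract has significant correlations",
                          call. = FALSE)
  long <- tidyr::unnest(tb[, c("roi", "r_values")],
                        cols = "r_values")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$roi,
                                                        .data$r_values,
                                                        FUN = mean),
                                     y = .data$r_values)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.5, scale = "width") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "significant Pearson r") +
    ggplot2::theme_minimal(base_size = 8)
}

#' Histogram of the burden-of-injury distribution
#'
#' @param object An `abnormality_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abnormality_profile <- function(object, ...) {
  ggplot2::ggplot(object$burden, ggplot2::aes(x = .data$burden)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "burden of injury (% abnormal tracts)",
                  y = "patients") +
    ggplot2::theme_minimal()
}

#' Heatmap of the lipid-class by tract injury correlations
#'
#' Rows and columns follow the hierarchical-clustering order stored on the
#' object.
#'
#' @param object A `class_injury_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_injury_matrix <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  tb$roi <- factor(tb$roi, levels = attr(object, "roi_order"))
  tb$class <- factor(tb$class, levels = attr(object, "class_order"))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$class, y = .data$roi,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", na.value = "grey90") +
    ggplot2::labs(x = "lipid class", y = NULL,
                  fill = "r(class sum,\ninjury)") +
    ggplot2::theme_minimal(base_size = 8)
}

#' Boxplot of held-out AUCs across repeats
#'
#' @param object An `auc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.auc_report <- function(object, ...) {
  s <- object$spec
  ggplot2::ggplot(object$results, ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(
      x = NULL, y = "held-out AUC",
      title = sprintf("%s / %s / %s", s$penalty, s$features, s$scope)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Circular layout plot of a partial-correlation network
#'
#' Lipid, tract and covariate nodes on a circle grouped by type, with edges
#' coloured by the sign of the partial correlation (blue positive, red
#' negative).
#'
#' @param object A `partial_corr_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partial_corr_graph <- function(object, ...) {
  nodes <- dplyr::arrange(object$nodes, .data$type, .data$group, .data$node)
  nn <- nrow(nodes)
  theta <- 2 * pi * (seq_len(nn) - 1) / nn
  nodes$x <- cos(theta)
  nodes$y <- sin(theta)
  e <- object$edges
  e$x0 <- nodes$x[match(e$from, nodes$node)]
  e$y0 <- nodes$y[match(e$from, nodes$node)]
  e$x1 <- nodes$x[match(e$to, nodes$node)]
  e$y1 <- nodes$y[match(e$to, nodes$node)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$sign,
                   linewidth = abs(.data$partial_r)),
      alpha = 0.5
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type),
      size = 2
    ) +
    ggplot2::scale_colour_manual(values = c(positive = "navy",
                                            negative = "firebrick")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s partial-correlation network (alpha = %g)",
                                  object$modality, object$alpha)) +
    ggplot2::theme_void()
}
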