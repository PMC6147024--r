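# ggplot2 displays for the main result types.

#' Volcano-style plot of DMF calls
#'
#' @param object A `dmf_tbl` from [call_dmfs()].
#' @param ... Unused.
#' @return A ggplot: methylation difference against -log10 q, with the
#'   joint DMF thresholds drawn.
#' @export
autoplot.dmf_tbl <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  delta <- attr(object, "delta") %||% 0.25
  ggplot2::ggplot(object, ggplot2::aes(x = .data$diff, y = -log10(.data$q),
                                       colour = .data$is_dmf)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-delta, delta), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "methylation difference (group B - group A)",
                  y = expression(-log[10] ~ q), colour = "DMF") +
    ggplot2::theme_minimal()
}

#' Element-wise group medians of a methylation summary
#'
#' @param object A `meth_summary` from [global_summary()].
#' @param ... Unused.
#' @export
autoplot.meth_summary <- function(object, ...) {
  el <- tidy.meth_summary(object)
  if (nrow(el) == 0L) rlang::abort("summary carries no element annotation")
  long <- tidyr::pivot_longer(el, c("median_A", "median_B"),
                              names_to = "group", values_to = "median")
  long$group <- names(object$group_median)[match(long$group, c("median_A", "median_B"))]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$median,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(~kind, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "median methylation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Correlogram tile plot
#'
#' @param object A `correlogram` from [regulator_correlogram()].
#' @param ... Unused.
#' @export
autoplot.correlogram <- function(object, ...) {
  nm <- rownames(object$rho)
  long <- tibble::tibble(
    var1 = factor(rep(nm, times = length(nm)), levels = nm),
    var2 = factor(rep(nm, each = length(nm)), levels = rev(nm)),
    rho = as.vector(object$rho))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$var1, y = .data$var2,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a scaled expression panel
#'
#' @param scaled Output of [panel_matrix()] or [scale_expression()].
#' @param design Optional [study_design()] used to order samples by group.
#' @return A ggplot tile heatmap (genes x samples).
#' @export
plot_panel_heatmap <- function(scaled, design = NULL) {
  long <- tidyr::pivot_longer(scaled, -"gene_id",
                              names_to = "sample_id", values_to = "value")
  if (!is.null(design)) {
    long$sample_id <- factor(long$sample_id,
                             levels = design$sample_id[order(design$group)])
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\nexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
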