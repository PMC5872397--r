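#' Stacked bar chart of tier proportions
#'
#' @param props Output of [tier_proportions()].
#' @return A ggplot.
#' @export
plot_tier_proportions <- function(props) {
  ggplot2::ggplot(props, ggplot2::aes(x = .data$sample, y = .data$proportion,
                                      fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(low = "#4575b4", medium = "grey80",
                                          high = "#d73027")) +
    { if ("mark" %in% names(props)) ggplot2::facet_wrap(~mark) } +
    ggplot2::labs(x = NULL, y = "proportion of sites", fill = "tier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname classify_switch_pairs
#' @param object A `switch_quadrants` object.
#' @method autoplot switch_quadrants
#' @export
autoplot.switch_quadrants <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$dir_x, y = .data$dir_y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#d73027") +
    ggplot2::labs(
      x = paste0("Δ ", object$marks[1]),
      y = paste0("Δ ", object$marks[2]),
      title = "Mark-switching quadrants", fill = "sites"
    ) +
    ggplot2::theme_minimal()
}

#' Signed feature-enrichment bar chart
#'
#' Hyper events plot positive, hypo events negative, following the sign
#' convention of the enrichment summaries produced by
#' [feature_enrichment()].
#'
#' @param enr Output of [feature_enrichment()].
#' @return A ggplot.
#' @export
plot_feature_enrichment <- function(enr) {
  ggplot2::ggplot(dplyr::filter(enr, !is.na(.data$signed_enrichment)),
                  ggplot2::aes(x = .data$feature,
                               y = .data$signed_enrichment,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_fill_manual(values = c("+" = "#d73027", "-" = "#4575b4"),
                               labels = c("+" = "hyper", "-" = "hypo")) +
    ggplot2::labs(x = NULL, y = "enrichment (hyper +, hypo -)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of chromatin-state by switch-code enrichment
#'
#' @param coloc Output of [state_colocalization()].
#' @return A ggplot.
#' @export
plot_state_colocalization <- function(coloc) {
  ggplot2::ggplot(coloc, ggplot2::aes(x = .data$code, y = .data$state,
                                      fill = .data$enrichment)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white",
                                  high = "#d73027", midpoint = 1,
                                  na.value = "grey90") +
    ggplot2::labs(x = "switch code", y = "chromatin state",
                  fill = "enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Plot an epigenetic sample tree
#'
#' @param x An [build_epitree()] result.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.epitree <- function(x, ...) {
  ape::plot.phylo(x$phylo, ...)
  invisible(x)
}
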