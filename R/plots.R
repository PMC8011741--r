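# ggplot2 front-ends for the main result types.

#' Plot a metagene profile
#'
#' Line plot of the aggregated per-bin signal, with the body shaded and the
#' flank boundaries marked.
#'
#' @param object A `lnc_metaprofile` from [aggregate_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_metaprofile <- function(object, ...) {
  spec <- attr(object, "spec")
  b1 <- spec$flank_bins + 0.5
  b2 <- spec$flank_bins + spec$body_bins + 0.5
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_index, y = .data$value)) +
    ggplot2::annotate("rect", xmin = b1, xmax = b2, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_line(linewidth = 0.7, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(b1, b2), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "bin (5' flank | body | 3' flank)",
                  y = paste0("mean signal (", spec$kind, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of a stratification table
#'
#' Proportion of each class with (+) and without (-) each mark.
#'
#' @param strat Output of [stratify()].
#' @return A ggplot object.
#' @export
plot_stratification <- function(strat) {
  ggplot2::ggplot(strat,
                  ggplot2::aes(x = .data$class, y = .data$percent,
                               fill = .data$status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~mark) +
    ggplot2::labs(x = NULL, y = "% of class", fill = "overlap") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Box plot of homology coverage by class and genome
#'
#' @param calls Output of [chain_hsps()].
#' @param classes Class table (`query_id`/`id` + `class`).
#' @return A ggplot object.
#' @export
plot_coverage <- function(calls, classes) {
  if ("id" %in% names(classes)) {
    classes <- dplyr::transmute(classes, query_id = .data$id, class = .data$class)
  }
  d <- dplyr::inner_join(calls, classes, by = "query_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$coverage)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~genome) +
    ggplot2::labs(x = NULL, y = "query coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
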