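# ggplot2 views of the main result types.

#' Plot a binned count track
#'
#' @param object A `cyc_counts` track.
#' @param ... Unused.
#' @return A ggplot: per-bin counts along each chromosome.
#' @method autoplot cyc_counts
#' @export
autoplot.cyc_counts <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$count)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "midpoints per bin") +
    ggplot2::theme_minimal()
}

#' Plot per-bin enrichment calls
#'
#' @param object A `cyc_calls` object.
#' @param ... Unused.
#' @return A ggplot: p-value histogram with the significance threshold.
#' @method autoplot cyc_calls
#' @export
autoplot.cyc_calls <- function(object, ...) {
  alpha <- attr(object, "alpha", exact = TRUE)
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.02),
                            fill = "grey35") +
    ggplot2::geom_vline(xintercept = alpha, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "one-sided Fisher p", y = "bins") +
    ggplot2::theme_minimal()
}

#' Plot a dynamics partition along the genome
#'
#' @param object A `cyc_dynamics` partition.
#' @param ... Unused.
#' @return A ggplot: class-coloured segments per chromosome.
#' @method autoplot cyc_dynamics
#' @export
autoplot.cyc_dynamics <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1,
                                    fill = .data$class)) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(
      conserved = "grey40", g1s_specific = "#2166ac",
      mitotic_specific = "#b2182b", unoccupied = "grey90"
    )) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot an expression comparison
#'
#' @param object A `cyc_expr_test` from [compare_expression()].
#' @param ... Unused.
#' @return A ggplot: log2(FPKM + 1) boxplots per group.
#' @method autoplot cyc_expr_test
#' @export
autoplot.cyc_expr_test <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = as.character(.data$group),
                               y = log2(.data$fpkm + 1))) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::labs(x = "group", y = "log2(FPKM + 1)",
                  subtitle = sprintf("Welch t = %.2f, p = %.3g",
                                     object$statistic, object$p_value)) +
    ggplot2::theme_minimal()
}
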