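# broom-style tidiers for the package's result objects.

#' @describeIn call_enriched_bins `tidy()`: per-bin results as a plain
#'   tibble.
#' @param x A `cyc_calls` object.
#' @param ... Unused.
#' @method tidy cyc_calls
#' @export
tidy.cyc_calls <- function(x, ...) {
  as_tibble(x)
}

#' @describeIn call_enriched_bins `glance()`: one-row summary (bins
#'   tested, significant count and rate, alpha, totals, scale factor).
#' @method glance cyc_calls
#' @export
glance.cyc_calls <- function(x, ...) {
  testable <- x$chip_count > 0 | x$input_count > 0
  tibble(
    n_bins = nrow(x),
    n_testable = sum(testable),
    n_significant = sum(x$significant),
    significant_rate = mean(x$significant),
    alpha = attr(x, "alpha", exact = TRUE),
    adjust = attr(x, "adjust", exact = TRUE),
    chip_total = attr(x, "chip_total", exact = TRUE),
    chip_total_effective = attr(x, "chip_total_effective", exact = TRUE),
    input_total = attr(x, "input_total", exact = TRUE),
    scale_factor = attr(x, "scale_factor", exact = TRUE)
  )
}

#' @describeIn classify_dynamics `tidy()`: the class-labelled interval
#'   tibble.
#' @param x A `cyc_dynamics` object.
#' @param ... Unused.
#' @method tidy cyc_dynamics
#' @export
tidy.cyc_dynamics <- function(x, ...) {
  as_tibble(x)
}

#' @describeIn classify_dynamics `glance()`: one row per class with total
#'   bp and genome fraction.
#' @method glance cyc_dynamics
#' @export
glance.cyc_dynamics <- function(x, ...) {
  layout <- attr(x, "layout", exact = TRUE)
  bp <- vapply(dynamics_levels,
               function(cls) sum(x$end[x$class == cls] - x$start[x$class == cls]),
               numeric(1))
  out <- tibble(class = dynamics_levels, bp = bp)
  if (!is.null(layout)) out$genome_fraction <- bp / genome_size(layout)
  out
}

#' @describeIn compare_expression `tidy()`: per-group medians, sizes and
#'   FPKM > 1 fractions.
#' @param x A `cyc_expr_test` object.
#' @param ... Unused.
#' @method tidy cyc_expr_test
#' @export
tidy.cyc_expr_test <- function(x, ...) {
  x$groups
}

#' @describeIn compare_expression `glance()`: Welch t statistic,
#'   Welch-Satterthwaite df and two-sided p.
#' @method glance cyc_expr_test
#' @export
glance.cyc_expr_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    log_transform = x$log_transform
  )
}
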