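# Domain assembly and cross-phase occupancy dynamics.

new_domains <- function(x, layout = NULL, condition = NA_character_) {
  structure(
    as_tibble(x),
    layout = layout,
    condition = condition,
    class = c("cyc_domains", class(tibble()))
  )
}

#' Coerce an interval table to a domain set
#'
#' Sorts and merges abutting/overlapping intervals so that the number of
#' domains is well defined.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param layout Optional `cyc_layout` used to validate bounds.
#' @param condition Optional condition label (e.g. `"G1S"`, `"M"`).
#' @return A `cyc_domains` tibble (sorted, disjoint, merged).
#' @export
as_domains <- function(x, layout = NULL, condition = NA_character_) {
  if (!is.null(layout)) check_intervals(x, "x", layout = layout)
  new_domains(interval_merge(x), layout, condition)
}

check_domains <- function(x, name = "domains") {
  check_intervals(x, name)
  invisible(x)
}

#' Merge significant bins into domains
#'
#' Maximal runs of significant bins separated by at most `max_gap` bp of
#' non-significant sequence become single domains. The default `max_gap = 0`
#' reads "adjacent" literally: only bins sharing a boundary merge, and a
#' lone significant bin is a single-bin domain.
#'
#' @param bins A `cyc_calls` object from [call_enriched_bins()].
#' @param max_gap Maximum non-significant gap to bridge, in bp (default 0).
#' @param condition Optional condition label carried on the result.
#' @return A `cyc_domains` tibble of sorted disjoint intervals.
#' @export
merge_bins_to_domains <- function(bins, max_gap = 0, condition = NA_character_) {
  check_calls(bins)
  check_scalar_number(max_gap, "max_gap", min = 0)
  sig <- bins[bins$significant, c("chrom", "start", "end")]
  new_domains(interval_merge(sig, max_gap = max_gap),
              layout = calls_layout(bins), condition = condition)
}

#' Summarize a domain set
#'
#' @param domains A domain set (any interval data frame; merged first).
#' @param layout A `cyc_layout` supplying the genome length.
#' @return A one-row tibble: `n_domains`, `median_size` (bp; mean of the
#'   central two for even counts; 0 with `empty = TRUE` for an empty set),
#'   `genome_fraction` (total domain bp over genome bp) and `empty`.
#' @export
domain_stats <- function(domains, layout) {
  check_layout(layout)
  check_domains(domains)
  d <- interval_merge(domains)
  n <- nrow(d)
  if (n == 0) {
    return(tibble(n_domains = 0L, median_size = 0, genome_fraction = 0,
                  empty = TRUE))
  }
  len <- d$end - d$start
  tibble(
    n_domains = n,
    median_size = median(len),
    genome_fraction = sum(len) / genome_size(layout),
    empty = FALSE
  )
}

dynamics_levels <- c("conserved", "g1s_specific", "mitotic_specific", "unoccupied")

#' Classify cross-phase domain dynamics at base-pair resolution
#'
#' Conserved regions are loci occupied in both G1/S and mitosis; loci
#' occupied in only one phase are phase-specific (mitotic-specific =
#' deposition over mitosis, G1/S-specific = removal); everything else is
#' unoccupied. Classification is by interval algebra on base pairs, not by
#' whole-domain identity: partially overlapping domains contribute their
#' overlap to the conserved class and their remainders to the specific
#' classes. The four classes are mutually disjoint and tile the genome
#' exactly.
#'
#' @param g1s,m Domain sets for the G1/S and mitotic conditions.
#' @param layout A `cyc_layout`.
#' @return A `cyc_dynamics` tibble with columns `chrom`, `start`, `end`,
#'   `class` (factor: conserved, g1s_specific, mitotic_specific,
#'   unoccupied), sorted by position.
#' @export
classify_dynamics <- function(g1s, m, layout) {
  check_layout(layout)
  check_intervals(g1s, "g1s", layout = layout)
  check_intervals(m, "m", layout = layout)
  pieces <- list(
    conserved = interval_intersect(g1s, m),
    g1s_specific = interval_subtract(g1s, m),
    mitotic_specific = interval_subtract(m, g1s),
    unoccupied = interval_complement(interval_union(g1s, m), layout)
  )
  out <- dplyr::bind_rows(pieces, .id = "class")
  out$class <- factor(out$class, levels = dynamics_levels)
  out <- out[, c("chrom", "start", "end", "class")]
  out <- dplyr::arrange(
    out,
    factor(.data$chrom, levels = layout$chroms$chrom),
    .data$start
  )
  structure(out, layout = layout,
            class = c("cyc_dynamics", class(tibble())))
}

#' Extract one class from a dynamics partition
#'
#' @param dynamics A `cyc_dynamics` object from [classify_dynamics()].
#' @param class One of `"conserved"`, `"g1s_specific"`,
#'   `"mitotic_specific"`, `"unoccupied"`.
#' @return A `cyc_domains` tibble of that class's intervals.
#' @export
dynamics_class <- function(dynamics, class) {
  class <- match.arg(class, dynamics_levels)
  check_intervals(dynamics, "dynamics")
  keep <- dynamics$class == class
  new_domains(interval_merge(dynamics[keep, c("chrom", "start", "end")]),
              layout = attr(dynamics, "layout", exact = TRUE),
              condition = class)
}

#' Fraction of the genome (or union) shared by two domain sets
#'
#' @param a,b Domain sets on the same layout.
#' @param layout A `cyc_layout`.
#' @param basis `"genome"` (default): shared bp over genome bp, the natural
#'   reading of regions spanning a portion "of the genome"; `"union"`:
#'   Jaccard-style shared bp over the bp of the union.
#' @return A proportion in `[0, 1]`.
#' @export
shared_fraction <- function(a, b, layout, basis = c("genome", "union")) {
  basis <- match.arg(basis)
  check_layout(layout)
  check_intervals(a, "a", layout = layout)
  check_intervals(b, "b", layout = layout)
  shared <- interval_bp(interval_intersect(a, b))
  denom <- if (basis == "genome") {
    genome_size(layout)
  } else {
    interval_bp(interval_union(a, b))
  }
  if (denom == 0) return(0)
  shared / denom
}

#' Base-pair Jaccard index between two interval sets
#'
#' @param a,b Interval data frames.
#' @return `|a intersect b| / |a union b|` in bp; 1 when both sets are
#'   empty.
#' @export
bp_jaccard <- function(a, b) {
  union_bp <- interval_bp(interval_union(a, b))
  if (union_bp == 0) return(1)
  interval_bp(interval_intersect(a, b)) / union_bp
}
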