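# Half-open interval algebra on (chrom, start, end) tibbles.
#
# All coordinates are 0-based half-open (BED convention). Set operations are
# delegated to IRanges/GenomicRanges behind this tabular surface; conversion
# adds 1 to starts because IRanges are 1-based closed.

check_intervals <- function(x, name = "intervals", layout = NULL) {
  check_columns(x, c("chrom", "start", "end"), name)
  if (nrow(x) > 0) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
      stop_record(sprintf("`%s` has non-numeric coordinates", name))
    }
    if (any(x$start >= x$end)) {
      stop_record(sprintf("`%s` has records with start >= end", name))
    }
    if (any(x$start < 0)) {
      stop_record(sprintf("`%s` has records with negative start", name))
    }
    if (!is.null(layout)) {
      ci <- match(x$chrom, layout$chroms$chrom)
      if (anyNA(ci)) {
        stop_record(sprintf("`%s` uses chromosomes absent from the layout", name))
      }
      if (any(x$end > layout$chroms$length[ci])) {
        stop_record(sprintf("`%s` has records beyond chromosome ends", name))
      }
    }
  }
  invisible(x)
}

# seqinfo-bearing GRanges from a tibble; seqlevels come from the layout when
# given, otherwise from the data (sorted for determinism)
as_gr <- function(x, layout = NULL, extra_levels = NULL) {
  levels <- if (!is.null(layout)) {
    layout$chroms$chrom
  } else {
    sort(unique(c(as.character(x$chrom), extra_levels)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(x$chrom), levels = levels),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
  if (!is.null(layout)) {
    GenomeInfoDb::seqlengths(gr) <- setNames(
      layout$chroms$length, layout$chroms$chrom
    )
  }
  gr
}

gr_to_tbl <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

empty_intervals <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric())
}

#' Merge overlapping or nearby intervals
#'
#' Overlapping and abutting intervals are always merged; intervals separated
#' by at most `max_gap` bp are merged as well.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param max_gap Maximum gap in bp to bridge (default 0: only overlapping or
#'   abutting intervals merge).
#' @return A sorted, disjoint interval tibble.
#' @export
interval_merge <- function(x, max_gap = 0) {
  check_intervals(x)
  check_scalar_number(max_gap, "max_gap", min = 0)
  if (nrow(x) == 0) return(empty_intervals())
  gr <- GenomicRanges::reduce(as_gr(x), min.gapwidth = max_gap + 1)
  gr_to_tbl(gr)
}

#' Interval set operations
#'
#' Standard half-open interval algebra on `(chrom, start, end)` tibbles:
#' union, intersection, subtraction and complement within a genome. Outputs
#' are sorted, disjoint and merged.
#'
#' @param a,b Interval data frames with columns `chrom`, `start`, `end`.
#' @param layout A `cyc_layout` giving chromosome extents (required for
#'   `interval_complement()`).
#' @return A sorted, disjoint interval tibble.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' b <- tibble::tibble(chrom = "chr1", start = 5, end = 20)
#' interval_union(a, b)
#' interval_subtract(b, a)
#' @name interval-ops
NULL

#' @rdname interval-ops
#' @export
interval_union <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  interval_merge(dplyr::bind_rows(
    a[, c("chrom", "start", "end")],
    b[, c("chrom", "start", "end")]
  ))
}

#' @rdname interval-ops
#' @export
interval_intersect <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals())
  levels <- sort(unique(c(a$chrom, b$chrom)))
  gr <- GenomicRanges::intersect(
    as_gr(a, extra_levels = levels),
    as_gr(b, extra_levels = levels)
  )
  gr_to_tbl(gr)
}

#' @rdname interval-ops
#' @export
interval_subtract <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  if (nrow(a) == 0) return(empty_intervals())
  if (nrow(b) == 0) return(interval_merge(a))
  levels <- sort(unique(c(a$chrom, b$chrom)))
  gr <- GenomicRanges::setdiff(
    as_gr(a, extra_levels = levels),
    as_gr(b, extra_levels = levels)
  )
  gr_to_tbl(gr)
}

#' @rdname interval-ops
#' @export
interval_complement <- function(a, layout) {
  check_layout(layout)
  check_intervals(a, "a", layout = layout)
  genome <- tibble(
    chrom = layout$chroms$chrom,
    start = 0,
    end = layout$chroms$length
  )
  if (nrow(a) == 0) return(genome)
  gr <- GenomicRanges::setdiff(as_gr(genome, layout), as_gr(a, layout))
  gr_to_tbl(gr)
}

#' Total base pairs spanned by an interval set
#'
#' Intervals are merged before summing, so overlapping inputs are not
#' double-counted.
#'
#' @param x An interval data frame.
#' @return Total bp as a number.
#' @export
interval_bp <- function(x) {
  m <- interval_merge(x)
  sum(m$end - m$start)
}

# per-row fraction of each `query` interval covered by the union of
# `subject`; returns a numeric vector aligned with rows of `query`
covered_fraction <- function(query, subject) {
  check_intervals(query, "query")
  if (nrow(query) == 0) return(numeric())
  subject <- interval_merge(subject)
  levels <- sort(unique(c(query$chrom, subject$chrom)))
  gq <- as_gr(query, extra_levels = levels)
  if (nrow(subject) == 0) return(rep(0, nrow(query)))
  gs <- as_gr(subject, extra_levels = levels)
  hits <- GenomicRanges::findOverlaps(gq, gs)
  ov <- GenomicRanges::pintersect(
    gq[S4Vectors::queryHits(hits)],
    gs[S4Vectors::subjectHits(hits)]
  )
  covered <- rep(0, nrow(query))
  if (length(hits) > 0) {
    bp <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(bp))] <- as.numeric(bp)
  }
  covered / (query$end - query$start)
}
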