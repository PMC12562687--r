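# Fragment handling: midpoints, per-bin counting, binned-track correlation.

check_fragments <- function(x, name = "fragments") {
  check_columns(x, c("chrom", "start", "end"), name)
  if (nrow(x) > 0) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
      stop_record(sprintf("`%s` has non-numeric coordinates", name))
    }
    if (any(x$start < 0) || any(x$start >= x$end)) {
      stop_record(sprintf("`%s` has records with start < 0 or start >= end", name))
    }
  }
  invisible(x)
}

#' Fragment midpoints
#'
#' The midpoint of a half-open fragment `[start, end)` is
#' `start + floor((end - start) / 2)` — the lower-median base for even
#' lengths — independent of strand.
#'
#' @param fragments A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @return The input as a tibble with a `midpoint` column appended.
#' @examples
#' frags <- tibble::tibble(chrom = "chr1", start = 3, end = 100)
#' fragment_midpoint(frags)$midpoint # 51
#' @export
fragment_midpoint <- function(fragments) {
  check_fragments(fragments)
  out <- as_tibble(fragments)
  out$midpoint <- out$start + (out$end - out$start) %/% 2
  out
}

#' Count fragment midpoints per genomic bin
#'
#' Every fragment contributes its midpoint to exactly one bin of the layout's
#' grid. Fragments on chromosomes absent from the layout (or with midpoints
#' beyond the chromosome end) are dropped with a warning, or raise an error
#' in strict mode.
#'
#' @param fragments A data frame with columns `chrom`, `start`, `end`.
#' @param layout A `cyc_layout`.
#' @param extend Optional fixed fragment extension in bp applied to the 3'
#'   end before midpoint computation (default 0: fragments used as mapped).
#'   Requires a `strand` column when non-zero.
#' @param strict If `TRUE`, out-of-layout fragments are an error instead of a
#'   warning.
#' @return A `cyc_counts` tibble: the bin grid (`chrom`, `start`, `end`,
#'   `bin`) plus a `count` column; attributes `layout` and `total` carry the
#'   grid and the library total.
#' @export
count_midpoints <- function(fragments, layout, extend = 0, strict = FALSE) {
  check_fragments(fragments)
  check_layout(layout)
  check_scalar_number(extend, "extend", min = 0)
  check_flag(strict, "strict")

  start <- fragments$start
  end <- fragments$end
  if (extend > 0 && nrow(fragments) > 0) {
    check_columns(fragments, "strand", "fragments")
    minus <- fragments$strand == "-"
    end <- ifelse(minus, end, start + pmax(end - start, extend))
    start <- ifelse(minus, pmin(start, end - extend), start)
  }
  mid <- start + (end - start) %/% 2
  idx <- bin_index(layout, fragments$chrom, mid)
  n_bad <- sum(is.na(idx))
  if (n_bad > 0) {
    msg <- sprintf(
      "%d fragment(s) outside the layout (unknown chromosome or out of range)",
      n_bad
    )
    if (strict) stop_record(msg)
    warn(msg, class = "cyc_dropped_records")
    idx <- idx[!is.na(idx)]
  }
  counts <- tabulate(idx, nbins = n_bins(layout))

  out <- make_bins(layout)
  out$count <- as.numeric(counts)
  structure(
    out,
    layout = layout,
    total = sum(counts),
    class = c("cyc_counts", class(out))
  )
}

counts_layout <- function(x) attr(x, "layout", exact = TRUE)

counts_total <- function(x) attr(x, "total", exact = TRUE)

check_counts <- function(x, name = "counts") {
  if (!inherits(x, "cyc_counts") || is.null(counts_layout(x))) {
    stop_invalid(sprintf("`%s` must come from count_midpoints()", name))
  }
  invisible(x)
}

same_layout <- function(a, b) {
  isTRUE(all.equal(a$chroms[, c("chrom", "length")],
                   b$chroms[, c("chrom", "length")])) &&
    a$bin_size == b$bin_size
}

#' Pearson correlation between two binned tracks
#'
#' Computes the Pearson correlation over all bins of two count tracks on the
#' same layout. By default each track is first scaled to counts per million
#' of its library total; Pearson is invariant to this positive scaling, but
#' CPM values are also what the exported tracks contain. Bins that are zero
#' in both tracks are retained.
#'
#' @param a,b `cyc_counts` tracks on the same layout.
#' @param normalize Scale each track to counts per million before
#'   correlating (default `TRUE`).
#' @return Pearson r in `[-1, 1]`.
#' @export
bin_pearson <- function(a, b, normalize = TRUE) {
  check_counts(a, "a")
  check_counts(b, "b")
  check_flag(normalize, "normalize")
  if (!same_layout(counts_layout(a), counts_layout(b))) {
    stop_layout("`a` and `b` are binned on different layouts")
  }
  x <- a$count
  y <- b$count
  if (normalize) {
    if (counts_total(a) > 0) x <- x / counts_total(a) * 1e6
    if (counts_total(b) > 0) y <- y / counts_total(b) * 1e6
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("correlation undefined: a track has zero variance",
          class = "cyc_undefined_correlation")
  }
  cor(x, y)
}
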