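#' Define a genome layout with a fixed bin grid
#'
#' A genome layout holds the ordered chromosomes (name and length) together
#' with the fixed bin width used for all binned operations. Every chromosome
#' is tiled with half-open bins `[i*B, min((i+1)*B, L))`; the trailing bin may
#' be shorter than `bin_size` and is kept, so that genome-fraction
#' denominators always equal the full genome length.
#'
#' @param chroms A data frame with columns `chrom` and `length`, or a named
#'   numeric vector of chromosome lengths.
#' @param bin_size Bin width in base pairs (default 2000).
#'
#' @return An object of class `cyc_layout`: a list with `chroms` (tibble of
#'   `chrom`, `length`, `n_bins`, `offset`) and `bin_size`.
#' @examples
#' layout <- genome_layout(c(chr1 = 5000, chr2 = 2000), bin_size = 2000)
#' genome_size(layout)
#' make_bins(layout)
#' @export
genome_layout <- function(chroms, bin_size = 2000) {
  check_scalar_number(bin_size, "bin_size", min = 0, strict_min = TRUE)
  if (is.numeric(chroms) && !is.null(names(chroms))) {
    chroms <- tibble(chrom = names(chroms), length = unname(chroms))
  }
  check_columns(chroms, c("chrom", "length"), "chroms")
  chroms <- as_tibble(chroms)[, c("chrom", "length")]
  chroms$chrom <- as.character(chroms$chrom)
  if (anyDuplicated(chroms$chrom)) {
    stop_invalid("chromosome names must be unique")
  }
  if (any(!is.finite(chroms$length)) || any(chroms$length <= 0)) {
    stop_invalid("chromosome lengths must be positive")
  }
  chroms$length <- as.numeric(chroms$length)
  chroms$n_bins <- ceiling(chroms$length / bin_size)
  chroms$offset <- cumsum(c(0, head(chroms$n_bins, -1L)))
  structure(
    list(chroms = chroms, bin_size = bin_size),
    class = "cyc_layout"
  )
}

#' @export
print.cyc_layout <- function(x, ...) {
  cat(sprintf(
    "<cyc_layout> %d chromosome(s), %s bp, bin_size = %s (%d bins)\n",
    nrow(x$chroms), format(genome_size(x), big.mark = ","),
    format(x$bin_size, big.mark = ","), n_bins(x)
  ))
  print(x$chroms, ...)
  invisible(x)
}

is_layout <- function(x) inherits(x, "cyc_layout")

check_layout <- function(x, name = "layout") {
  if (!is_layout(x)) {
    stop_invalid(sprintf("`%s` must be a cyc_layout (see genome_layout())", name))
  }
  invisible(x)
}

#' Total genome size of a layout
#'
#' @param layout A `cyc_layout`.
#' @return Total genome length in base pairs.
#' @export
genome_size <- function(layout) {
  check_layout(layout)
  sum(layout$chroms$length)
}

#' Number of bins in a layout
#'
#' @param layout A `cyc_layout`.
#' @return Total number of bins across all chromosomes.
#' @export
n_bins <- function(layout) {
  check_layout(layout)
  sum(layout$chroms$n_bins)
}

#' Enumerate the bin grid of a layout
#'
#' Bins are half-open `[start, end)` intervals in chromosome order; the last
#' bin of each chromosome is truncated at the chromosome end.
#'
#' @param layout A `cyc_layout`.
#' @return A tibble with columns `chrom`, `start`, `end` and the global bin
#'   index `bin` (1-based, chromosome-order).
#' @export
make_bins <- function(layout) {
  check_layout(layout)
  B <- layout$bin_size
  out <- purrr::pmap_dfr(
    layout$chroms,
    function(chrom, length, n_bins, offset) {
      start <- (seq_len(n_bins) - 1) * B
      tibble(
        chrom = chrom,
        start = start,
        end = pmin(start + B, length),
        bin = offset + seq_len(n_bins)
      )
    }
  )
  out
}

# global bin index for (chrom, position); NA for unknown chromosome or
# out-of-range position
bin_index <- function(layout, chrom, pos) {
  ci <- match(chrom, layout$chroms$chrom)
  len <- layout$chroms$length[ci]
  idx <- layout$chroms$offset[ci] + floor(pos / layout$bin_size) + 1
  idx[is.na(ci) | pos < 0 | pos >= len] <- NA_real_
  idx
}
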