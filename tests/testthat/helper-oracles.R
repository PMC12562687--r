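# Shared fixtures and independent oracles used across the suite.

# build a cyc_counts track with prescribed per-bin counts by planting one
# 1-bp fragment per midpoint
make_counts <- function(layout, counts) {
  bins <- make_bins(layout)
  stopifnot(length(counts) == nrow(bins))
  idx <- rep.int(seq_len(nrow(bins)), counts)
  frags <- tibble::tibble(
    chrom = bins$chrom[idx],
    start = bins$start[idx] + (bins$end[idx] - bins$start[idx]) %/% 2,
    end = bins$start[idx] + (bins$end[idx] - bins$start[idx]) %/% 2 + 1
  )
  count_midpoints(frags, layout)
}

# exhaustive hypergeometric tail sum: P(X >= chip_k) for the 2x2 table
# with row totals (chip_n, input_n) and column total chip_k + input_k.
# Enumerates every admissible table; independent of stats::phyper.
hyper_tail_oracle <- function(chip_k, chip_n, input_k, input_n) {
  k <- chip_k + input_k
  hi <- pmin(k, chip_n)
  lens <- hi - chip_k + 1
  idx <- rep(seq_along(chip_k), lens)
  x <- sequence(lens, from = chip_k)
  logp <- lchoose(chip_n[idx], x) +
    lchoose(input_n[idx], k[idx] - x) -
    lchoose(chip_n[idx] + input_n[idx], k[idx])
  as.numeric(rowsum(exp(logp), idx))
}

# per-bp boolean masks for interval algebra on small genomes
interval_mask <- function(x, layout) {
  lapply(seq_len(nrow(layout$chroms)), function(ci) {
    chrom <- layout$chroms$chrom[ci]
    m <- rep(FALSE, layout$chroms$length[ci])
    rows <- x[x$chrom == chrom, , drop = FALSE]
    if (nrow(rows) > 0) {
      for (i in seq_len(nrow(rows))) {
        m[(rows$start[i] + 1):rows$end[i]] <- TRUE
      }
    }
    m
  })
}

mask_to_intervals <- function(masks, layout) {
  out <- lapply(seq_along(masks), function(ci) {
    r <- rle(masks[[ci]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    tibble::tibble(
      chrom = layout$chroms$chrom[ci],
      start = starts[r$values],
      end = ends[r$values]
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  res
}

expect_same_intervals <- function(got, want) {
  got <- dplyr::arrange(tibble::as_tibble(got)[, c("chrom", "start", "end")],
                        chrom, start)
  want <- dplyr::arrange(tibble::as_tibble(want)[, c("chrom", "start", "end")],
                         chrom, start)
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
}

# random possibly-overlapping interval sets for property tests
random_intervals <- function(layout, n, max_len = 5000) {
  ci <- sample.int(nrow(layout$chroms), n, replace = TRUE,
                   prob = layout$chroms$length)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (layout$chroms$length[ci] - len))
  tibble::tibble(
    chrom = layout$chroms$chrom[ci],
    start = start,
    end = start + len
  )
}
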