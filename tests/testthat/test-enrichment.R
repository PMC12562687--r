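test_that("one-sided Fisher p matches the hypergeometric tail", {
  # no outcome more extreme than observing zero
  expect_equal(fisher_bin_test(0, 10, 5, 10), 1.0)
  expect_equal(fisher_bin_test(0, 1000, 0, 1000), 1.0)

  # margins (10, 10), column total 3: only the all-chip table is as extreme
  expect_equal(fisher_bin_test(3, 10, 0, 10), 120 / 1140, tolerance = 1e-12)

  # enumeration oracle across a grid of small tables
  grid <- expand.grid(chip_n = c(5, 12, 30), input_n = c(7, 30),
                      chip_k = 0:5, input_k = 0:5)
  grid <- grid[grid$chip_k <= grid$chip_n & grid$input_k <= grid$input_n, ]
  got <- fisher_bin_test(grid$chip_k, grid$chip_n, grid$input_k, grid$input_n)
  want <- hyper_tail_oracle(grid$chip_k, grid$chip_n, grid$input_k,
                            grid$input_n)
  expect_equal(got, want, tolerance = 1e-12)

  # and against stats::fisher.test one-sided greater on a few tables
  for (tbl in list(c(8, 20, 3, 25), c(1, 10, 9, 10), c(15, 40, 15, 40))) {
    m <- matrix(c(tbl[1], tbl[2] - tbl[1], tbl[3], tbl[4] - tbl[3]),
                nrow = 2, byrow = TRUE)
    expect_equal(
      fisher_bin_test(tbl[1], tbl[2], tbl[3], tbl[4]),
      stats::fisher.test(m, alternative = "greater")$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("Fisher p is monotone decreasing in the ChIP count", {
  for (input_k in c(0, 5, 20)) {
    p <- fisher_bin_test(0:40, 40, input_k, 40)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("Fisher test rejects invalid tables", {
  expect_error(fisher_bin_test(5, 4, 0, 10), class = "cyc_invalid_parameter")
  expect_error(fisher_bin_test(-1, 4, 0, 10), class = "cyc_invalid_parameter")
  expect_error(fisher_bin_test(1, 4, 0, 0), class = "cyc_invalid_parameter")
})

test_that("Benjamini-Hochberg step-up adjustment", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(1.0), 1.0)
  set.seed(3)
  p <- runif(50)
  expect_true(all(benjamini_hochberg(p) >= p))
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "cyc_invalid_parameter")
})

test_that("identical chip and input tracks yield no significant bins", {
  layout <- genome_layout(c(chr1 = 20000), 2000)
  x <- make_counts(layout, c(5, 9, 14, 3, 7, 11, 2, 8, 6, 10))
  calls <- call_enriched_bins(x, x)
  expect_false(any(calls$significant))
  expect_true(all(calls$p >= 0.5))
})

test_that("a single bin holding the whole ChIP library is called", {
  layout <- genome_layout(c(chr1 = 20000), 2000)
  chip <- make_counts(layout, c(200, rep(0, 9)))
  input <- make_counts(layout, rep(20, 10))
  calls <- call_enriched_bins(chip, input, scale = "library")
  expect_true(calls$significant[1])
  expect_false(any(calls$significant[-1]))
  # oracle p for the hot bin at these margins
  expect_equal(calls$p[1], hyper_tail_oracle(200, 200, 20, 200),
               tolerance = 1e-12)
})

test_that("untestable bins get p = 1 and are excluded from the BH m", {
  layout <- genome_layout(c(chr1 = 12000), 2000)
  chip <- make_counts(layout, c(30, 0, 12, 0, 9, 4))
  input <- make_counts(layout, c(5, 0, 10, 0, 11, 8))
  calls <- call_enriched_bins(chip, input, adjust = "bh", scale = "library")
  testable <- calls$chip_count > 0 | calls$input_count > 0
  expect_equal(calls$p[!testable], rep(1, 2))
  expect_false(any(calls$significant[!testable]))
  expect_equal(calls$padj[testable],
               stats::p.adjust(calls$p[testable], "BH"))
})

test_that("mismatched layouts and empty libraries are rejected", {
  a <- make_counts(genome_layout(c(chr1 = 8000), 2000), c(1, 2, 3, 4))
  b <- make_counts(genome_layout(c(chr1 = 6000), 2000), c(1, 2, 3))
  expect_error(call_enriched_bins(a, b), class = "cyc_layout_mismatch")
  zero <- make_counts(genome_layout(c(chr1 = 8000), 2000), c(0, 0, 0, 0))
  expect_error(call_enriched_bins(a, zero), class = "cyc_invalid_parameter")
})

test_that("planted enrichment is recovered with calibrated background", {
  # 200 bins, 20% enriched at ratio 5, 30x depth
  set.seed(41)
  layout <- genome_layout(c(chr1 = 4e5), 2000)
  truth <- rep(c(TRUE, FALSE), c(40, 160))[sample.int(200)]
  chip <- make_counts(layout, rpois(200, ifelse(truth, 150, 30)))
  input <- make_counts(layout, rpois(200, 30))
  calls <- call_enriched_bins(chip, input)
  expect_gte(mean(calls$significant[truth]), 0.95)
  expect_lte(mean(calls$significant[!truth]), 2 * 0.05)
})

test_that("background scale estimation recovers the planted ratio", {
  set.seed(5)
  truth <- rep(c(TRUE, FALSE), c(300, 700))
  chip <- rpois(1000, ifelse(truth, 150, 30))
  input <- rpois(1000, 30)
  s <- estimate_background_scale(chip, input)
  # background chip/input count ratio is 1 by construction
  expect_equal(s, 1, tolerance = 0.1)
  # sparse-mark data: background dominates, scale ~ library ratio
  chip2 <- rpois(1000, 10)
  expect_equal(estimate_background_scale(chip2, input),
               sum(chip2) / sum(input), tolerance = 0.15)
})
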