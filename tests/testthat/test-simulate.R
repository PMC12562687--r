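# A small parameter set keeps unit tests fast; the full-scale defaults are
# exercised in test-acceptance.R.
small_params <- function(seed = 7, n_genes = 60, n_enhancers = 40, ...) {
  sim_params(n_chroms = 1, chrom_length = 1e6, n_genes = n_genes,
             n_enhancers = n_enhancers, seed = seed, ...)
}

test_that("the generators are pure functions of (params, seed)", {
  p <- small_params(seed = 99)
  t1 <- simulate_truth(p)
  t2 <- simulate_truth(p)
  expect_identical(t1$partition, t2$partition)

  f1 <- simulate_fragments(t1, "M", "chip")
  f2 <- simulate_fragments(t2, "M", "chip")
  expect_identical(f1, f2)
  # different samples draw from different streams
  expect_false(identical(f1, simulate_fragments(t1, "M", "input")))

  e1 <- simulate_enhancers(t1)
  e2 <- simulate_enhancers(t2)
  expect_identical(e1, e2)

  g1 <- simulate_genes_expression(t1)
  g2 <- simulate_genes_expression(t2)
  expect_identical(g1, g2)
})

test_that("planted class fractions land near their targets", {
  p <- sim_params(seed = 13) # 2 x 5 Mb, fractions .50/.10/.15
  part <- simulate_truth(p)$partition
  g <- glance(part)
  targets <- c(conserved = 0.50, g1s_specific = 0.10,
               mitotic_specific = 0.15)
  for (cls in names(targets)) {
    got <- g$genome_fraction[g$class == cls]
    expect_lt(abs(got - targets[[cls]]) / targets[[cls]], 0.02)
  }
  # partition tiles the genome exactly and classes are disjoint
  expect_identical(sum(g$bp), genome_size(simulate_truth(p)$layout))
  expect_identical(sum(part$end - part$start), genome_size(simulate_truth(p)$layout))
})

test_that("zero fractions produce an empty truth", {
  p <- small_params(fractions = c(conserved = 0, g1s_specific = 0,
                                  mitotic_specific = 0))
  part <- simulate_truth(p)$partition
  expect_true(all(part$class == "unoccupied"))
  expect_error(
    sim_params(fractions = c(conserved = 0.6, g1s_specific = 0.3,
                             mitotic_specific = 0.3)),
    class = "cyc_invalid_parameter"
  )
})

test_that("planted domain lengths track the configured median", {
  p <- sim_params(n_chroms = 1, chrom_length = 5e6, domain_median = 6000,
                  fractions = c(conserved = 0.2, g1s_specific = 0.05,
                                mitotic_specific = 0.05), seed = 3)
  part <- simulate_truth(p)$partition
  planted <- part[part$class != "unoccupied", ]
  med <- median(planted$end - planted$start)
  expect_lte(abs(med - 6000), p$bin_size) # within one bin of the target
})

test_that("ChIP rates are elevated by the enrichment ratio, input is flat", {
  p <- sim_params(n_chroms = 1, chrom_length = 2e6, seed = 19) # 1000 bins
  truth <- simulate_truth(p)
  layout <- truth$layout
  occ <- cycledomains:::phase_occupied(truth, "M")
  bins <- make_bins(layout)
  inside <- cycledomains:::covered_fraction(bins, occ) == 1
  outside <- cycledomains:::covered_fraction(bins, occ) == 0

  chip <- count_midpoints(simulate_fragments(truth, "M", "chip"), layout)
  input <- count_midpoints(simulate_fragments(truth, "M", "input"), layout)

  # Poisson 3-sigma bands around depth and ratio * depth
  band <- function(mu, n) 3 * sqrt(mu / n)
  expect_lt(abs(mean(chip$count[inside]) - 150), band(150, sum(inside)))
  expect_lt(abs(mean(chip$count[outside]) - 30), band(30, sum(outside)))
  expect_lt(abs(mean(input$count) - 30), band(30, nrow(bins)))

  # ratio 1 collapses chip to the input model
  p1 <- sim_params(n_chroms = 1, chrom_length = 2e6, enrichment_ratio = 1,
                   seed = 19)
  t1 <- simulate_truth(p1)
  chip1 <- count_midpoints(simulate_fragments(t1, "M", "chip"), layout)
  expect_lt(abs(mean(chip1$count) - 30), band(30, nrow(bins)))
})

test_that("covered genes sit inside mitotic-specific truth and express high", {
  p <- small_params(seed = 23)
  truth <- simulate_truth(p)
  ge <- simulate_genes_expression(truth)
  m_spec <- dynamics_class(truth$partition, "mitotic_specific")
  cov <- gene_coverage(ge$genes, m_spec)
  expect_true(all(cov$coverage[cov$covered] == 1))
  expect_true(all(cov$coverage[!cov$covered] == 0))
  expect_false(any(duplicated(ge$genes$gene_id)))

  med <- tapply(ge$expression$fpkm_sim, ge$genes$covered, median)
  expect_gt(med[["TRUE"]], med[["FALSE"]])

  none <- simulate_genes_expression(truth, small_params(n_genes = 0))
  expect_equal(nrow(none$genes), 0)
  expect_equal(nrow(none$expression), 0)
})

test_that("counts back-computed from FPKM round-trip through compute_fpkm", {
  p <- small_params(seed = 29)
  truth <- simulate_truth(p)
  ge <- simulate_genes_expression(truth)
  rec <- compute_fpkm(ge$expression[, c("gene_id", "count")], ge$genes,
                      library_size = ge$library_size)
  # counts are rounded: recovered FPKM differs by at most half a count unit
  unit <- 0.5 / ((rec$length / 1e3) * (ge$library_size / 1e6))
  expect_true(all(abs(rec$fpkm - ge$expression$fpkm_sim) <= unit + 1e-9))
})

test_that("enhancer labels are consistent with the planted landscape", {
  p <- small_params(seed = 31)
  truth <- simulate_truth(p)
  ea <- simulate_enhancers(truth)
  m_spec <- dynamics_class(truth$partition, "mitotic_specific")
  frac <- cycledomains:::covered_fraction(
    ea$enhancers[, c("chrom", "start", "end")], m_spec
  )
  expect_true(all(frac[ea$enhancers$covered] == 1))
  expect_true(all(frac[!ea$enhancers$covered] == 0))

  res <- associate_enhancers(ea$enhancers[, c("chrom", "start", "end")],
                             ea$accessibility, m_spec)
  # every enhancer labelled (covered, accessible) is recovered, and no
  # uncovered enhancer is
  expect_true(all(res$associated[ea$enhancers$covered & ea$enhancers$accessible]))
  expect_false(any(res$associated[!ea$enhancers$covered]))

  shut <- simulate_enhancers(truth, small_params(accessible_fraction = 0,
                                                 seed = 31))
  res0 <- associate_enhancers(shut$enhancers[, c("chrom", "start", "end")],
                              shut$accessibility, m_spec)
  expect_false(any(res0$associated))
})
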