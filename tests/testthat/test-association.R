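gene_tbl <- function(...) {
  x <- tibble::tribble(...)
  if (!"strand" %in% names(x)) x$strand <- "+"
  if (!"biotype" %in% names(x)) x$biotype <- "protein_coding"
  x
}

test_that("gene-body coverage by a domain set", {
  genes <- gene_tbl(
    ~gene_id, ~chrom, ~start, ~end,
    "g1", "c", 1000, 6000,
    "g2", "c", 500, 900,
    "g3", "c", 0, 5000
  )
  domains <- tibble::tibble(chrom = "c", start = c(0, 3000),
                            end = c(4000, 4000))
  cov <- gene_coverage(genes, domains)
  expect_equal(cov$coverage, c(3000 / 5000, 1.0, 4000 / 5000))

  two <- tibble::tibble(chrom = "c", start = c(1000, 3000),
                        end = c(2000, 4000))
  expect_equal(gene_coverage(genes[3, ], two)$coverage, 0.4)
})

test_that("coverage grows monotonically as the domain set grows", {
  set.seed(31)
  layout <- genome_layout(c(c = 50000), 2000)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:10), chrom = "c",
    start = seq(0, 45000, by = 5000), end = seq(3000, 48000, by = 5000)
  )
  d1 <- as_domains(random_intervals(layout, 5, max_len = 4000))
  d2 <- interval_union(d1, random_intervals(layout, 5, max_len = 4000))
  expect_true(all(gene_coverage(genes, d2)$coverage >=
                    gene_coverage(genes, d1)$coverage))
})

test_that("deposition-associated genes use a strict coverage threshold", {
  genes <- gene_tbl(
    ~gene_id, ~chrom, ~start, ~end,
    "hit", "c", 0, 10000,     # covered 8100/10000 = 0.81
    "edge", "c", 20000, 30000, # covered exactly 0.80
    "nc", "c", 40000, 50000
  )
  genes$biotype <- c("protein_coding", "protein_coding", "lncRNA")
  domains <- tibble::tibble(chrom = "c", start = c(0, 20000),
                            end = c(8100, 28000))
  res <- deposition_associated_genes(genes, domains)
  expect_equal(res$gene_id, c("hit", "edge")) # lncRNA filtered out
  expect_equal(res$associated, c(TRUE, FALSE))

  none <- deposition_associated_genes(genes, domains[0, ])
  expect_false(any(none$associated))
})

test_that("genic/intergenic partition on both bases", {
  genes <- gene_tbl(
    ~gene_id, ~chrom, ~start, ~end,
    "g1", "c", 0, 10000
  )
  d <- tibble::tibble(chrom = "c", start = c(5000, 20000, 40000),
                      end = c(12000, 24000, 42000))
  res <- partition_domains_genic(d, genes)
  expect_equal(res$genic, 1 / 3)
  expect_equal(res$genic + res$intergenic, 1)

  inside <- tibble::tibble(chrom = "c", start = c(1000, 4000),
                           end = c(2000, 6000))
  expect_equal(partition_domains_genic(inside, genes)$genic, 1)
  expect_equal(partition_domains_genic(inside, genes, basis = "bp")$genic, 1)

  empty <- partition_domains_genic(d[0, ], genes)
  expect_true(empty$empty)
  expect_equal(empty$genic + empty$intergenic, 0)

  # bp basis against the mask oracle on a random instance
  layout <- genome_layout(c(c = 50000), 2000)
  set.seed(37)
  d2 <- as_domains(random_intervals(layout, 10, max_len = 4000))
  g2 <- tibble::tibble(gene_id = paste0("g", 1:6), chrom = "c",
                       start = seq(0, 40000, by = 8000),
                       end = seq(3000, 43000, by = 8000))
  md <- interval_mask(d2, layout)[[1]]
  mg <- interval_mask(g2, layout)[[1]]
  expect_equal(partition_domains_genic(d2, g2, basis = "bp")$genic,
               sum(md & mg) / sum(md))
  # domain basis: overlap flags from the mask
  genic_flags <- vapply(seq_len(nrow(d2)), function(i) {
    any(mg[(d2$start[i] + 1):d2$end[i]])
  }, logical(1))
  expect_equal(partition_domains_genic(d2, g2)$genic, mean(genic_flags))
})

test_that("FPKM formula, scale invariance and edge cases", {
  genes <- gene_tbl(~gene_id, ~chrom, ~start, ~end, "g1", "c", 0, 2000)
  counts <- tibble::tibble(gene_id = "g1", count = 100)
  expect_equal(compute_fpkm(counts, genes, library_size = 1e6)$fpkm, 50)

  genes2 <- gene_tbl(
    ~gene_id, ~chrom, ~start, ~end,
    "a", "c", 0, 1500,
    "b", "c", 3000, 7000
  )
  counts2 <- tibble::tibble(gene_id = c("a", "b"), count = c(30, 120))
  f1 <- compute_fpkm(counts2, genes2)
  counts2x <- dplyr::mutate(counts2, count = count * 2)
  expect_equal(compute_fpkm(counts2x, genes2)$fpkm, f1$fpkm)

  expect_equal(
    compute_fpkm(tibble::tibble(gene_id = "a", count = 0), genes2,
                 library_size = 1e6)$fpkm, 0
  )
  expect_error(
    compute_fpkm(tibble::tibble(gene_id = "zz", count = 5), genes2),
    class = "cyc_invalid_record"
  )
})

test_that("Welch comparison matches the textbook formula", {
  # 4-vs-5 case, hand-computed:
  # a = {1,2,3,4}: mean 2.5, var 5/3; b = {2,4,6,8,10}: mean 6, var 10
  # t = -3.5 / sqrt(5/12 + 2) = -2.2514111
  # df = (5/12 + 2)^2 / ((5/12)^2/3 + 4/4) = 5.5207852
  df_in <- tibble::tibble(
    fpkm = c(1, 2, 3, 4, 2, 4, 6, 8, 10),
    group = rep(c(FALSE, TRUE), c(4, 5))
  )
  res <- compare_expression(df_in, fpkm, group, log_transform = FALSE)
  expect_equal(res$statistic, -2.2514363, tolerance = 1e-6)
  expect_equal(res$df, 5.5207877, tolerance = 1e-6)
  tt <- stats::t.test(fpkm ~ group, data = df_in)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$df, unname(tt$parameter))
  expect_equal(res$p_value, tt$p.value)

  g <- glance(res)
  expect_equal(g$statistic, res$statistic)
})

test_that("Welch comparison reports medians and FPKM > 1 fractions", {
  same <- tibble::tibble(fpkm = rep(c(1, 2, 3), 2),
                         group = rep(c(FALSE, TRUE), each = 3))
  res <- compare_expression(same, fpkm, group)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$groups$median_fpkm, c(2, 2))

  shifted <- tibble::tibble(fpkm = c(1, 2, 3, 11, 12, 13),
                            group = rep(c(FALSE, TRUE), each = 3))
  res2 <- compare_expression(shifted, fpkm, group)
  expect_equal(diff(res2$groups$median_fpkm), 10)
  expect_equal(res2$groups$fraction_fpkm_gt1, c(2 / 3, 1))

  flat <- tibble::tibble(fpkm = rep(5, 6),
                         group = rep(c(FALSE, TRUE), each = 3))
  res3 <- compare_expression(flat, fpkm, group)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)

  expect_error(compare_expression(same[1:3, ], fpkm, group),
               class = "cyc_invalid_parameter")
})

test_that("DEG filtering is strict on both thresholds", {
  degs <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(2.5, 2.0, 3.0, -2.5, -3.0),
    padj = c(0.005, 0.005, 0.01, 0.005, 0.0001)
  )
  res <- filter_degs(degs)
  expect_equal(res$gene_id, c("a", "d", "e"))
  expect_equal(res$direction, c("up", "down", "down"))
  expect_equal(nrow(filter_degs(degs[0, ])), 0)
})

test_that("DEG overlap report", {
  r <- deg_overlap(c("a", "b"), c("b", "c", "d"), c("a", "b", "c", "d", "e"))
  expect_equal(r$n_overlap, 1)
  expect_equal(r$fraction_of_associated, 1 / 3)
  expect_equal(deg_overlap(c("x"), c("y"), c("x", "y"))$n_overlap, 0)
  expect_equal(deg_overlap(c("a", "b"), c("a"), c("a"))$fraction_of_associated, 1)
  expect_true(deg_overlap(c("a"), character(), c("a"))$empty)
})

test_that("enhancer association needs accessibility and domain coverage", {
  enh <- tibble::tibble(chrom = "c",
                        start = c(1000, 5000, 9000),
                        end = c(1600, 5600, 9600))
  acc <- tibble::tibble(chrom = "c", start = c(900, 5100),
                        end = c(1700, 5300))
  m_spec <- tibble::tibble(chrom = "c", start = c(0, 8000),
                           end = c(2000, 10000))
  res <- associate_enhancers(enh, acc, m_spec)
  # 1: accessible + fully covered -> kept
  # 2: accessible, no domain overlap -> dropped
  # 3: fully covered but inaccessible -> dropped
  expect_equal(res$associated, c(TRUE, FALSE, FALSE))

  half <- tibble::tibble(chrom = "c", start = 1300, end = 2000)
  res2 <- associate_enhancers(enh, acc, half)
  expect_equal(res2$coverage[1], 0.5)
  expect_true(res2$associated[1])  # >= 50% rule
  res3 <- associate_enhancers(enh, acc, half, rule = "full")
  expect_false(res3$associated[1])
  res4 <- associate_enhancers(enh, acc, tibble::tibble(
    chrom = "c", start = 1599, end = 1600
  ), rule = "any")
  expect_true(res4$associated[1])
})

test_that("enhancer-gene links use a closed +/- window on the midpoint", {
  genes <- gene_tbl(~gene_id, ~chrom, ~start, ~end,
                    "g", "c", 200000, 205000)
  enh <- tibble::tibble(
    chrom = "c",
    start = c(89999, 49999, 74999),
    end = c(90001, 50001, 75001)
  )
  # midpoints 90000 (110 kb away), 50000 (150 kb), 75000 (exactly 125 kb)
  links <- link_enhancers_to_genes(enh, genes)
  expect_equal(sort(links$midpoint), c(75000, 90000))
  expect_equal(attr(links, "fraction_genes_linked"), 1)

  far <- link_enhancers_to_genes(enh[2, ], genes)
  expect_equal(nrow(far), 0)
  expect_equal(attr(far, "fraction_genes_linked"), 0)
})

test_that("ortholog-set intersection through a homology map", {
  map <- tibble::tibble(id_a = c("g1", "g3"), id_b = c("h1", "h3"))
  res <- intersect_ortholog_sets(c("g1", "g2"), c("h1"), map)
  expect_equal(as.data.frame(res$shared),
               data.frame(id_a = "g1", id_b = "h1"))
  expect_equal(res$a_unique, "g2")
  expect_equal(res$b_unique, character())

  empty_map <- map[0, ]
  expect_equal(nrow(intersect_ortholog_sets("g1", "h1", empty_map)$shared), 0)

  ident <- tibble::tibble(id_a = c("x", "y"), id_b = c("x", "y"))
  all_shared <- intersect_ortholog_sets(c("x", "y"), c("x", "y"), ident)
  expect_equal(nrow(all_shared$shared), 2)
  expect_equal(all_shared$a_unique, character())

  dup <- tibble::tibble(id_a = c("g1", "g1"), id_b = c("h1", "h2"))
  expect_error(intersect_ortholog_sets("g1", "h1", dup),
               class = "cyc_format_error")
})
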