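# Gene, expression, DEG, enhancer and ortholog association with
# phase-specific domains.

check_genes <- function(x, name = "genes") {
  check_columns(x, c("gene_id", "chrom", "start", "end"), name)
  check_intervals(x, name)
  if (anyDuplicated(x$gene_id)) {
    stop_record(sprintf("`%s` has duplicated gene_id values", name))
  }
  invisible(x)
}

# strand-aware TSS (0-based coordinate of the first transcribed base)
add_tss <- function(genes) {
  if (!"tss" %in% names(genes)) {
    strand <- if ("strand" %in% names(genes)) genes$strand else "+"
    genes$tss <- ifelse(strand == "-", genes$end - 1, genes$start)
  }
  genes
}

#' Fraction of each gene body covered by a domain set
#'
#' @param genes A gene table (columns `gene_id`, `chrom`, `start`, `end`;
#'   gene body = TSS-to-TES span).
#' @param domains A domain set (interval data frame).
#' @return The gene table as a tibble with a `coverage` column: bp of the
#'   gene body covered by the union of `domains`, divided by body length.
#' @export
gene_coverage <- function(genes, domains) {
  check_genes(genes)
  check_domains(domains)
  out <- as_tibble(genes)
  out$coverage <- covered_fraction(out, domains)
  out
}

#' Identify deposition-associated genes
#'
#' Protein-coding genes whose body is covered by mitotic-specific domains
#' beyond a threshold fraction are deposition-associated: loci that acquire
#' the histone variant specifically over mitosis. The threshold is a strict
#' inequality (coverage of exactly `threshold` is excluded), matching the
#' ">80%" convention.
#'
#' @param genes A gene table; rows are filtered to `biotype == "protein_coding"`
#'   before scoring when a `biotype` column is present.
#' @param mitotic_specific Mitotic-specific domain set.
#' @param threshold Coverage threshold in `(0, 1]` (default 0.8).
#' @return A tibble of the scored (protein-coding) genes with `coverage` and
#'   logical `associated` columns.
#' @export
deposition_associated_genes <- function(genes, mitotic_specific,
                                        threshold = 0.8) {
  check_scalar_number(threshold, "threshold", min = 0, max = 1,
                      strict_min = TRUE)
  check_genes(genes)
  if ("biotype" %in% names(genes)) {
    genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  }
  out <- gene_coverage(genes, mitotic_specific)
  out$associated <- out$coverage > threshold
  out
}

#' Genic vs intergenic partition of a domain set
#'
#' @param domains A domain set.
#' @param genes A gene table supplying gene bodies.
#' @param basis `"domain"` (default): a domain is genic if it overlaps at
#'   least 1 bp of any gene body, proportions over the number of domains;
#'   `"bp"`: proportions of domain base pairs inside vs outside the
#'   gene-body union.
#' @return A one-row tibble: `genic`, `intergenic` (proportions summing to
#'   1), `n_domains`, `basis`, `empty`.
#' @export
partition_domains_genic <- function(domains, genes,
                                    basis = c("domain", "bp")) {
  basis <- match.arg(basis)
  check_genes(genes)
  d <- interval_merge(domains)
  if (nrow(d) == 0) {
    return(tibble(genic = 0, intergenic = 0, n_domains = 0L,
                  basis = basis, empty = TRUE))
  }
  bodies <- genes[, c("chrom", "start", "end")]
  if (basis == "domain") {
    frac <- covered_fraction(d, bodies)
    genic <- mean(frac > 0)
  } else {
    total <- sum(d$end - d$start)
    genic <- sum(covered_fraction(d, bodies) * (d$end - d$start)) / total
  }
  tibble(genic = genic, intergenic = 1 - genic, n_domains = nrow(d),
         basis = basis, empty = FALSE)
}

#' Compute FPKM from gene-level counts
#'
#' FPKM = count / ((body length / 1e3) * (library total / 1e6)). The
#' library total defaults to the sum of the supplied counts; pass
#' `library_size` when the counted library includes fragments outside the
#' supplied genes (the usual case for genome-wide totals).
#'
#' @param counts A data frame with columns `gene_id` and `count`.
#' @param genes A gene table supplying gene-body lengths.
#' @param library_size Total mapped fragments (default `sum(counts$count)`).
#' @return A tibble with `gene_id`, `count`, `length` and `fpkm`.
#' @export
compute_fpkm <- function(counts, genes, library_size = NULL) {
  check_columns(counts, c("gene_id", "count"), "counts")
  check_genes(genes)
  if (any(counts$count < 0)) stop_invalid("counts must be non-negative")
  lengths <- setNames(genes$end - genes$start, genes$gene_id)
  len <- unname(lengths[counts$gene_id])
  if (anyNA(len)) stop_record("counts contain gene_id values absent from `genes`")
  if (any(len <= 0)) stop_record("zero-length gene body")
  if (is.null(library_size)) library_size <- sum(counts$count)
  check_scalar_number(library_size, "library_size", min = 0, strict_min = TRUE)
  tibble(
    gene_id = counts$gene_id,
    count = counts$count,
    length = as.numeric(len),
    fpkm = counts$count / ((len / 1e3) * (library_size / 1e6))
  )
}

#' Compare expression between two gene groups
#'
#' Summarizes FPKM per group (median, fraction above 1) and tests the
#' group difference with Welch's unequal-variance two-sample t-test, by
#' default on `log2(FPKM + 1)` values since FPKM is heavily right-skewed.
#'
#' @param data A data frame with one row per gene.
#' @param fpkm,group Columns (tidy-eval) holding FPKM values and a
#'   two-level group label (logical or factor-like; the *second* sorted
#'   level / `TRUE` is reported as group B).
#' @param log_transform Test `log2(FPKM + 1)` instead of raw FPKM
#'   (default `TRUE`).
#' @return A `cyc_expr_test` object; see [tidy()] and [glance()] methods.
#'   Degenerate input (zero variance in both groups with equal means)
#'   yields `t = 0`, `p = 1`.
#' @export
compare_expression <- function(data, fpkm, group, log_transform = TRUE) {
  check_flag(log_transform, "log_transform")
  fpkm <- dplyr::pull(data, {{ fpkm }})
  group <- dplyr::pull(data, {{ group }})
  if (length(unique(group[!is.na(group)])) != 2) {
    stop_invalid("`group` must have exactly two levels")
  }
  keep <- !is.na(fpkm) & !is.na(group)
  fpkm <- fpkm[keep]
  group <- group[keep]
  levels <- sort(unique(group))
  a <- fpkm[group == levels[1]]
  b <- fpkm[group == levels[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop_invalid("each group needs at least 2 values")
  }
  xa <- if (log_transform) log2(a + 1) else a
  xb <- if (log_transform) log2(b + 1) else b
  va <- var(xa); vb <- var(xb)
  na <- length(xa); nb <- length(xb)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t_stat <- 0
    df <- na + nb - 2
    p <- 1
  } else {
    t_stat <- (mean(xa) - mean(xb)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(
    list(
      groups = tibble(
        group = as.character(levels),
        n = c(na, nb),
        median_fpkm = c(median(a), median(b)),
        fraction_fpkm_gt1 = c(mean(a > 1), mean(b > 1))
      ),
      statistic = t_stat,
      df = df,
      p_value = p,
      log_transform = log_transform,
      data = tibble(fpkm = fpkm, group = group)
    ),
    class = "cyc_expr_test"
  )
}

#' @export
print.cyc_expr_test <- function(x, ...) {
  cat("<cyc_expr_test> Welch two-sample t-test",
      if (x$log_transform) "on log2(FPKM + 1)" else "on raw FPKM", "\n")
  print(x$groups, ...)
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Filter a differential-expression table to significant genes
#'
#' Keeps genes with adjusted p strictly below `padj_max` and absolute log2
#' fold change strictly above `lfc_min` (both strict, as conventionally
#' printed: Padj < 0.01, |log2FC| > 2).
#'
#' @param degs A data frame with columns `gene_id`, `log2fc`, `padj`.
#' @param padj_max Adjusted-p threshold (default 0.01).
#' @param lfc_min Absolute log2 fold-change threshold (default 2).
#' @return The significant rows with a `direction` column (`"up"` /
#'   `"down"` by the sign of `log2fc`).
#' @export
filter_degs <- function(degs, padj_max = 0.01, lfc_min = 2) {
  check_columns(degs, c("gene_id", "log2fc", "padj"), "degs")
  check_scalar_number(padj_max, "padj_max", min = 0, strict_min = TRUE)
  check_scalar_number(lfc_min, "lfc_min", min = 0, strict_min = TRUE)
  out <- as_tibble(degs)
  out <- out[!is.na(out$padj) & !is.na(out$log2fc) &
               out$padj < padj_max & abs(out$log2fc) > lfc_min, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out
}

#' Overlap of differentially expressed genes with an associated gene set
#'
#' @param deg_ids Character vector of significant DEG ids.
#' @param associated_ids Character vector of deposition-associated gene ids.
#' @param expressed_ids Character vector of all expressed gene ids (the DEG
#'   universe).
#' @return A one-row tibble: `n_deg`, `n_associated`, `n_overlap`,
#'   `fraction_of_associated` (overlap / associated; 0 with `empty = TRUE`
#'   when no associated genes), `fraction_deg_of_expressed`.
#' @export
deg_overlap <- function(deg_ids, associated_ids, expressed_ids) {
  deg_ids <- unique(as.character(deg_ids))
  associated_ids <- unique(as.character(associated_ids))
  expressed_ids <- unique(as.character(expressed_ids))
  n_overlap <- length(intersect(deg_ids, associated_ids))
  tibble(
    n_deg = length(deg_ids),
    n_associated = length(associated_ids),
    n_overlap = n_overlap,
    fraction_of_associated = if (length(associated_ids) == 0) 0 else
      n_overlap / length(associated_ids),
    fraction_deg_of_expressed = if (length(expressed_ids) == 0) 0 else
      length(intersect(deg_ids, expressed_ids)) / length(expressed_ids),
    empty = length(associated_ids) == 0
  )
}

#' Select deposition-associated enhancers
#'
#' Keeps enhancers that are chromatin-accessible (at least 1 bp overlap
#' with the accessibility intervals) and covered by mitotic-specific
#' domains. "Covered" defaults to at least half the enhancer's base pairs
#' (`rule = "fraction"`, `cover_min = 0.5`); `rule = "any"` accepts any
#' overlap and `rule = "full"` requires complete coverage.
#'
#' @param enhancers An interval data frame of enhancer elements.
#' @param accessibility An interval data frame of accessible chromatin
#'   (e.g. ATAC-seq peaks).
#' @param mitotic_specific Mitotic-specific domain set.
#' @param cover_min Minimum covered fraction under `rule = "fraction"`
#'   (default 0.5).
#' @param rule Coverage rule: `"fraction"` (default), `"any"`, `"full"`.
#' @return The enhancer tibble with `accessible`, `coverage` and logical
#'   `associated` columns.
#' @export
associate_enhancers <- function(enhancers, accessibility, mitotic_specific,
                                cover_min = 0.5,
                                rule = c("fraction", "any", "full")) {
  rule <- match.arg(rule)
  check_scalar_number(cover_min, "cover_min", min = 0, max = 1,
                      strict_min = TRUE)
  check_intervals(enhancers, "enhancers")
  check_intervals(accessibility, "accessibility")
  check_domains(mitotic_specific, "mitotic_specific")
  out <- as_tibble(enhancers)
  out$accessible <- covered_fraction(out, accessibility) > 0
  out$coverage <- covered_fraction(out, mitotic_specific)
  covered <- switch(rule,
    fraction = out$coverage >= cover_min,
    any = out$coverage > 0,
    full = out$coverage >= 1
  )
  out$associated <- out$accessible & covered
  out
}

#' Link enhancers to genes through a TSS window
#'
#' An enhancer is linked to a gene when the enhancer midpoint lies within
#' the closed window `[TSS - window, TSS + window]`; midpoints avoid
#' double-counting long enhancers straddling the boundary. Links are
#' many-to-many.
#'
#' @param enhancers An interval data frame of (associated) enhancers.
#' @param genes A gene table; a strand-aware `tss` column is derived when
#'   absent.
#' @param window Half-width of the regulatory window in bp (default
#'   125000).
#' @return A tibble of links (`gene_id`, `tss`, enhancer `chrom`, `start`,
#'   `end`, `midpoint`, `distance`), with attribute
#'   `fraction_genes_linked`: the fraction of supplied genes with at least
#'   one linked enhancer.
#' @export
link_enhancers_to_genes <- function(enhancers, genes, window = 125000) {
  check_scalar_number(window, "window", min = 0, strict_min = TRUE)
  check_intervals(enhancers, "enhancers")
  check_genes(genes)
  genes <- add_tss(as_tibble(genes))
  enh <- fragment_midpoint(as_tibble(enhancers))
  links <- dplyr::inner_join(
    dplyr::mutate(genes[, c("gene_id", "chrom", "tss")], .gchrom = .data$chrom,
                  chrom = NULL),
    dplyr::mutate(enh, .echrom = .data$chrom),
    by = dplyr::join_by(".gchrom" == ".echrom"),
    relationship = "many-to-many"
  )
  links$distance <- abs(links$midpoint - links$tss)
  links <- links[links$distance <= window,
                 c("gene_id", "tss", "chrom", "start", "end",
                   "midpoint", "distance")]
  frac <- if (nrow(genes) == 0) 0 else
    length(unique(links$gene_id)) / nrow(genes)
  structure(as_tibble(links), fraction_genes_linked = frac)
}

#' Intersect two gene sets through an ortholog map
#'
#' @param set_a,set_b Character vectors of gene ids in species A and B.
#' @param ortholog_map A data frame with columns `id_a`, `id_b` giving
#'   one-to-one ortholog pairs.
#' @param strict Error on duplicated ids in the map (default `TRUE`);
#'   otherwise the first occurrence wins.
#' @return A list: `shared` (tibble of matched `id_a`, `id_b` pairs),
#'   `a_unique`, `b_unique`.
#' @export
intersect_ortholog_sets <- function(set_a, set_b, ortholog_map,
                                    strict = TRUE) {
  check_columns(ortholog_map, c("id_a", "id_b"), "ortholog_map")
  check_flag(strict, "strict")
  map <- as_tibble(ortholog_map)
  if (anyDuplicated(map$id_a) || anyDuplicated(map$id_b)) {
    if (strict) stop_format("ortholog_map must be one-to-one on both sides")
    map <- map[!duplicated(map$id_a) & !duplicated(map$id_b), , drop = FALSE]
  }
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  shared <- map[map$id_a %in% set_a & map$id_b %in% set_b, , drop = FALSE]
  list(
    shared = shared,
    a_unique = setdiff(set_a, shared$id_a),
    b_unique = setdiff(set_b, shared$id_b)
  )
}
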