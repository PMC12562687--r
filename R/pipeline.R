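# End-to-end orchestration: count -> call -> merge -> dynamics ->
# gene/expression/enhancer association, with all artifacts written as
# plain-text BED/TSV plus one machine-readable JSON summary.

#' Configure a pipeline run
#'
#' Every numeric default mirrors the analysis conventions used throughout
#' the package: 2 kb bins, Fisher p < 0.05 unadjusted, strict bin
#' adjacency for domain merging, a strict >80% gene-body coverage rule and
#' a +/-125 kb enhancer regulatory window. Inputs come either from a
#' seeded synthetic study (`sim`) or from files (`paths`).
#'
#' @param out_dir Output directory for all artifacts.
#' @param sim A `cyc_sim_params` to generate inputs (default); ignored
#'   when `paths` is given.
#' @param paths Optional named list of input files: `chrom_sizes`,
#'   `fragments` (named list with `g1s_chip`, `g1s_input`, `m_chip`,
#'   `m_input` BED paths), `genes`, `counts`, `enhancers`,
#'   `accessibility`, and optionally `degs`.
#' @param bin_size Bin width in bp.
#' @param alpha Per-bin significance level.
#' @param adjust `"none"` or `"bh"` (Benjamini-Hochberg).
#' @param scale ChIP effective-total normalization: `"background"` or
#'   `"library"` (see [call_enriched_bins()]).
#' @param max_gap Domain merge gap in bp.
#' @param coverage_threshold Strict gene-coverage threshold.
#' @param enhancer_window TSS regulatory window half-width in bp.
#' @param enhancer_cover_min,enhancer_rule Enhancer coverage rule (see
#'   [associate_enhancers()]).
#' @param genic_basis `"domain"` or `"bp"` for the genic partition.
#' @param shared_basis `"genome"` or `"union"` for shared fractions.
#' @param library_size RNA library total for FPKM; `NULL` uses the
#'   simulated study's library size or the sum of counts for file input.
#' @param deg_padj_max,deg_lfc_min DEG thresholds.
#' @param seed Seed used for simulation.
#' @param strict Strict parsing of input files.
#' @return A `cyc_config` list.
#' @export
run_config <- function(out_dir,
                       sim = sim_params(seed = seed),
                       paths = NULL,
                       bin_size = 2000,
                       alpha = 0.05,
                       adjust = "none",
                       scale = "background",
                       max_gap = 0,
                       coverage_threshold = 0.8,
                       enhancer_window = 125000,
                       enhancer_cover_min = 0.5,
                       enhancer_rule = "fraction",
                       genic_basis = "domain",
                       shared_basis = "genome",
                       library_size = NULL,
                       deg_padj_max = 0.01,
                       deg_lfc_min = 2,
                       seed = 1,
                       strict = TRUE) {
  structure(
    list(
      out_dir = out_dir, sim = sim, paths = paths, bin_size = bin_size,
      alpha = alpha, adjust = adjust, scale = scale, max_gap = max_gap,
      coverage_threshold = coverage_threshold,
      enhancer_window = enhancer_window,
      enhancer_cover_min = enhancer_cover_min,
      enhancer_rule = enhancer_rule, genic_basis = genic_basis,
      shared_basis = shared_basis, library_size = library_size,
      deg_padj_max = deg_padj_max, deg_lfc_min = deg_lfc_min,
      seed = as.integer(seed), strict = strict
    ),
    class = "cyc_config"
  )
}

load_pipeline_inputs <- function(config) {
  if (is.null(config$paths)) {
    study <- simulate_study(config$sim)
    list(
      layout = study$layout,
      fragments = study$fragments,
      genes = study$genes,
      counts = study$expression[, c("gene_id", "count")],
      library_size = config$library_size %||% study$library_size,
      enhancers = study$enhancers[, c("chrom", "start", "end")],
      accessibility = study$accessibility,
      degs = NULL,
      study = study
    )
  } else {
    p <- config$paths
    sizes <- read_chrom_sizes(p$chrom_sizes)
    layout <- genome_layout(sizes, bin_size = config$bin_size)
    frags <- lapply(p$fragments, read_bed, strict = config$strict)
    counts <- read_expression_table(p$counts)
    list(
      layout = layout,
      fragments = frags,
      genes = read_gene_table(p$genes, strict = config$strict),
      counts = counts,
      library_size = config$library_size %||% sum(counts$count),
      enhancers = read_bed(p$enhancers, strict = config$strict),
      accessibility = read_bed(p$accessibility, strict = config$strict),
      degs = if (!is.null(p$degs)) read_deg_table(p$degs) else NULL,
      study = NULL
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full domain-dynamics pipeline
#'
#' Executes count -> enrichment call -> domain merge -> summary stats ->
#' cross-phase dynamics -> gene, expression and enhancer association, and
#' writes every artifact under `config$out_dir`: per-sample bedGraph
#' tracks, per-phase bin tables and domain BEDs, the four dynamics-class
#' BEDs plus a combined TSV, gene scores, associated-gene and
#' associated-enhancer BEDs, enhancer links, and a `summary.json` holding
#' all headline numbers. Identical (config, seed) reruns produce
#' byte-identical outputs.
#'
#' @param config A `cyc_config` from [run_config()].
#' @return A `cyc_run` list: all intermediate objects plus `summary`
#'   (the list written to `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "cyc_config")) {
    stop_invalid("`config` must come from run_config()")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  inputs <- load_pipeline_inputs(config)
  layout <- inputs$layout

  # stage: count fragment midpoints per bin
  tracks <- lapply(inputs$fragments, count_midpoints, layout = layout,
                   strict = config$strict)
  for (nm in names(tracks)) {
    write_bedgraph(tracks[[nm]], out(paste0("track_", nm, ".bedgraph")))
  }

  # stage: per-bin enrichment calls per phase
  calls <- list(
    G1S = call_enriched_bins(tracks$g1s_chip, tracks$g1s_input,
                             alpha = config$alpha, adjust = config$adjust,
                             scale = config$scale),
    M = call_enriched_bins(tracks$m_chip, tracks$m_input,
                           alpha = config$alpha, adjust = config$adjust,
                           scale = config$scale)
  )
  for (nm in names(calls)) {
    tbl <- int_cols(as_tibble(calls[[nm]]), c("start", "end", "bin"))
    readr::write_tsv(tbl, out(paste0("bins_", nm, ".tsv")), progress = FALSE)
    write_bed(calls[[nm]][calls[[nm]]$significant,
                          c("chrom", "start", "end")],
              out(paste0("significant_bins_", nm, ".bed")))
  }

  # stage: merge significant bins into domains, summarize
  domains <- list(
    G1S = merge_bins_to_domains(calls$G1S, max_gap = config$max_gap,
                                condition = "G1S"),
    M = merge_bins_to_domains(calls$M, max_gap = config$max_gap,
                              condition = "M")
  )
  stats <- lapply(domains, domain_stats, layout = layout)
  for (nm in names(domains)) {
    write_bed(domains[[nm]], out(paste0("domains_", nm, ".bed")))
  }
  readr::write_tsv(dplyr::bind_rows(stats, .id = "condition"),
                   out("domain_stats.tsv"), progress = FALSE)

  # stage: cross-phase dynamics at base-pair resolution
  dynamics <- classify_dynamics(domains$G1S, domains$M, layout)
  for (cls in dynamics_levels) {
    write_bed(dynamics[dynamics$class == cls, c("chrom", "start", "end")],
              out(paste0("dynamics_", cls, ".bed")))
  }
  readr::write_tsv(int_cols(as_tibble(dynamics), c("start", "end")),
                   out("dynamics.tsv"), progress = FALSE)
  class_bp <- vapply(
    dynamics_levels,
    function(cls) interval_bp(dynamics[dynamics$class == cls, ]),
    numeric(1)
  )

  correlation <- tryCatch(
    bin_pearson(tracks$g1s_chip, tracks$m_chip),
    cyc_undefined_correlation = function(e) NA_real_
  )

  # stage: genes, expression, association
  m_specific <- dynamics_class(dynamics, "mitotic_specific")
  scored <- deposition_associated_genes(inputs$genes, m_specific,
                                        threshold = config$coverage_threshold)
  fpkm <- compute_fpkm(inputs$counts, inputs$genes,
                       library_size = inputs$library_size)
  scored <- dplyr::left_join(scored, fpkm[, c("gene_id", "count", "fpkm")],
                             by = "gene_id")
  readr::write_tsv(int_cols(scored, c("start", "end", "tss")),
                   out("gene_scores.tsv"), progress = FALSE)
  write_bed(
    dplyr::rename(scored[scored$associated,
                         c("chrom", "start", "end", "gene_id")],
                  name = "gene_id"),
    out("associated_genes.bed")
  )
  expr_test <- if (sum(scored$associated) >= 2 &&
                     sum(!scored$associated) >= 2) {
    compare_expression(scored, .data$fpkm, .data$associated)
  } else NULL

  genic <- partition_domains_genic(
    dynamics_class(dynamics, "conserved"), inputs$genes,
    basis = config$genic_basis
  )

  # stage: enhancers
  enh <- associate_enhancers(inputs$enhancers, inputs$accessibility,
                             m_specific,
                             cover_min = config$enhancer_cover_min,
                             rule = config$enhancer_rule)
  write_bed(enh[enh$associated, c("chrom", "start", "end")],
            out("associated_enhancers.bed"))
  links <- link_enhancers_to_genes(
    enh[enh$associated, c("chrom", "start", "end")],
    scored[scored$associated, , drop = FALSE],
    window = config$enhancer_window
  )
  readr::write_tsv(int_cols(links, c("start", "end", "tss", "midpoint",
                                     "distance")),
                   out("enhancer_links.tsv"), progress = FALSE)

  # stage: optional DEG overlap
  deg_report <- NULL
  if (!is.null(inputs$degs)) {
    sig <- filter_degs(inputs$degs, padj_max = config$deg_padj_max,
                       lfc_min = config$deg_lfc_min)
    expressed <- scored$gene_id[!is.na(scored$fpkm) & scored$fpkm > 1]
    deg_report <- deg_overlap(sig$gene_id,
                              scored$gene_id[scored$associated], expressed)
    readr::write_tsv(deg_report, out("deg_overlap.tsv"), progress = FALSE)
  }

  summary <- list(
    parameters = list(
      bin_size = layout$bin_size, alpha = config$alpha,
      adjust = config$adjust, scale = config$scale,
      max_gap = config$max_gap,
      coverage_threshold = config$coverage_threshold,
      enhancer_window = config$enhancer_window, seed = config$seed
    ),
    library_totals = lapply(tracks, counts_total),
    n_bins = n_bins(layout),
    n_significant_bins = lapply(calls, function(x) sum(x$significant)),
    domains = lapply(stats, as.list),
    dynamics_bp = as.list(class_bp),
    dynamics_fraction = as.list(class_bp / genome_size(layout)),
    tiling_ok = sum(class_bp) == genome_size(layout),
    shared_fraction = shared_fraction(domains$G1S, domains$M, layout,
                                      basis = config$shared_basis),
    phase_correlation = correlation,
    genes = c(
      list(
        n_scored = nrow(scored),
        n_associated = sum(scored$associated)
      ),
      if (!is.null(expr_test)) list(
        median_fpkm_associated =
          expr_test$groups$median_fpkm[expr_test$groups$group == "TRUE"],
        median_fpkm_other =
          expr_test$groups$median_fpkm[expr_test$groups$group == "FALSE"],
        fraction_fpkm_gt1_associated =
          expr_test$groups$fraction_fpkm_gt1[expr_test$groups$group == "TRUE"],
        welch_t = expr_test$statistic,
        welch_df = expr_test$df,
        welch_p = expr_test$p_value
      )
    ),
    genic_partition = as.list(genic[, c("genic", "intergenic", "basis")]),
    enhancers = list(
      n_input = nrow(enh),
      n_associated = sum(enh$associated),
      n_links = nrow(links),
      fraction_genes_linked = attr(links, "fraction_genes_linked")
    ),
    deg_overlap = if (!is.null(deg_report)) as.list(deg_report)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(
    list(
      config = config, layout = layout, tracks = tracks, calls = calls,
      domains = domains, domain_stats = stats, dynamics = dynamics,
      genes = scored, expression = fpkm, expr_test = expr_test,
      enhancers = enh, links = links, deg_report = deg_report,
      study = inputs$study, truth = inputs$study$truth, summary = summary
    ),
    class = "cyc_run"
  )
}

#' @export
print.cyc_run <- function(x, ...) {
  s <- x$summary
  cat("<cyc_run>\n")
  cat(sprintf("  bins: %d, significant G1S/M: %d/%d\n", s$n_bins,
              s$n_significant_bins$G1S, s$n_significant_bins$M))
  cat(sprintf("  domains G1S: %d (median %s bp, %.1f%% of genome)\n",
              s$domains$G1S$n_domains, format(s$domains$G1S$median_size),
              100 * s$domains$G1S$genome_fraction))
  cat(sprintf("  domains M:   %d (median %s bp, %.1f%% of genome)\n",
              s$domains$M$n_domains, format(s$domains$M$median_size),
              100 * s$domains$M$genome_fraction))
  cat(sprintf("  conserved: %.1f%%  g1s-specific: %.1f%%  mitotic-specific: %.1f%%\n",
              100 * s$dynamics_fraction$conserved,
              100 * s$dynamics_fraction$g1s_specific,
              100 * s$dynamics_fraction$mitotic_specific))
  cat(sprintf("  associated genes: %d of %d\n", s$genes$n_associated,
              s$genes$n_scored))
  if (!is.null(s$genes$welch_p)) {
    cat(sprintf("  median FPKM associated/other: %.2f / %.2f (Welch p = %.3g)\n",
                s$genes$median_fpkm_associated, s$genes$median_fpkm_other,
                s$genes$welch_p))
  }
  cat(sprintf("  associated enhancers: %d; genes with linked enhancer: %.1f%%\n",
              s$enhancers$n_associated,
              100 * s$enhancers$fraction_genes_linked))
  invisible(x)
}
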