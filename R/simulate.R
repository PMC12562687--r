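# Seeded synthetic study generator: planted domain landscape, ChIP/input
# fragments, genes with expression, and accessible enhancers.

#' Parameters for the synthetic study
#'
#' Defaults describe a desk-scale study: a 2 x 5 Mb genome (5,000 bins of
#' 2 kb) in which broad histone-variant domains cover 75% of the genome —
#' 50% conserved across the cell cycle, 10% G1/S-specific (removed over
#' mitosis) and 15% mitotic-specific (deposited over mitosis) — with
#' log-normal domain lengths (median ~5 kb, i.e. a few bins, snapped to the
#' bin grid), ChIP rate 5x background inside occupied loci, and a mean of
#' 30 fragment midpoints per bin. Genes are compact (0.8-1.8 kb, the
#' genome-wide scale-down of real gene bodies); genes planted inside
#' mitotic-specific loci draw FPKM from a high log-normal (median 8) and
#' all others from a low one (median 0.4), emulating the observation that
#' mitotic deposition targets genes active in interphase.
#'
#' @param n_chroms,chrom_length,bin_size Genome shape.
#' @param fractions Named target genome fractions for `conserved`,
#'   `g1s_specific`, `mitotic_specific`; their sum must be at most 1.
#' @param domain_median,domain_sdlog Log-normal planted domain lengths (bp).
#' @param enrichment_ratio ChIP rate inside occupied loci over background.
#' @param depth Mean fragment midpoints per bin (background and input).
#' @param fragment_length Fixed fragment length in bp (mononucleosome
#'   scale).
#' @param n_genes,covered_gene_fraction,gene_length_range Gene model.
#' @param fpkm_meanlog_high,fpkm_meanlog_low,fpkm_sdlog Expression model on
#'   the log scale.
#' @param library_size RNA library total used to back-compute counts.
#' @param n_enhancers,enhancer_length_range,enhancer_covered_fraction,accessible_fraction
#'   Enhancer model.
#' @param seed Integer seed; every generator is a pure function of
#'   (params, seed).
#' @return A `cyc_sim_params` list.
#' @export
sim_params <- function(n_chroms = 2,
                       chrom_length = 5e6,
                       bin_size = 2000,
                       fractions = c(conserved = 0.50,
                                     g1s_specific = 0.10,
                                     mitotic_specific = 0.15),
                       domain_median = 5000,
                       domain_sdlog = 0.35,
                       enrichment_ratio = 5,
                       depth = 30,
                       fragment_length = 150,
                       n_genes = 400,
                       covered_gene_fraction = 0.5,
                       gene_length_range = c(800, 1800),
                       fpkm_meanlog_high = log(8),
                       fpkm_meanlog_low = log(0.4),
                       fpkm_sdlog = 1,
                       library_size = 2e7,
                       n_enhancers = 300,
                       enhancer_length_range = c(400, 800),
                       enhancer_covered_fraction = 0.5,
                       accessible_fraction = 0.8,
                       seed = 1) {
  check_scalar_number(n_chroms, "n_chroms", min = 1)
  check_scalar_number(chrom_length, "chrom_length", min = 0, strict_min = TRUE)
  check_scalar_number(bin_size, "bin_size", min = 0, strict_min = TRUE)
  stopifnot(is.numeric(fractions))
  required <- c("conserved", "g1s_specific", "mitotic_specific")
  if (!all(required %in% names(fractions))) {
    stop_invalid("`fractions` must name conserved, g1s_specific, mitotic_specific")
  }
  fractions <- fractions[required]
  if (any(fractions < 0) || sum(fractions) > 1) {
    stop_invalid("class fractions must be non-negative and sum to at most 1")
  }
  check_scalar_number(enrichment_ratio, "enrichment_ratio", min = 0,
                      strict_min = TRUE)
  check_scalar_number(depth, "depth", min = 0, strict_min = TRUE)
  check_scalar_number(seed, "seed")
  structure(
    list(
      n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
      bin_size = bin_size, fractions = fractions,
      domain_median = domain_median, domain_sdlog = domain_sdlog,
      enrichment_ratio = enrichment_ratio, depth = depth,
      fragment_length = fragment_length,
      n_genes = as.integer(n_genes),
      covered_gene_fraction = covered_gene_fraction,
      gene_length_range = gene_length_range,
      fpkm_meanlog_high = fpkm_meanlog_high,
      fpkm_meanlog_low = fpkm_meanlog_low,
      fpkm_sdlog = fpkm_sdlog,
      library_size = library_size,
      n_enhancers = as.integer(n_enhancers),
      enhancer_length_range = enhancer_length_range,
      enhancer_covered_fraction = enhancer_covered_fraction,
      accessible_fraction = accessible_fraction,
      seed = as.integer(seed)
    ),
    class = "cyc_sim_params"
  )
}

check_params <- function(p) {
  if (!inherits(p, "cyc_sim_params")) {
    stop_invalid("`params` must come from sim_params()")
  }
  invisible(p)
}

sim_layout <- function(p) {
  genome_layout(
    setNames(rep(p$chrom_length, p$n_chroms), paste0("chr", seq_len(p$n_chroms))),
    bin_size = p$bin_size
  )
}

#' Plant the ground-truth domain landscape
#'
#' Walks each chromosome left to right, alternating geometric gaps with
#' log-normal domain lengths snapped to the bin grid, and assigns each
#' planted domain to a class with probability proportional to that class's
#' remaining bp budget. Budget tracking makes realized class fractions
#' land within a couple of percent of the targets. Planted domains are
#' bin-aligned so that recovery error measures calling error, not grid
#' quantization.
#'
#' @param params A `cyc_sim_params`.
#' @return A list of class `cyc_truth`: `layout` (`cyc_layout`),
#'   `partition` (a `cyc_dynamics`-style tibble tiling the genome with
#'   classes conserved / g1s_specific / mitotic_specific / unoccupied) and
#'   `params`.
#' @export
simulate_truth <- function(params) {
  check_params(params)
  p <- params
  layout <- sim_layout(p)
  set.seed(p$seed)
  B <- p$bin_size
  total_bins <- n_bins(layout)
  budget <- round(p$fractions * total_bins)
  f_occ <- sum(p$fractions)
  mean_dom_bins <- max(1, p$domain_median * exp(p$domain_sdlog^2 / 2) / B)
  mean_gap_bins <- if (f_occ >= 1) 0 else mean_dom_bins * (1 - f_occ) / f_occ
  p_gap <- 1 / (1 + mean_gap_bins)

  segs <- list()
  k <- 0L
  for (ci in seq_len(nrow(layout$chroms))) {
    chrom <- layout$chroms$chrom[ci]
    chrom_bins <- layout$chroms$n_bins[ci]
    chrom_len <- layout$chroms$length[ci]
    pos <- 0
    while (pos < chrom_bins && sum(budget) > 0) {
      pos <- pos + rgeom(1, p_gap)
      if (pos >= chrom_bins) break
      active <- which(budget > 0)
      cls <- names(budget)[
        active[sample.int(length(active), 1, prob = budget[active])]
      ]
      len <- max(1, round(rlnorm(1, log(p$domain_median), p$domain_sdlog) / B))
      len <- min(len, budget[[cls]], chrom_bins - pos)
      k <- k + 1L
      segs[[k]] <- tibble(
        chrom = chrom,
        start = pos * B,
        end = min((pos + len) * B, chrom_len),
        class = cls
      )
      budget[[cls]] <- budget[[cls]] - len
      pos <- pos + len
    }
  }
  planted <- if (k > 0) dplyr::bind_rows(segs) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           class = character())
  occupied <- planted[, c("chrom", "start", "end")]
  unocc <- interval_complement(occupied, layout)
  unocc$class <- "unoccupied"
  partition <- dplyr::bind_rows(planted, unocc)
  partition$class <- factor(partition$class, levels = dynamics_levels)
  partition <- dplyr::arrange(
    partition,
    factor(.data$chrom, levels = layout$chroms$chrom), .data$start
  )
  partition <- structure(partition, layout = layout,
                         class = c("cyc_dynamics", class(tibble())))
  structure(list(layout = layout, partition = partition, params = p),
            class = "cyc_truth")
}

check_truth <- function(x) {
  if (!inherits(x, "cyc_truth")) {
    stop_invalid("`truth` must come from simulate_truth()")
  }
  invisible(x)
}

# occupied set of one phase: conserved plus that phase's specific class
phase_occupied <- function(truth, phase = c("G1S", "M")) {
  phase <- match.arg(phase)
  specific <- if (phase == "G1S") "g1s_specific" else "mitotic_specific"
  part <- truth$partition
  interval_merge(part[part$class %in% c("conserved", specific),
                      c("chrom", "start", "end")])
}

#' Simulate ChIP or input fragments for one phase
#'
#' Per-bin midpoint counts are Poisson: the input is uniform at `depth`
#' per bin, and the ChIP rate is raised by `enrichment_ratio` inside the
#' phase's occupied set (conserved plus the phase-specific class).
#' Midpoints are placed uniformly within their bin and fragments span
#' `fragment_length` bp, shifted inward at chromosome edges so every
#' fragment's midpoint stays in its bin.
#'
#' @param truth A `cyc_truth` from [simulate_truth()].
#' @param phase `"G1S"` or `"M"`.
#' @param role `"chip"` or `"input"`.
#' @param params A `cyc_sim_params` (defaults to the truth's own).
#' @return A fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @export
simulate_fragments <- function(truth, phase = c("G1S", "M"),
                               role = c("chip", "input"),
                               params = truth$params) {
  check_truth(truth)
  phase <- match.arg(phase)
  role <- match.arg(role)
  check_params(params)
  p <- params
  layout <- truth$layout
  offset <- c(G1S.chip = 11L, G1S.input = 12L, M.chip = 13L, M.input = 14L)
  set.seed(p$seed + offset[[paste(phase, role, sep = ".")]])

  bins <- make_bins(layout)
  rate <- rep(p$depth, nrow(bins))
  if (role == "chip") {
    frac <- covered_fraction(bins, phase_occupied(truth, phase))
    rate <- p$depth * (1 + (p$enrichment_ratio - 1) * frac)
  }
  counts <- rpois(nrow(bins), rate)
  idx <- rep.int(seq_len(nrow(bins)), counts)
  width <- (bins$end - bins$start)[idx]
  mid <- bins$start[idx] + floor(runif(length(idx)) * width)
  len <- p$fragment_length
  start <- mid - len %/% 2
  chrom_len <- layout$chroms$length[match(bins$chrom[idx], layout$chroms$chrom)]
  start <- pmin(pmax(start, 0), chrom_len - len)
  out <- tibble(
    chrom = bins$chrom[idx],
    start = start,
    end = start + len,
    strand = "."
  )
  dplyr::arrange(out, factor(.data$chrom, levels = layout$chroms$chrom),
                 .data$start)
}

# place n non-overlapping intervals of the given lengths inside `space`
# (a merged interval set); returns a tibble or errors after bounded retries
place_intervals <- function(space, lengths, label, max_tries = 200) {
  space <- interval_merge(space)
  seg_len <- space$end - space$start
  placed <- vector("list", length(lengths))
  occupied <- list()
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    ok_seg <- which(seg_len >= len)
    if (length(ok_seg) == 0) {
      abort(sprintf("no %s segment can hold an interval of %d bp", label, len),
            class = "cyc_infeasible_layout")
    }
    done <- FALSE
    for (try in seq_len(max_tries)) {
      si <- ok_seg[sample.int(length(ok_seg), 1,
                              prob = seg_len[ok_seg] - len + 1)]
      s <- space$start[si] + floor(runif(1) * (seg_len[si] - len + 1))
      e <- s + len
      chrom <- space$chrom[si]
      clash <- FALSE
      prev <- occupied[[chrom]]
      if (!is.null(prev)) {
        clash <- any(s < prev$end & e > prev$start)
      }
      if (!clash) {
        placed[[i]] <- tibble(chrom = chrom, start = s, end = e)
        occupied[[chrom]] <- dplyr::bind_rows(prev,
                                              tibble(start = s, end = e))
        done <- TRUE
        break
      }
    }
    if (!done) {
      abort(sprintf("could not place %s interval %d without overlap", label, i),
            class = "cyc_infeasible_layout")
    }
  }
  dplyr::bind_rows(placed)
}

#' Simulate genes and their expression
#'
#' A configurable fraction of genes is placed fully inside mitotic-specific
#' truth (labelled `covered`); the rest are placed outside the
#' mitotic-specific set. Covered genes draw FPKM from the high log-normal
#' and the others from the low one; counts are back-computed from FPKM,
#' gene length and the fixed library size.
#'
#' @param truth A `cyc_truth`.
#' @param params A `cyc_sim_params` (defaults to the truth's own).
#' @return A list: `genes` (gene table with `covered` label), `expression`
#'   (`gene_id`, `count`, `fpkm_sim`), `library_size`.
#' @export
simulate_genes_expression <- function(truth, params = truth$params) {
  check_truth(truth)
  check_params(params)
  p <- params
  set.seed(p$seed + 21L)
  if (p$n_genes == 0) {
    genes <- tibble(gene_id = character(), chrom = character(),
                    start = numeric(), end = numeric(), strand = character(),
                    biotype = character(), covered = logical())
    return(list(genes = genes,
                expression = tibble(gene_id = character(), count = numeric(),
                                    fpkm_sim = numeric()),
                library_size = p$library_size))
  }
  n_cov <- round(p$n_genes * p$covered_gene_fraction)
  n_unc <- p$n_genes - n_cov
  lengths <- round(runif(p$n_genes, p$gene_length_range[1],
                         p$gene_length_range[2]))
  m_spec <- dynamics_class(truth$partition, "mitotic_specific")
  other <- interval_complement(m_spec, truth$layout)
  cov_genes <- if (n_cov > 0) {
    place_intervals(m_spec, lengths[seq_len(n_cov)], "mitotic-specific")
  } else empty_intervals()
  unc_genes <- if (n_unc > 0) {
    place_intervals(other, lengths[n_cov + seq_len(n_unc)], "non-covered")
  } else empty_intervals()
  genes <- dplyr::bind_rows(cov_genes, unc_genes)
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  genes$strand <- rep(c("+", "-"), length.out = nrow(genes))
  genes$biotype <- "protein_coding"
  genes$covered <- rep(c(TRUE, FALSE), c(n_cov, n_unc))
  genes <- add_tss(genes[, c("gene_id", "chrom", "start", "end", "strand",
                             "biotype", "covered")])

  meanlog <- ifelse(genes$covered, p$fpkm_meanlog_high, p$fpkm_meanlog_low)
  fpkm <- rlnorm(nrow(genes), meanlog, p$fpkm_sdlog)
  len <- genes$end - genes$start
  count <- round(fpkm * (len / 1e3) * (p$library_size / 1e6))
  list(
    genes = genes,
    expression = tibble(gene_id = genes$gene_id, count = count,
                        fpkm_sim = fpkm),
    library_size = p$library_size
  )
}

#' Simulate enhancers and chromatin accessibility
#'
#' Enhancers are placed inside or outside the mitotic-specific truth in the
#' configured proportion; a configured fraction of enhancers is accessible,
#' and accessibility intervals are the accessible enhancers padded by
#' 100 bp and merged.
#'
#' @param truth A `cyc_truth`.
#' @param params A `cyc_sim_params` (defaults to the truth's own).
#' @return A list: `enhancers` (tibble with `covered` and `accessible`
#'   labels) and `accessibility` (interval tibble).
#' @export
simulate_enhancers <- function(truth, params = truth$params) {
  check_truth(truth)
  check_params(params)
  p <- params
  set.seed(p$seed + 31L)
  if (p$n_enhancers == 0) {
    return(list(
      enhancers = tibble(chrom = character(), start = numeric(),
                         end = numeric(), covered = logical(),
                         accessible = logical()),
      accessibility = empty_intervals()
    ))
  }
  n_cov <- round(p$n_enhancers * p$enhancer_covered_fraction)
  n_unc <- p$n_enhancers - n_cov
  lengths <- round(runif(p$n_enhancers, p$enhancer_length_range[1],
                         p$enhancer_length_range[2]))
  m_spec <- dynamics_class(truth$partition, "mitotic_specific")
  other <- interval_complement(m_spec, truth$layout)
  enh <- dplyr::bind_rows(
    if (n_cov > 0) place_intervals(m_spec, lengths[seq_len(n_cov)],
                                   "mitotic-specific enhancer")
    else empty_intervals(),
    if (n_unc > 0) place_intervals(other, lengths[n_cov + seq_len(n_unc)],
                                   "background enhancer")
    else empty_intervals()
  )
  enh$covered <- rep(c(TRUE, FALSE), c(n_cov, n_unc))
  enh$accessible <- runif(nrow(enh)) < p$accessible_fraction
  acc <- enh[enh$accessible, c("chrom", "start", "end")]
  if (nrow(acc) > 0) {
    chrom_len <- truth$layout$chroms$length[
      match(acc$chrom, truth$layout$chroms$chrom)
    ]
    acc$start <- pmax(acc$start - 100, 0)
    acc$end <- pmin(acc$end + 100, chrom_len)
    acc <- interval_merge(acc)
  }
  list(enhancers = enh, accessibility = acc)
}

#' Run the full synthetic study
#'
#' Convenience wrapper generating the truth, the four fragment samples
#' (ChIP and input for G1/S and mitosis), genes with expression, and
#' enhancers with accessibility, all deterministically from
#' `params$seed`.
#'
#' @param params A `cyc_sim_params`.
#' @return A list of class `cyc_study` with components `params`, `layout`,
#'   `truth`, `fragments` (named list `g1s_chip`, `g1s_input`, `m_chip`,
#'   `m_input`), `genes`, `expression`, `library_size`, `enhancers`,
#'   `accessibility`.
#' @export
simulate_study <- function(params = sim_params()) {
  check_params(params)
  truth <- simulate_truth(params)
  ge <- simulate_genes_expression(truth, params)
  ea <- simulate_enhancers(truth, params)
  structure(
    list(
      params = params,
      layout = truth$layout,
      truth = truth,
      fragments = list(
        g1s_chip = simulate_fragments(truth, "G1S", "chip", params),
        g1s_input = simulate_fragments(truth, "G1S", "input", params),
        m_chip = simulate_fragments(truth, "M", "chip", params),
        m_input = simulate_fragments(truth, "M", "input", params)
      ),
      genes = ge$genes,
      expression = ge$expression,
      library_size = ge$library_size,
      enhancers = ea$enhancers,
      accessibility = ea$accessibility
    ),
    class = "cyc_study"
  )
}
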