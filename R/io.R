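# Readers and writers for the plain-text interchange formats:
# chrom.sizes, BED, bedGraph, GTF-lite gene rows, and the TSV tables.
# All interval output is 0-based half-open; GTF is converted at this
# boundary (1-based closed -> 0-based half-open).

bed_is_skippable <- function(lines) {
  grepl("^(#|track\\b|browser\\b)", lines) | lines == ""
}

int_cols <- function(x, cols) {
  for (col in cols) x[[col]] <- as.integer(round(x[[col]]))
  x
}

#' Read a chrom.sizes table
#'
#' @param path Two-column TSV (chromosome name, length).
#' @return A tibble with columns `chrom`, `length`, ready for
#'   [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  if (any(!is.finite(x$length)) || any(x$length <= 0)) {
    stop_format("chrom.sizes lengths must be positive numbers")
  }
  x
}

#' Read a BED file of intervals
#'
#' Parses 3-6 column BED (0-based half-open), skipping comment, `track`
#' and `browser` lines. Records with non-numeric coordinates or
#' `start >= end` raise an error in strict mode, or are dropped with a
#' warning otherwise. Records are returned sorted by (chrom, start).
#'
#' @param path BED file path.
#' @param min_cols Minimum number of columns required (default 3).
#' @param strict Error on malformed records (default `TRUE`).
#' @return A tibble with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path, min_cols = 3, strict = TRUE) {
  check_flag(strict, "strict")
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!bed_is_skippable(lines)]
  if (length(lines) == 0) return(empty_intervals())
  fields <- stringr::str_split(lines, "\t")
  n_fields <- lengths(fields)
  if (any(n_fields < min_cols)) {
    stop_format(sprintf("BED records with fewer than %d columns", min_cols))
  }
  ncol_use <- min(6, min(n_fields))
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol_use)]
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  out <- as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE), cols))
  out$start <- suppressWarnings(as.numeric(out$start))
  out$end <- suppressWarnings(as.numeric(out$end))
  bad <- !is.finite(out$start) | !is.finite(out$end) |
    out$start < 0 | out$start >= out$end
  if (any(bad)) {
    if (strict) {
      stop_record(sprintf("%d malformed BED record(s) in %s", sum(bad), path))
    }
    warn(sprintf("dropped %d malformed BED record(s)", sum(bad)),
         class = "cyc_dropped_records")
    out <- out[!bad, , drop = FALSE]
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write intervals as BED
#'
#' @param x A data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  # BED columns are positional: keep the longest gap-free prefix present
  bed_cols <- c("chrom", "start", "end", "name", "score", "strand")
  have <- cumprod(bed_cols %in% names(x)) == 1
  cols <- bed_cols[have]
  out <- int_cols(as_tibble(x)[, cols, drop = FALSE], c("start", "end"))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(x)
}

#' Write a binned count track as bedGraph
#'
#' @param counts A `cyc_counts` object (or any tibble with `chrom`,
#'   `start`, `end` and a value column).
#' @param path Output path.
#' @param value Name of the value column (default `"count"`).
#' @return `counts`, invisibly.
#' @export
write_bedgraph <- function(counts, path, value = "count") {
  check_columns(counts, c("chrom", "start", "end", value), "counts")
  out <- int_cols(as_tibble(counts)[, c("chrom", "start", "end", value)],
                  c("start", "end"))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(counts)
}

#' Read a bedGraph track
#'
#' @param path bedGraph path (4 columns: chrom, start, end, value).
#' @return A tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!bed_is_skippable(lines)]
  readr::read_tsv(I(lines), col_names = c("chrom", "start", "end", "value"),
                  col_types = "cddd", progress = FALSE)
}

parse_gtf_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0(key, '\\s+"([^"]*)"'))
  m[, 2]
}

#' Read a gene table from GTF or TSV
#'
#' The GTF reader consumes gene rows (feature type `"gene"`, one row per
#' gene) with `gene_id` and `gene_biotype` attributes, converting 1-based
#' closed coordinates to 0-based half-open. The TSV format carries columns
#' `gene_id`, `chrom`, `start`, `end`, `strand`, `biotype` already 0-based
#' half-open. A strand-aware `tss` column is added (start of the body on
#' `+`, last base on `-`).
#'
#' @param path Input path.
#' @param format `"auto"` (by file extension), `"gtf"` or `"tsv"`.
#' @param strict Error on duplicated or missing gene ids (default `TRUE`).
#' @return A gene-table tibble.
#' @export
read_gene_table <- function(path, format = c("auto", "gtf", "tsv"),
                            strict = TRUE) {
  format <- match.arg(format)
  check_flag(strict, "strict")
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  }
  if (format == "gtf") {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[!grepl("^#", lines) & lines != ""]
    gtf <- readr::read_tsv(
      I(lines),
      col_names = c("chrom", "source", "feature", "start", "end", "score",
                    "strand", "frame", "attributes"),
      col_types = "cccddcccc", progress = FALSE
    )
    gtf <- gtf[gtf$feature == "gene", , drop = FALSE]
    genes <- tibble(
      gene_id = parse_gtf_attr(gtf$attributes, "gene_id"),
      chrom = gtf$chrom,
      start = gtf$start - 1,   # 1-based closed -> 0-based half-open
      end = gtf$end,
      strand = gtf$strand,
      biotype = parse_gtf_attr(gtf$attributes, "gene_biotype")
    )
  } else {
    genes <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = "c", chrom = "c", start = "d", end = "d",
      strand = "c", biotype = "c", .default = "?"
    ), progress = FALSE)
    check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  }
  if (anyNA(genes$gene_id)) {
    if (strict) stop_record("gene record(s) without gene_id")
    genes <- genes[!is.na(genes$gene_id), , drop = FALSE]
  }
  if (anyDuplicated(genes$gene_id)) {
    if (strict) stop_record("duplicated gene_id values")
    genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  }
  check_genes(genes)
  add_tss(genes)
}

#' Write a gene table as GTF gene rows
#'
#' @param genes A gene table (0-based half-open); written as 1-based
#'   closed GTF gene rows with `gene_id` and `gene_biotype` attributes.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `genes`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "cycledomains") {
  check_genes(genes)
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  biotype <- if ("biotype" %in% names(genes)) genes$biotype else "protein_coding"
  lines <- sprintf(
    '%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    genes$chrom, source, as.integer(genes$start + 1), as.integer(genes$end),
    strand, genes$gene_id, biotype
  )
  readr::write_lines(lines, path)
  invisible(genes)
}

#' Read a gene-level count table
#'
#' @param path TSV with columns `gene_id`, `count`.
#' @return A tibble.
#' @export
read_expression_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", count = "d", .default = "?"
  ), progress = FALSE)
  check_columns(x, c("gene_id", "count"), "expression")
  x
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `padj`.
#' @return A tibble.
#' @export
read_deg_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", log2fc = "d", padj = "d", .default = "?"
  ), progress = FALSE)
  check_columns(x, c("gene_id", "log2fc", "padj"), "degs")
  x
}

#' Read a two-column ortholog map
#'
#' @param path TSV with columns `id_a`, `id_b`.
#' @return A tibble.
#' @export
read_ortholog_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    id_a = "c", id_b = "c", .default = "?"
  ), progress = FALSE)
  check_columns(x, c("id_a", "id_b"), "ortholog_map")
  x
}

#' Write a synthetic study to disk
#'
#' Emits exactly the formats the pipeline consumes: `chrom.sizes`,
#' per-sample fragment BEDs, genes as GTF and TSV, a count TSV, enhancer
#' and accessibility BEDs, ground-truth class BEDs with a label TSV, and a
#' `params.yaml` carrying every simulation parameter including the seed.
#'
#' @param study A `cyc_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "cyc_study")) {
    stop_invalid("`study` must come from simulate_study()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(dir, ...)
  readr::write_tsv(
    int_cols(study$layout$chroms[, c("chrom", "length")], "length"),
    path("chrom.sizes"), col_names = FALSE, progress = FALSE
  )
  for (nm in names(study$fragments)) {
    write_bed(study$fragments[[nm]], path(paste0("fragments_", nm, ".bed")))
  }
  genes <- study$genes
  write_gtf(genes, path("genes.gtf"))
  readr::write_tsv(int_cols(genes, c("start", "end", "tss")),
                   path("genes.tsv"), progress = FALSE)
  readr::write_tsv(study$expression, path("counts.tsv"), progress = FALSE)
  write_bed(study$enhancers[, c("chrom", "start", "end")],
            path("enhancers.bed"))
  write_bed(study$accessibility, path("accessibility.bed"))
  part <- study$truth$partition
  for (cls in dynamics_levels) {
    write_bed(part[part$class == cls, c("chrom", "start", "end")],
              path(paste0("truth_", cls, ".bed")))
  }
  labels <- dplyr::bind_rows(
    tibble(id = genes$gene_id, kind = "gene", covered = genes$covered),
    tibble(id = sprintf("enh%04d", seq_len(nrow(study$enhancers))),
           kind = "enhancer", covered = study$enhancers$covered,
           accessible = study$enhancers$accessible)
  )
  readr::write_tsv(labels, path("truth_labels.tsv"), progress = FALSE)
  params <- study$params
  yaml::write_yaml(unclass(params), path("params.yaml"))
  invisible(dir)
}
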