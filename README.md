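# cycledomains

Broad histone-variant chromatin domains — macroH2A-style marks that blanket
half the genome in multi-kilobase blocks — are remodelled over the cell
cycle: some loci stay occupied from G1/S through mitosis, others gain the
variant specifically over mitosis (deposition) or lose it (removal).
`cycledomains` is an R package for epigenomics analysts that turns mapped
ChIP/input fragments from two cell-cycle conditions into that domain-dynamics
map and relates it to genes, expression and enhancers. It is
tidyverse-native: every step takes a data frame and returns a tibble, so the
whole analysis chains with the pipe, and fitted results carry
`tidy()`/`glance()`/`autoplot()` methods.

## The method

* **Binning and counting.** The genome is tiled with fixed 2 kb bins
  (half-open, BED convention; the short trailing bin is kept) and each
  fragment contributes the bin containing its midpoint.
* **Enrichment.** Each bin is tested with a one-sided Fisher exact test on
  the 2x2 table `[[a, C - a], [b, I - b]]` — ChIP count `a` of effective
  total `C`, input count `b` of total `I` — i.e. the hypergeometric tail
  `P(X >= a)`. Bins with `p < 0.05` (unadjusted; BH optional) are enriched.
  Because a broad mark's enriched fraction dominates the ChIP library, `C`
  is by default a *background-scaled* total `C = s * I`, with `s` the
  background ChIP:input count ratio estimated by a signal-extraction-style
  cut on cumulative coverage (see the methods vignette,
  `vignettes/domain-dynamics.Rmd`).
* **Domains and dynamics.** Adjacent significant bins merge into domains;
  base-pair set algebra between the G1/S and mitotic domain sets yields the
  exact genome partition *conserved / G1S-specific / mitotic-specific /
  unoccupied*.
* **Association.** Protein-coding genes with >80% (strict) of their body
  covered by mitotic-specific domains are *deposition-associated*; their
  FPKM (`count / ((len/1e3) * (library/1e6))`) is compared to the remaining
  genes with Welch's t-test on `log2(FPKM + 1)`. DEG tables are filtered at
  `padj < 0.01` and `|log2FC| > 2` (strict). Enhancers overlapping
  accessible chromatin and covered (>= 50% bp) by mitotic-specific domains
  are deposition-associated enhancers, linked to genes whose TSS lies
  within a closed ±125 kb window of the enhancer midpoint.
* **Synthetic studies.** A seeded generator (`simulate_study()`) plants a
  ground-truth domain landscape, Poisson ChIP/input fragments, genes whose
  expression depends on their planted coverage, and accessible enhancers,
  so every stage is testable end to end without sequencing data.

## Worked example

```r
library(cycledomains)

run <- run_pipeline(run_config(out_dir = "results/demo",
                               sim = sim_params(seed = 1), seed = 1))
print(run)
#> <cyc_run>
#>   bins: 5000, significant G1S/M: 3020/3276
#>   domains G1S: 676 (median 6000 bp, 60.4% of genome)
#>   domains M:   690 (median 8000 bp, 65.5% of genome)
#>   conserved: 50.0%  g1s-specific: 10.4%  mitotic-specific: 15.5%
#>   associated genes: 192 of 400
#>   median FPKM associated/other: 8.02 / 0.42 (Welch p = 2.1e-66)
#>   associated enhancers: 124; genes with linked enhancer: 98.4%
```

Reading the output: of 5,000 bins, 3,020 (G1/S) and 3,276 (M) are enriched
over input; merging adjacent significant bins gives 676 and 690 domains
covering 60.4% and 65.5% of the genome (the simulation planted 60%/65%
occupancy). The base-pair partition recovers the planted 50/10/15% class
fractions. 192 of 400 protein-coding genes exceed the strict 80%
mitotic-specific coverage rule (the generator planted 200 covered genes),
and their median FPKM (8.02) is far above the remaining genes' (0.42) —
Welch p ≈ 2e-66 — reproducing the deposition-on-active-genes pattern. 124
accessible, domain-covered enhancers are retained, and 98.4% of associated
genes have at least one enhancer within ±125 kb of their TSS.

All artifacts (bedGraph tracks, per-phase bin tables and domain BEDs, the
four dynamics-class BEDs, gene scores, enhancer links, `summary.json`) are
written under `out_dir`; identical (config, seed) reruns are
byte-identical. The same pipeline runs on file inputs (chrom.sizes,
fragment BEDs, GTF/TSV genes, count TSV, enhancer/accessibility BEDs) via
`run_config(paths = ...)`, and a thin CLI lives at
`inst/cli/cycledomains.R` (`simulate` / `run` subcommands).

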