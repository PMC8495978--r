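# splitlr

Computational pipeline for **LR-Split-seq**: single-cell long-read RNA-seq
built on split-pool combinatorial barcoding.  Three successive rounds of
well barcodes plus a UMI identify the cell of origin of each cDNA molecule;
sequencing the barcoded cDNA on a long-read platform reads transcript
structure and cell identity together, which makes transcription start/end
sites (TSS/TES) and isoform usage accessible at single-cell resolution.

`splitlr` is for analysts working with such libraries and implements the
computation specific to this design:

* **Demultiplexing** — locate the two inter-barcode linkers by bounded
  semi-global alignment (≤ 2 edits each, both orientations), extract the
  three barcode windows and UMI, correct each barcode to its per-round
  whitelist within Levenshtein distance 3 (shifted windows charged
  `dist + |shift| ≤ 3` to absorb indels; ties rejected as ambiguous),
  optionally keep only barcode combinations seen in companion short-read
  data, and merge the oligo-dT / random-hexamer well pair of each cell.
* **End calling** — TSS/TES peaks from novelty-filtered read 5′/3′ ends:
  positions chained when gaps ≤ 50 bp; summit, wide and narrow peaks; ≥ 2
  supporting long reads (≥ 20 for short-read ends); per-gene fractional
  filter `count > f·M` (f = 0.10 single-cell TSS, 0.05 bulk TSS, 0.80 TES);
  peaks named `<gene>_<k>` by coordinate; 1-bp-overlap validation against
  external BED sets.
* **TSS quantification** — read starts expanded ±25 bp, intersected with
  peak wide intervals (≥ 1 bp), gene-gated, counted per cell; cell filter
  at ≥ 500 reads; novel-transcript reproducibility filters (≥ 4 sub-cells
  single-cell; ≥ 5 copies in ≥ 2 replicates bulk).
* **Differential usage** — per gene, an n×2 contingency table over isoform
  or TSS counts in two cell groups (≤ 11 rows, lowest-expressed pooled),
  Pearson chi-squared (df = rows − 1, no continuity correction), effect
  size Δπ = Σ|π_A − π_B| over the top-two features (0–200 percent points),
  Benjamini-Hochberg correction; significant when p_adj ≤ 0.05 and
  Δπ ≥ 10, testable at ≥ 10 reads per condition.
* **ATAC integration** — group means of TSS expression and accessibility,
  log2 fold changes with pseudocount 1, group-specific TSSs beyond 2·SD in
  *both* modalities, binary expressed/accessible states (cutoffs 2 reads /
  1000 normalized units), top-TSS concordance, Pearson/Spearman
  correlations.
* **Simulation** — seed-controlled generators with complete ground truth
  for every stage: barcoded reads with configurable substitution/indel
  rates, read ends around planted TSS/TES architectures, usage matrices
  with planted switches, accessibility coupled to expression at an exact
  target correlation.

See `vignettes/splitlr-methods.Rmd` for the full model description and the
design decisions.

## Worked example

```r
library(splitlr)

# 2,000 noisy barcoded reads from 48 cells, then demultiplex them
layout <- sim_barcode_layout(seed = 1)
sim <- simulate_barcoded_reads(layout, n_reads = 2000, n_cells = 48, seed = 2)
dm <- demux_reads(sim$seq, layout)
table(dm$records$status)
#> NO_LINKERS         OK
#>          7       1993
```

1,993 of 2,000 reads are assigned (7 lost linkers to simulated sequencing
errors), and every assigned read lands in its true cell — the simulation
whitelists guarantee unambiguous correction at edit distance 3.

```r
# planted TSS architecture -> called peaks
models <- sim_gene_models(n_genes = 6, max_tss = 3, pi_shape = Inf, seed = 3)
ends <- simulate_end_annotations(models, reads_per_gene = 200,
                                 jitter_sd = 5, seed = 4)
tss <- call_ends(ends$annotations, end_call_config("tss", "sc"))
head(tss[, c("name", "chrom", "strand", "wide_start", "wide_end",
             "summit", "read_count")])
#>        name chrom strand wide_start wide_end  summit read_count
#> 1 gene001_1  chr1      +     999986  1000014 1000001        200
#> 2 gene002_1  chr2      -    2049989  2050013 2050000         71
#> 3 gene002_2  chr2      -    2050291  2050310 2050304         64
#> 4 gene002_3  chr2      -    2050588  2050613 2050598         65
#> 5 gene003_1  chr3      +    2999988  3000013 2999999        114
#> 6 gene003_2  chr3      +    3000288  3000317 3000295         86
```

Summits sit within a few bp of the planted sites (1,000,000; 2,050,000 +
300-bp spacing; ...), and per-gene read counts follow the planted usage.

```r
# differential usage between two groups with 4 planted switch genes
usage <- simulate_usage_counts(n_genes = 40, n_features = 3,
                               reads_per_group = 120, n_switch = 4,
                               pi_a = c(0.7, 0.2, 0.1), seed = 5)
res <- run_usage_tests(usage$matrix, usage$feature_genes,
                       usage$cell_groups, pair = c("A", "B"))
subset(res, significant)[, c("gene_id", "chi2", "df", "p_adj", "dpi")]
#>    gene_id     chi2 df        p_adj      dpi
#> 1 gene0001 55.57719  2 1.148300e-11 89.16667
#> 2 gene0002 68.29871  2 5.904510e-14 99.16667
#> 3 gene0003 53.34954  2 2.601921e-11 86.66667
#> 4 gene0004 55.56084  2 1.148300e-11 93.33333
```

Exactly the four planted switch genes are significant: the chi-squared
statistic is large, the adjusted p-values are far below 0.05, and the
recovered Δπ (≈ 87–99 percent points) reflects the planted top-two usage
flip.

A thin command-line wrapper over the same functions ships at
`inst/scripts/splitlr` (subcommands `demux`, `call-ends`, `quant-tss`,
`test-usage`, `pipeline`).

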