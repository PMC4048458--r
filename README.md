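# genedist

Gene units defined by **genetic distance** for gene- and pathway-based
association analysis.

## The problem

Gene-level association methods (VEGAS-style statistics, pathway enrichment
over GWAS results, gene–gene interaction scans) assign SNPs to genes
through an extended gene unit: the gene body plus flanking sequence, where
cis-regulatory variants sit and where LD carries information about untyped
coding variation. The near-universal convention is a fixed physical window,
usually ± 50 Kb. But LD decays with genetic distance, and the exchange rate
between genetic and physical distance varies wildly along the genome —
most recombination happens in narrow hotspots separated by long
low-recombination stretches. A fixed window reaches too far across a
hotspot and not far enough through a recombination desert.

## The method

`genedist` builds units from a recombination map on a fixed 10 Kb genome
grid:

1. **Standardize**: each bin's rate r_i (cM/Mb) becomes the standardized
   recombination rate, SRR_i = r_i / r̄, where r̄ is the genome-wide mean;
   mean(SRR) = 1 by construction.
2. **Extend**: from each gene boundary, walk outward bin by bin,
   accumulating SRR, and stop at the first bin where the running sum
   reaches a threshold T (default **SRR ≥ 2**, which gives a genome-wide
   median extension close to the customary 50 Kb). The unit boundary is
   that bin's outer edge. Bins inside the gene body are never counted.
   Extensions are long where recombination is low and short where it is
   high.
3. **Fallback**: a side that runs out of map coverage (telomeres,
   centromeres) gets the median length of all completed extensions on its
   chromosome.

The fixed ± 50 Kb comparator, locus/candidate scorecards, and one-tailed
Fisher exact comparisons are included, plus a synthetic-map generator
(zero-inflated gamma with hotspots and coverage gaps) so every stage is
testable without downloads.

## Worked example

Using the small synthetic map and gene catalogue shipped with the package:

```r
library(genedist)

map   <- standardize_map(read_recombination_map(
           system.file("extdata", "example_map.tsv", package = "genedist")))
genes <- collapse_transcripts(read_genes(
           system.file("extdata", "example_genes.refgene", package = "genedist"),
           format = "refgene"))

units <- build_gene_units(genes, map, method = "srr")
units
#> gene units (srr method): 8 genes, 0 with a fallback side
as.data.frame(units)[1:4, c("name","left","right","ext_left","ext_right",
                            "cum_srr_left","cum_srr_right")]
#>       name   left   right ext_left ext_right cum_srr_left cum_srr_right
#> 1 GENE0008  10000   50000     5429     28647     2.197113      5.572415
#> 2 GENE0004 300000  450000    41693    104175     3.294917      7.912778
#> 3 GENE0002 610000  800000   113037     24333     2.283999     20.422172
#> 4 GENE0006 880000 1040000    18343     70479     4.414204      9.565746
```

Each row is one gene unit `[left, right)`: `ext_left`/`ext_right` are the
flank lengths in bp and `cum_srr_*` the cumulative SRR attained when the
walk stopped (always ≥ 2, overshooting when a hotspot bin is crossed).
GENE0008 gained only a 5.4 Kb left flank — its neighbourhood recombines
hard — while GENE0002 reached 113 Kb leftwards through a recombination
desert. Summaries and the comparison with the fixed rule:

```r
extension_length_summary(units)
#> 16 extensions: median 34.4 Kb (IQR = 21.6-61.1 Kb)
boundary_concordance(units, build_gene_units(genes, method = "fixed"))
#> boundary concordance (+/- 10000 bp, 8 genes): 31.2% per extension, 12.5% per gene
srr_histogram(map)
#> SRR distribution over 250 bins
#>   SRR = 0        : 44.0%
#>   SRR < 1        : 78.0%
#>   SRR >= 2       : 14.4%
```

Most boundaries disagree with the ± 50 Kb rule by more than 10 Kb — the
point of the method. Evaluation helpers compare definitions against expert
locus lists; e.g. an exact one-tailed Fisher test on 17/18 vs 6/18 fully
concordant loci:

```r
fisher_exact_one_tailed(matrix(c(17, 1, 6, 12), 2, byrow = TRUE), "row1_higher")
#> [1] 0.000148313
```

A thin command-line front end lives at `inst/scripts/genedist.R`
(subcommands `extend`, `srr`, `stats`, `compare`, `overlap`, `fisher`,
`simulate`).

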