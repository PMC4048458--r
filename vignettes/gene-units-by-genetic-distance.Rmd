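---
title: "Defining gene units by genetic distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining gene units by genetic distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedist)
```

## The problem

Gene- and pathway-based association methods (VEGAS-style statistics,
gene-set enrichment over GWAS results, gene-level interaction scans) need an
operational definition of "the SNPs belonging to a gene". The gene body
alone is too narrow: flanking SNPs tag untyped coding variation through
linkage disequilibrium (LD) and often sit in cis-regulatory sequence. The
customary fix is a fixed physical window, most often the gene ± 50 Kb.

Physical distance is the wrong currency. LD decays with *genetic* distance,
and the exchange rate between the two varies enormously along the genome:
most recombination concentrates in narrow hotspots, while megabase-long
stretches recombine hardly at all. A fixed 50 Kb window therefore reaches
much too far across a hotspot and not nearly far enough through a
recombination desert.

## The unit definition

`genedist` builds gene units from a recombination map laid out on a
fixed-width genome grid (10 Kb bins by default), in three steps.

**Standardization.** Each bin's sex-averaged rate (cM/Mb) is divided by the
unweighted genome-wide mean over all bins present in the map, zeros
included. The result, the standardized recombination rate (SRR), is
unitless, has mean exactly 1 over covered bins, and is invariant to
rescaling all rates — so maps reported in different units standardize to
the same SRR. Missing bins are excluded from the mean; because every bin
has equal width, the unweighted mean equals the length-weighted one.

**Cumulative-SRR extension.** For each gene and each side independently,
the walk starts at the bin containing the first base beyond the gene
boundary and moves outward, summing SRR, until the cumulative sum reaches
the threshold (default 2). The unit boundary is the stopping bin's outer
edge. Details that matter:

* Bins entirely inside the gene body are never counted; the first counted
  bin counts in full even when it partially overlaps the gene. An extension
  can therefore be shorter than one bin width (gene ends just inside a
  high-SRR bin).
* A boundary exactly on a bin edge starts the walk at the next full bin
  outward — the natural reading under half-open coordinates.
* The stop rule is inclusive (cumulative SRR ≥ threshold; the threshold may
  be overshot) and is applied with a 1e-9 tolerance, because
  standardization of a uniform map can leave SRR at 1 ± 1 ulp and the
  exact-threshold case must still stop on the exact bin. On a uniform map
  (SRR = 1 everywhere) a grid-aligned gene is thus extended by exactly
  `ceil(threshold) × bin_width` on each side — the closed form the test
  suite checks.
* Strand is recorded but ignored: the procedure is symmetric in genomic
  left/right, so 5′/3′ labels never change a boundary.

**Telomere/centromere fallback.** Where the walk meets the end of map
coverage — or an interior coverage gap, which is treated the same way —
before reaching the threshold, the side is flagged and its extension
replaced by the median length of all completed extensions on that
chromosome (both sides pooled, quartile-free plain median), with the
boundary recomputed from the gene edge and clipped at coordinate 0. A
chromosome with no completed extension at all borrows the genome-wide
median, with a warning.

The threshold default of 2 is deliberately a plain integer: it was chosen
(in the literature this package implements) so that the genome-wide median
extension lands near the customary 50 Kb, which makes the genetic-distance
and fixed-distance definitions directly comparable — the comparison then
isolates the *reallocation* of flanking sequence, not a change in overall
genome coverage. No finer optimization of the threshold is attempted here
for the same reason.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `srr_threshold` | 2 | unitless | cumulative SRR at which a side stops |
| `fixed_distance` | 50,000 | bp | comparator window |
| `bin_width` | 10,000 | bp | map grid; must match the map file |
| `tolerance` (concordance) | 10,000 | bp | boundary-agreement window |

Raising `srr_threshold` never shortens a completed extension
(monotonicity); multiplying all raw rates by a constant changes nothing
(scale invariance). Both are enforced as property tests over randomized
maps.

## Coordinate conventions and degenerate inputs

All internal coordinates are 0-based half-open; readers convert 1-based
dialects at the boundary (`one_based = TRUE`). Half-openness resolves every
tie: a unit touching a region boundary does not overlap it, and a SNP at
`right` is outside the unit. Validation rejects negative rates, misaligned
or overlapping bins, duplicate bins, and degenerate (`start >= end`) genes.
One short terminal bin per chromosome is accepted, with its true end used
as a right-side stopping edge. Transcript-level catalogues are collapsed to
one record per gene symbol by union span; the same symbol on two
chromosomes is split with `_chrN` suffixes rather than silently merged.
The transcript span (txStart–txEnd) is what gets extended; CDS structure is
not modeled.

## Evaluation machinery

Two definitions are compared the way expert locus analyses are reported:

* **Region overlap** — a gene counts for an association region if any part
  of its unit overlaps the region. `locus_scorecard()` tallies extra and
  missing genes against an expert list per locus; a locus is *fully
  concordant* when both counts are zero.
* **SNP containment** — a nominated candidate gene is captured when its
  unit contains the top SNP. `snp_scorecard()` tallies misses;
  `paired_miss_table()` builds the 2×2 comparison after excluding
  candidates missed by both definitions, which carry no information about
  the *difference* between them. (This exclusion is an interpretive choice:
  the comparison asks which definition loses more candidates *beyond the
  common failures*.)
* **One-tailed Fisher exact** — `fisher_exact_one_tailed()` computes the
  exact hypergeometric tail with fixed margins via `stats::phyper`;
  a brute-force enumeration over all fixed-margin tables serves as the
  oracle in the test suite, exact for every table with total ≤ 12.
* **Distribution summaries** — pooled 5′/3′ extension lengths (median and
  IQR by linear interpolation of order statistics, `quantile` type 7, a
  convention stated here because small samples make the quartile rule
  visible) and boundary concordance within ± 10 Kb, per extension and per
  gene.

## What the synthetic generator emulates — and what it does not

`simulate_map()` draws per-bin rates from a zero-inflated gamma: a point
mass at zero (default 0.426) and `Gamma(shape = 0.295, scale = 6.673)`
otherwise, with optional Poisson-placed hotspot bins and telomere/
centromere coverage gaps. The defaults are moment-matched to the three
genome-wide SRR mass points of the human sex-averaged map (≈ 42.6% of bins
at SRR = 0, ≈ 78.4% below 1, ≈ 12.9% at or above 2). The zero mass is
matched exactly; one free shape parameter cannot satisfy both remaining
constraints simultaneously, and the least-squares compromise yields about
79.0% below 1 and 14.2% at or above 2. The default scale sets the genome
mean near 1.13 cM/Mb, though SRR is insensitive to it.

What the generator deliberately does **not** reproduce: spatial
autocorrelation of rates (real hotspots cluster and deserts run long, which
lengthens the upper tail of extension lengths), hotspot sequence motifs,
sex differences, and inter-population differences in map structure. Passing
tests on simulated maps therefore demonstrate the *algorithmic* properties
of the method — correct walking, fallback handling, parameter recovery —
not that any particular empirical median (e.g. ≈ 45 Kb on the human map)
will be reproduced; with independent bins the simulated median extension
comes out somewhat shorter and the concordance fractions differ from the
human values.

`simulate_genes()` places log-normal gene bodies (median ≈ 20 Kb,
`sdlog = 0.9` — a serviceable approximation of human transcript spans)
uniformly in covered spans with a minimum gap, by rejection sampling; an
infeasible packing request fails with the constraint named.

## Encoded evaluation fixtures

Two fixtures encode published locus-evaluation tables row by row as
geometric micro-scenarios (`make_fixture("wtccc-table1")`,
`make_fixture("rbc-table2")`): each locus or SNP sits on its own
pseudo-chromosome, expert or candidate genes get unit intervals whose
overlap/containment status encodes the printed outcome, and the package's
own scorecard and Fisher machinery must regenerate the printed totals (107
expert genes with +7 vs +26 extras; 4 vs 10 missed candidates with 3
shared) and tail probabilities (1.48e-4 and 0.028). These fixtures test the
evaluation pipeline end to end without any external download; they are
synthetic encodings of printed tables, not the original genomic
coordinates.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data:
property suites use 1,000 randomized maps of 12–40 bins; simulation
recovery uses 100,000 bins; the end-to-end consistency check uses a
10-chromosome, 94,000-bin genome with 1,500 genes — sizes chosen so the
full suite completes in well under a minute per suite while leaving the
binomial sampling bounds meaningful. The per-gene walk is vectorized over
each chromosome slice; exact rational comparisons in tests use a 1e-12
relative tolerance against enumeration, comfortably above `phyper`'s
accuracy.

## Known limitations

* The definitions depend on the map's population: a European-ancestry map
  yields European-ancestry units. Other populations need their own maps.
* Assembly conversion is out of scope; inputs must share one assembly
  (users should lift over SNP data externally rather than the map).
* Interior map gaps are treated identically to telomere/centromere gaps
  (median fallback); if a map had large mid-arm holes the fallback fraction
  would rise accordingly.
* The 17q21 inversion-type loci, where exceptional LD breaks the
  recombination-distance logic, should be excluded by the user; the package
  provides no special handling.
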