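# Hand-constructed micro-scenarios with analytically known outputs, used by
# the test-suite and by the acceptance script. Each fixture returns the
# inputs the pipeline needs plus the expected outputs it must regenerate.

#' Built-in test and evaluation fixtures
#'
#' @description
#' Returns a named bundle of inputs and analytically known expected outputs:
#'
#' * `"uniform"` — a one-chromosome map with all rates equal (so SRR = 1
#'   everywhere) and grid-aligned genes; every extension must be exactly
#'   `srr_threshold * bin_width` = 20 Kb at the defaults.
#' * `"staircase"` — a map with hand-chosen rates whose mean is exactly 1,
#'   so SRR equals the raw rates; the gene's outward prefix sums are known
#'   by hand (right: 0.5, 0.5, 0.9, 0.2 stopping at the fourth bin with
#'   cumulative 2.1; left: a single 2.5 bin).
#' * `"gap-fallback"` — a map whose coverage ends two low-SRR bins to the
#'   right of one gene, triggering the per-chromosome median fallback; the
#'   other genes complete normally and determine the median.
#' * `"wtccc-table1"` — 18 labeled association regions with expert gene
#'   lists (107 genes in total) and two hand-built unit sets under which the
#'   overlap rule yields 7 extra genes for the genetic-distance definition
#'   (all in one gene-dense, low-recombination locus) and 26 for the
#'   +/- 50 Kb definition, the counts of the corresponding published
#'   evaluation; the fully-concordant-locus table is [[17,1],[6,12]].
#' * `"rbc-table2"` — 31 top SNPs carrying 43 nominated functional
#'   candidate genes and two hand-built unit sets under which the
#'   SNP-containment rule misses 4 candidates (genetic-distance definition)
#'   and 10 (+/- 50 Kb), 3 of them shared; the paired miss table after
#'   excluding shared misses is [[1,39],[7,33]].
#'
#' @param name one of the registered scenario names.
#' @return list with elements among `map`, `genes`, `params`, `regions`,
#'   `snps`, `defs` (named list of unit tables) and `expected`.
#' @export
make_fixture <- function(name) {
  registry <- c("uniform", "staircase", "gap-fallback", "wtccc-table1",
                "rbc-table2")
  if (!is.character(name) || length(name) != 1L || !name %in% registry) {
    stop_("unknown fixture %s; registry: %s",
          paste(name, collapse = ","), paste(registry, collapse = ", "))
  }
  switch(name,
         "uniform" = fixture_uniform(),
         "staircase" = fixture_staircase(),
         "gap-fallback" = fixture_gap_fallback(),
         "wtccc-table1" = fixture_wtccc_table1(),
         "rbc-table2" = fixture_rbc_table2())
}

fixture_uniform <- function() {
  w <- 10000
  bins <- data.frame(chrom = "chr1", start = seq(0, 990000, w),
                     end = seq(w, 1000000, w), rate = 1.0)
  map <- standardize_map(recombination_map(bins, bin_width = w))
  genes <- gene_records(c("GU1", "GU2", "GU3"), "chr1", "+",
                        start = c(100000, 400000, 700000),
                        end = c(200000, 430000, 790000))
  list(map = map, genes = genes, params = extension_params(),
       expected = list(ext = 20000, cum = 2.0))
}

fixture_staircase <- function() {
  w <- 10000
  starts <- seq(0, 390000, w)
  rate <- rep(1.016, 40)                       # filler keeps the mean at 1
  rate[10:20] <- c(2.5, rep(1, 10))            # [90000,100000) left walk bin
  rate[21:24] <- c(0.5, 0.5, 0.9, 0.2)         # right walk from 200000
  rate[11:20] <- 1                             # inside gene body, never counted
  # enforce mean exactly 1: adjust filler bins
  filler <- setdiff(seq_along(rate), c(10:24))
  rate[filler] <- (40 - sum(rate[-filler])) / length(filler)
  bins <- data.frame(chrom = "chr1", start = starts, end = starts + w,
                     rate = rate)
  map <- standardize_map(recombination_map(bins, bin_width = w))
  genes <- gene_records("GS1", "chr1", "+", start = 100000, end = 200000)
  list(map = map, genes = genes, params = extension_params(),
       expected = list(ext_left = 10000, cum_left = 2.5,
                       ext_right = 40000, cum_right = 2.1))
}

fixture_gap_fallback <- function() {
  w <- 10000
  # coverage [0, 300000) only; rates mostly 1 so completed extensions are
  # 20 Kb, and the right walk of GF3 meets the gap after two 0.1-SRR bins.
  starts <- seq(0, 290000, w)
  rate <- rep(1, 30)
  rate[29:30] <- 0.1                # [280000,300000): GF3's truncated walk
  bins <- data.frame(chrom = "chr1", start = starts, end = starts + w,
                     rate = rate)
  map <- standardize_map(recombination_map(bins, bin_width = w))
  genes <- gene_records(c("GF1", "GF2", "GF3"), "chr1", "+",
                        start = c(60000, 150000, 260000),
                        end = c(100000, 190000, 280000))
  list(map = map, genes = genes, params = extension_params(),
       expected = list(fallback_gene = "GF3", fallback_side = "right"))
}

# --- encoded published evaluation rows --------------------------------------

# 18 association loci: expert gene count, extras under each definition.
wtccc_table1_rows <- function() {
  data.frame(
    locus = c("5p13-CD", "10q24-CD", "10q25-T2D", "9p21-CAD", "10q21-CD",
              "16q12-CD", "16q12-T2D", "5q33-CD", "1p13-RA", "1p13-T1D",
              "16p13-T1D", "16p12-BD", "1p31-CD", "2q37-CD", "18p11-CD",
              "12q24-T1D", "12q13-T1D", "3p21-CD"),
    n_expert = c(0L, 1L, 1L, 2L, 3L, 4L, 1L, 2L, 7L, 7L, 8L, 9L, 1L, 1L,
                 1L, 15L, 26L, 18L),
    extra_srr = c(rep(0L, 17), 7L),
    extra_fixed = c(rep(0L, 6), 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L,
                    3L, 9L),
    stringsAsFactors = FALSE)
}

# Construct the table-1 scenario geometrically: each locus sits on its own
# pseudo-chromosome with the region at [1e6, 2e6). Expert genes lie inside
# the region under both definitions. An extra gene under one definition has
# its body outside the region but that definition's extension reaching in.
fixture_wtccc_table1 <- function() {
  rows <- wtccc_table1_rows()
  regions <- data.frame(locus = rows$locus,
                        chrom = paste0("L", seq_len(nrow(rows))),
                        start = 1e6, end = 2e6, stringsAsFactors = FALSE)
  srr_units <- list()
  fixed_units <- list()
  expert <- vector("list", nrow(rows))
  mk <- function(name, chrom, gs, ge, left, right, method) {
    unit_row(list(name = name, chrom = chrom, strand = "+",
                  start = gs, end = ge),
             left, right, method,
             ext_left = gs - left, ext_right = right - ge)
  }
  for (i in seq_len(nrow(rows))) {
    ch <- regions$chrom[i]
    # expert genes: bodies inside the region, modest extensions either way
    if (rows$n_expert[i] > 0) {
      nm <- sprintf("%s_G%02d", rows$locus[i], seq_len(rows$n_expert[i]))
      gs <- 1e6 + 20000 * seq_len(rows$n_expert[i])
      for (j in seq_along(nm)) {
        srr_units[[length(srr_units) + 1L]] <-
          mk(nm[j], ch, gs[j], gs[j] + 10000, gs[j] - 10000, gs[j] + 20000, "srr")
        fixed_units[[length(fixed_units) + 1L]] <-
          mk(nm[j], ch, gs[j], gs[j] + 10000, gs[j] - 50000, gs[j] + 60000, "fixed")
      }
      expert[[i]] <- nm
    } else expert[[i]] <- character()
    # extras under the SRR rule: bodies ~60 Kb left of the region edge in a
    # low-recombination stretch, so the 80 Kb genetic-distance extension
    # reaches into the region while the 50 Kb one falls short
    if (rows$extra_srr[i] > 0) {
      for (j in seq_len(rows$extra_srr[i])) {
        ge <- 1e6 - 60000 - 2000 * (j - 1)
        nm <- sprintf("%s_XS%02d", rows$locus[i], j)
        srr_units[[length(srr_units) + 1L]] <-
          mk(nm, ch, ge - 10000, ge, ge - 90000, ge + 80000, "srr")
        fixed_units[[length(fixed_units) + 1L]] <-
          mk(nm, ch, ge - 10000, ge, ge - 60000, ge + 50000, "fixed")
      }
    }
    # extras under the 50 Kb rule: bodies ~30 Kb left of the region edge
    # next to a hotspot, so the genetic-distance extension stops at 5 Kb
    # while the 50 Kb one reaches in
    if (rows$extra_fixed[i] > 0) {
      for (j in seq_len(rows$extra_fixed[i])) {
        ge <- 1e6 - 30000 - 2000 * (j - 1)
        nm <- sprintf("%s_XF%02d", rows$locus[i], j)
        srr_units[[length(srr_units) + 1L]] <-
          mk(nm, ch, ge - 10000, ge, ge - 15000, ge + 5000, "srr")
        fixed_units[[length(fixed_units) + 1L]] <-
          mk(nm, ch, ge - 10000, ge, ge - 60000, ge + 50000, "fixed")
      }
    }
  }
  regions$expert_genes <- expert
  defs <- list(srr = do.call(rbind, srr_units),
               fixed = do.call(rbind, fixed_units))
  list(regions = regions, defs = defs,
       expected = list(n_expert = 107L, extra_srr = 7L, extra_fixed = 26L,
                       concordance_table = matrix(c(17L, 1L, 6L, 12L), 2,
                                                  byrow = TRUE),
                       fisher_p = 342720 / 2310789600))
}

# 31 rows of the candidate-gene evaluation: top SNP per locus/criterion,
# nominated candidates, and which definition missed which candidate.
rbc_table2_rows <- function() {
  row <- function(locus, criterion, cand, miss_srr = "", miss_fixed = "") {
    data.frame(locus = locus, criterion = criterion, candidates = cand,
               miss_srr = miss_srr, miss_fixed = miss_fixed,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("1q23-MCHC", "nsSNP", "OR6Y1,OR10Z1,SPTA1", "", "OR6Y1"),
    row("1q44-RBC", "nsSNP", "TRIM58"),
    row("6p21-MCH", "nsSNP", "HFE", "HFE", "HFE"),
    row("6p21-RBC", "nsSNP", "HLA-DQA1"),
    row("10q11-MCV", "nsSNP", "MARCH8"),
    row("11q13-MCV", "nsSNP", "RPS6KB2"),
    row("11q13-HB", "nsSNP", "ARHGEF17"),
    row("12q24-HB", "nsSNP", "SH2B3"),
    row("12q24-MCV", "nsSNP", "ACADS"),
    row("16q22-RBC", "nsSNP", "CTRL,PSMB10", "", "CTRL,PSMB10"),
    row("19p13-MCV", "nsSNP", "UBXD1,NUDT19", "UBXD1", "UBXD1"),
    row("22q11-MCV", "nsSNP", "YDJC", "YDJC", ""),
    row("22q12-MCH", "nsSNP", "FBXO7,TMPRSS6"),
    row("4q27-MCV", "eQTL", "CCNA2"),
    row("6p23-MCH", "eQTL", "GMPR"),
    row("6p21-RBC2", "eQTL", "HLA-DQA1,HLA-DQA2", "HLA-DQA2", "HLA-DQA2"),
    row("8p11-MCHC", "eQTL", "C8orf40"),
    row("10q11-MCV2", "eQTL", "MARCH8"),
    row("11p15-HB", "eQTL", "AKIP1,C11orf16,NRIP3", "", "NRIP3"),
    row("11q13-MCV2", "eQTL", "RPS6KB2,PTPRCAP,COROB1"),
    row("11q13-HB2", "eQTL", "ARHGEF17"),
    row("15q22-MCV", "eQTL", "PTPLAD1", "", "PTPLAD1"),
    row("15q25-MCHC", "eQTL", "DNAJA4"),
    row("16q22-RBC2", "eQTL", "DUS2L", "", "DUS2L"),
    row("17q11-MCH", "eQTL", "ERAL1,TRAF4", "", "ERAL1"),
    row("17q12-RBC", "eQTL", "CDK12"),
    row("17q25-HB", "eQTL", "PGS1"),
    row("18q21-MCH", "eQTL", "C18orf25"),
    row("19p13-MCH", "eQTL", "CALR,FARSA"),
    row("22q11-MCV2", "eQTL", "UBE2L3"),
    row("22q13-MCV", "eQTL", "ECGF1")
  )
}

# Geometric encoding: one pseudo-chromosome per row, SNP at 1e6. The gene
# body position encodes the row's outcome; both definitions extend the same
# body (the fixed one by exactly 50 Kb, the genetic-distance one by a short
# or a long extension as recombination would dictate):
#   included by both  — body over the SNP itself;
#   missed by both    — body 200 Kb out, short SRR extension;
#   missed by fixed   — body 100 Kb out, low recombination gives the SRR
#                       rule a 110 Kb reach while 50 Kb falls short;
#   missed by SRR     — body 30 Kb out, a hotspot keeps the SRR extension
#                       at 5 Kb while 50 Kb reaches the SNP.
fixture_rbc_table2 <- function() {
  rows <- rbc_table2_rows()
  snps <- data.frame(rsid = sprintf("rs%04d", seq_len(nrow(rows))),
                     chrom = paste0("S", seq_len(nrow(rows))),
                     pos = 1e6, stringsAsFactors = FALSE)
  snps$candidate_genes <- strsplit(rows$candidates, ",", fixed = TRUE)
  srr_units <- list()
  fixed_units <- list()
  mk <- function(name, chrom, gs, ge, left, right, method) {
    unit_row(list(name = name, chrom = chrom, strand = "+",
                  start = gs, end = ge),
             left, right, method,
             ext_left = gs - left, ext_right = right - ge)
  }
  for (i in seq_len(nrow(rows))) {
    ch <- snps$chrom[i]
    cands <- snps$candidate_genes[[i]]
    ms <- strsplit(rows$miss_srr[i], ",", fixed = TRUE)[[1]]
    mf <- strsplit(rows$miss_fixed[i], ",", fixed = TRUE)[[1]]
    for (j in seq_along(cands)) {
      g <- cands[j]
      jitter <- 3000 * (j - 1)         # distinct, possibly overlapping bodies
      gs <- if (g %in% ms && g %in% mf) 1.2e6 + 30000 * (j - 1)
        else if (g %in% mf) 1.1e6 + jitter
        else if (g %in% ms) 1.03e6 + jitter
        else 990000 + jitter           # body over the SNP position
      ge <- gs + 20000
      srr_ext <- if (g %in% ms) 5000 else 110000
      srr_units[[length(srr_units) + 1L]] <-
        mk(g, ch, gs, ge, max(0, gs - srr_ext), ge + srr_ext, "srr")
      fixed_units[[length(fixed_units) + 1L]] <-
        mk(g, ch, gs, ge, max(0, gs - 50000), ge + 50000, "fixed")
    }
  }
  defs <- list(srr = do.call(rbind, srr_units),
               fixed = do.call(rbind, fixed_units))
  list(snps = snps, defs = defs, rows = rows,
       expected = list(n_candidates = 43L, missed_srr = 4L,
                       missed_fixed = 10L, n_shared = 3L,
                       miss_table = matrix(c(1L, 39L, 7L, 33L), 2,
                                           byrow = TRUE),
                       fisher_p = 0.02837934))
}
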