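# Evaluation machinery: length summaries, concordance, overlap rules,
# scorecards, and the one-tailed Fisher exact test.

mk_unit <- function(name, chrom, gs, ge, left, right, method = "srr") {
  u <- extend_gene_fixed(gene_records(name, chrom, "+", gs, ge)[1, ],
                         extension_params(fixed_distance = 0))
  u$method <- method
  u$left <- left; u$right <- right
  u$ext_left <- gs - left; u$ext_right <- right - ge
  u
}

units_from_ext <- function(ext_kb) {
  # one gene per pair of pooled extensions
  stopifnot(length(ext_kb) %% 2 == 0)
  do.call(rbind, lapply(seq_len(length(ext_kb) / 2), function(i) {
    el <- ext_kb[2 * i - 1] * 1000
    er <- ext_kb[2 * i] * 1000
    gs <- 1e6 * i
    mk_unit(paste0("G", i), "chr1", gs, gs + 1e4, gs - el, gs + 1e4 + er)
  }))
}

test_that("extension lengths summarize with interpolated quartiles", {
  s <- extension_length_summary(units_from_ext(c(10, 20, 30, 40)))
  expect_equal(s$median, 25)
  expect_equal(s$iqr_low, 17.5)
  expect_equal(s$iqr_high, 32.5)
  s2 <- extension_length_summary(units_from_ext(rep(30, 6)))
  expect_equal(s2$iqr_high - s2$iqr_low, 0)
  expect_error(extension_length_summary(units_from_ext(c(1, 2))[0, ]), "no units")
  mixed <- rbind(units_from_ext(c(1, 2)),
                 {u <- units_from_ext(c(1, 2)); u$method <- "fixed"; u})
  expect_error(extension_length_summary(mixed), "mix")
})

test_that("cutoff fractions are strict tails", {
  s <- extension_length_summary(units_from_ext(c(5, 10, 20, 600)),
                                cutoffs = c(10, 500))
  expect_equal(unname(s$fraction_below["<10Kb"]), 0.25)
  expect_equal(unname(s$fraction_above[">500Kb"]), 0.25)
})

test_that("boundary concordance counts per extension and per gene", {
  a <- units_from_ext(c(10, 20, 30, 40))
  expect_equal(boundary_concordance(a, a)$fraction_per_extension, 1)
  expect_equal(boundary_concordance(a, a)$fraction_per_gene, 1)
  b <- a
  b$left <- b$left - 20000
  b$right <- b$right + 20000
  cc <- boundary_concordance(a, b, tolerance = 10000)
  expect_equal(cc$fraction_per_extension, 0)
  expect_equal(cc$fraction_per_gene, 0)
  # one concordant side per gene
  b2 <- a
  b2$left <- b2$left - 20000
  cc2 <- boundary_concordance(a, b2, tolerance = 10000)
  expect_equal(cc2$fraction_per_extension, 0.5)
  expect_equal(cc2$fraction_per_gene, 0)
  # unmatched genes are excluded with a warning
  expect_warning(cc3 <- boundary_concordance(a, b[1, ]), "excluded")
  expect_equal(cc3$n_genes, 1L)
})

test_that("region overlap is any-part, half-open", {
  u <- mk_unit("G", "chr1", 60, 120, 50, 150)
  region <- list(locus = "L", chrom = "chr1", start = 100, end = 200)
  expect_equal(genes_overlapping_region(u, region), "G")
  u2 <- mk_unit("G", "chr1", 10, 90, 0, 100)     # touches the boundary
  expect_equal(genes_overlapping_region(u2, region), character(0))
  expect_equal(genes_overlapping_region(u, list(chrom = "chr2", start = 0,
                                                end = 1e9)), character(0))
})

test_that("position containment is half-open and returns all overlapping units", {
  u <- rbind(mk_unit("A", "chr1", 90000, 110000, 50000, 250000),
             mk_unit("B", "chr1", 95000, 105000, 60000, 240000))
  expect_equal(genes_containing_position(u, list(chrom = "chr1", pos = 100000)),
               c("A", "B"))
  expect_equal(genes_containing_position(u[1, ], list(chrom = "chr1",
                                                      pos = 250000)),
               character(0))   # pos == right boundary is outside
  expect_equal(genes_containing_position(u[1, ], list(chrom = "chr1",
                                                      pos = 50000)), "A")
})

test_that("containment implies region overlap for regions holding the position", {
  set.seed(7)
  for (i in 1:30) {
    u <- units_from_ext(sample(5:100, 6) / 1)
    pos <- sample(5e5:4e6, 1)
    inside <- genes_containing_position(u, list(chrom = "chr1", pos = pos))
    region <- list(chrom = "chr1", start = pos - sample(0:1e5, 1),
                   end = pos + sample(1:1e5, 1))
    overlapping <- genes_overlapping_region(u, region)
    expect_true(all(inside %in% overlapping))
  }
})

test_that("locus scorecards count extra and missing genes", {
  u <- rbind(mk_unit("A", "chr1", 1100, 1200, 1000, 1300),
             mk_unit("B", "chr1", 1400, 1500, 1350, 1600),
             mk_unit("C", "chr1", 1700, 1800, 1650, 1900))
  regions <- data.frame(locus = "L1", chrom = "chr1", start = 1000, end = 2000)
  regions$expert_genes <- list(c("A", "B"))
  sc <- locus_scorecard(list(m = u), regions)
  expect_equal(sc$n_extra, 1L)       # C
  expect_equal(sc$n_missing, 0L)
  regions$expert_genes <- list(c("A", "Z"))
  sc2 <- locus_scorecard(list(m = u), regions)
  expect_equal(sc2$n_extra, 2L)
  expect_equal(sc2$missing_genes, "Z")
})

test_that("the encoded locus-evaluation fixture reproduces its totals", {
  fx <- make_fixture("wtccc-table1")
  sc <- locus_scorecard(fx$defs, fx$regions)
  tot <- scorecard_totals(sc)
  expect_equal(tot$n_expert[tot$method == "srr"], 107L)
  expect_equal(tot$n_extra[tot$method == "srr"], 7L)
  expect_equal(tot$n_extra[tot$method == "fixed"], 26L)
  expect_equal(tot$n_missing, c(0L, 0L))
  expect_equal(scorecard_concordance_table(sc, c("srr", "fixed")),
               fx$expected$concordance_table, ignore_attr = TRUE)
})

test_that("the encoded candidate-gene fixture reproduces its misses", {
  fx <- make_fixture("rbc-table2")
  sc <- snp_scorecard(fx$defs, fx$snps)
  agg <- tapply(sc$n_missed, sc$method, sum)
  expect_equal(unname(agg["srr"]), 4L)
  expect_equal(unname(agg["fixed"]), 10L)
  expect_equal(sum(sc$n_candidates[sc$method == "srr"]), 43L)
})

test_that("one-tailed Fisher matches brute-force enumeration on all small tables", {
  for (n in 1:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      for (dir in c("row1_lower", "row1_higher")) {
        p <- suppressWarnings(fisher_exact_one_tailed(c(a, b, cc, d), dir))
        if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) {
          expect_equal(p, 1)
        } else {
          expect_equal(p, brute_fisher(a, b, cc, d, dir), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("Fisher symmetry: swapping rows flips the tested tail", {
  set.seed(3)
  for (i in 1:25) {
    t <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact_one_tailed(t, "row1_lower"),
                 fisher_exact_one_tailed(t[2:1, ], "row1_higher"),
                 tolerance = 1e-12)
  }
})

test_that("Fisher probabilities are in (0, 1] and extreme tails give 1", {
  # observed cell at the opposite extreme of the tested tail
  expect_equal(fisher_exact_one_tailed(c(5, 0, 0, 5), "row1_lower"), 1)
  expect_equal(fisher_exact_one_tailed(c(0, 5, 5, 0), "row1_higher"), 1)
  expect_equal(fisher_exact_one_tailed(c(0, 1, 1, 0), "row1_lower"), 0.5)
  expect_warning(p <- fisher_exact_one_tailed(c(0, 0, 3, 4), "row1_lower"),
                 "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact_one_tailed(c(-1, 1, 1, 1)), "non-negative")
  expect_error(fisher_exact_one_tailed(c(0, 0, 0, 0)), "no observations")
  set.seed(9)
  for (i in 1:20) {
    t <- matrix(rpois(4, 3), 2)
    p <- suppressWarnings(fisher_exact_one_tailed(t, "row1_higher"))
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("one-tailed Fisher agrees with stats::fisher.test on random tables", {
  set.seed(17)
  for (i in 1:25) {
    t <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(fisher_exact_one_tailed(t, "row1_lower"),
                 stats::fisher.test(t, alternative = "less")$p.value,
                 tolerance = 1e-10)
    expect_equal(fisher_exact_one_tailed(t, "row1_higher"),
                 stats::fisher.test(t, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("paired miss tables exclude shared misses from both margins", {
  miss_a <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  miss_b <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  tab <- paired_miss_table(miss_a, miss_b)
  expect_equal(attr(tab, "n_shared"), 2L)
  expect_equal(unname(tab[1, ]), c(0L, 3L))
  expect_equal(unname(tab[2, ]), c(2L, 1L))
})

test_that("region and SNP files read with expert and candidate lists", {
  rp <- tempfile(); ep <- tempfile(); sp <- tempfile()
  writeLines(c("chr1\t1000\t2000\tlocusA", "chr2\t5000\t9000\tlocusB"), rp)
  writeLines("locusA\tG1,G2", ep)
  writeLines(c("chr1\t1500\trs1\tG1,G2", "chr2\t6000\trs2"), sp)
  regions <- read_regions(rp, ep)
  expect_equal(regions$expert_genes[[1]], c("G1", "G2"))
  expect_equal(regions$expert_genes[[2]], character(0))
  snps <- read_snps(sp)
  expect_equal(snps$pos, c(1500, 6000))
  expect_equal(snps$candidate_genes[[1]], c("G1", "G2"))
  expect_equal(snps$candidate_genes[[2]], character(0))
})
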