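# The cumulative-SRR extension walk, the fixed-distance comparator, the
# median fallback, and the definition-file writer.

test_that("a uniform map extends every grid-aligned gene by threshold x bin width", {
  fx <- make_fixture("uniform")
  u <- build_gene_units(fx$genes, fx$map, fx$params, method = "srr")
  expect_equal(u$ext_left, rep(20000, 3))
  expect_equal(u$ext_right, rep(20000, 3))
  expect_equal(u$cum_srr_left, rep(2, 3))
  expect_false(any(u$fallback_left | u$fallback_right))
})

test_that("the staircase map stops at the hand-summed bins", {
  fx <- make_fixture("staircase")
  u <- build_gene_units(fx$genes, fx$map, fx$params, method = "srr")
  expect_equal(u$ext_left, fx$expected$ext_left)
  expect_equal(u$ext_right, fx$expected$ext_right)
  expect_equal(u$cum_srr_left, fx$expected$cum_left, tolerance = 1e-9)
  expect_equal(u$cum_srr_right, fx$expected$cum_right, tolerance = 1e-9)
})

test_that("a gene boundary inside a bin can yield an extension below one bin width", {
  # 20 bins, mean rate exactly 1; the bin [100000,110000) holds SRR 5
  rates <- rep(15 / 19, 20)
  rates[11] <- 5
  map <- tiny_map(rates)
  g <- gene_records("G", "chr1", "+", 50000, 105000)
  u <- extend_gene_srr(g[1, ], map)
  expect_equal(u$right, 110000)
  expect_equal(u$ext_right, 5000)
  expect_equal(u$cum_srr_right, 5)
})

test_that("a boundary exactly on a bin edge starts at the next full bin outward", {
  map <- tiny_map(rep(1, 30))
  g <- gene_records("G", "chr1", "+", 100000, 200000)
  u <- extend_gene_srr(g[1, ], map)
  # right walk starts at [200000,210000), left walk at [90000,100000)
  expect_equal(u$right, 220000)
  expect_equal(u$left, 80000)
})

test_that("bins inside the gene body are never counted", {
  # huge SRR inside the gene must not shorten the extension
  rates <- rep(15 / 19, 20)
  rates[11] <- 5                     # inside the body below
  map <- tiny_map(rates)
  g <- gene_records("G", "chr1", "+", 100000, 120000)
  u <- extend_gene_srr(g[1, ], map)
  expect_gt(u$ext_right, 10000)      # did not stop on the internal hotspot
  # left walk needs three 15/19-SRR bins to pass 2
  expect_equal(u$ext_left, 30000)
  expect_equal(u$cum_srr_left, 45 / 19, tolerance = 1e-9)
})

test_that("coverage gaps and map edges trigger the fallback flag", {
  fx <- make_fixture("gap-fallback")
  raw <- do.call(rbind, lapply(seq_len(nrow(fx$genes)), function(i) {
    extend_gene_srr(fx$genes[i, ], fx$map, fx$params)
  }))
  expect_true(raw$fallback_right[raw$name == "GF3"])
  expect_false(any(raw$fallback_left))
  # after the median fallback the flagged side gets the chromosome median
  u <- apply_fallback(raw, fx$params)
  med <- stats::median(c(raw$ext_left[!raw$fallback_left],
                         raw$ext_right[!raw$fallback_right]))
  expect_equal(u$ext_right[u$name == "GF3"], med)
  expect_true(u$fallback_right[u$name == "GF3"])
  expect_true(is.na(u$cum_srr_right[u$name == "GF3"]))
  # an interior gap (not just the chromosome end) also triggers it
  map2 <- tiny_map(c(rep(0.1, 10), NA, rep(1, 10)))
  g2 <- gene_records("G", "chr1", "+", 30000, 50000)
  u2 <- extend_gene_srr(g2[1, ], map2)
  expect_true(u2$fallback_right)
})

test_that("the fallback median pools both sides and clips at zero", {
  mk <- function(name, gs, ge, el, er, fl, fr) {
    u <- extend_gene_fixed(gene_records(name, "chr1", "+", gs, ge)[1, ])
    u$method <- "srr"
    u$left <- gs - el; u$right <- ge + er
    u$ext_left <- el; u$ext_right <- er
    u$fallback_left <- fl; u$fallback_right <- fr
    u
  }
  # completed extensions 10, 20, 30, 40 Kb -> median 25 Kb
  units <- rbind(mk("A", 1e6, 1.1e6, 10000, 20000, FALSE, FALSE),
                 mk("B", 2e6, 2.1e6, 30000, 40000, FALSE, FALSE),
                 mk("C", 3000, 3.1e6, 5000, 1000, TRUE, TRUE))
  out <- apply_fallback(units)
  expect_equal(out$ext_right[3], 25000)
  expect_equal(out$left[3], 0)          # 3 Kb from the origin, clipped
  expect_equal(out$ext_left[3], 3000)
  # no flagged sides: identity
  expect_equal(apply_fallback(units[1:2, ]), units[1:2, ])
})

test_that("a chromosome without completed extensions uses the genome median", {
  fx <- make_fixture("gap-fallback")
  raw <- do.call(rbind, lapply(seq_len(nrow(fx$genes)), function(i) {
    extend_gene_srr(fx$genes[i, ], fx$map, fx$params)
  }))
  orphan <- raw[1, ]
  orphan$chrom <- "chr9"
  orphan$fallback_left <- orphan$fallback_right <- TRUE
  expect_warning(out <- apply_fallback(rbind(raw, orphan)), "genome-wide")
  med <- stats::median(c(raw$ext_left[!raw$fallback_left],
                         raw$ext_right[!raw$fallback_right]))
  expect_equal(out$ext_right[out$chrom == "chr9"], med)
})

test_that("fixed-distance units are simple arithmetic with clipping", {
  g <- gene_records(c("A", "B", "C"), "chr1", "+",
                    start = c(100000, 20000, 5e5), end = c(200000, 60000, 6e5))
  u1 <- extend_gene_fixed(g[g$name == "A", ])
  expect_equal(c(u1$left, u1$right), c(50000, 250000))
  u2 <- extend_gene_fixed(g[g$name == "B", ])
  expect_equal(u2$left, 0)
  u3 <- extend_gene_fixed(g[g$name == "C", ], extension_params(fixed_distance = 0))
  expect_equal(c(u3$left, u3$right), c(5e5, 6e5))
  u4 <- extend_gene_fixed(g[g$name == "C", ], chrom_length = 620000)
  expect_equal(u4$right, 620000)
})

test_that("build_gene_units orders deterministically and handles edge inputs", {
  fx <- make_fixture("uniform")
  u <- build_gene_units(fx$genes, fx$map, method = "srr")
  expect_equal(u$left, sort(u$left))
  empty <- build_gene_units(fx$genes[0, ], fx$map, method = "srr")
  expect_equal(nrow(empty), 0L)
  # chromosome absent from the map: stop by default, skip on request
  g2 <- gene_records("GX", "chr7", "+", 0, 1000)
  both <- rbind(fx$genes, g2)
  class(both) <- class(fx$genes)
  expect_error(build_gene_units(both, fx$map, method = "srr"), "GX")
  expect_warning(u2 <- build_gene_units(both, fx$map, method = "srr",
                                        on_error = "skip"), "skipping")
  expect_equal(nrow(u2), 3L)
  # fixed method needs no map
  uf <- build_gene_units(fx$genes, method = "fixed")
  expect_equal(uf$ext_left, rep(50000, 3))
})

test_that("every unit contains its gene body", {
  for (seed in 1:40) {
    sc <- random_small_scenario(seed)
    u <- build_gene_units(sc$genes, sc$map, method = "srr")
    expect_true(all(u$left <= u$gene_start))
    expect_true(all(u$right >= u$gene_end))
    expect_true(all(u$left >= 0))
    expect_equal(u$ext_left, u$gene_start - u$left)
    expect_equal(u$ext_right, u$right - u$gene_end)
  }
})

test_that("raising the threshold never shortens a non-fallback extension", {
  for (seed in 41:80) {
    sc <- random_small_scenario(seed)
    us <- lapply(c(1, 2, 3.5), function(th) {
      do.call(rbind, lapply(seq_len(nrow(sc$genes)), function(i) {
        extend_gene_srr(sc$genes[i, ], sc$map,
                        extension_params(srr_threshold = th))
      }))
    })
    for (k in 1:2) {
      ok <- !us[[k]]$fallback_right & !us[[k + 1]]$fallback_right
      expect_true(all(us[[k + 1]]$ext_right[ok] >= us[[k]]$ext_right[ok]))
      ok <- !us[[k]]$fallback_left & !us[[k + 1]]$fallback_left
      expect_true(all(us[[k + 1]]$ext_left[ok] >= us[[k]]$ext_left[ok]))
    }
  }
})

test_that("rescaling all rates leaves every unit unchanged", {
  for (seed in 81:110) {
    sc <- random_small_scenario(seed)
    u1 <- build_gene_units(sc$genes, sc$map, method = "srr")
    raw <- sc$map
    raw$rate <- raw$rate * 13.7
    u2 <- build_gene_units(sc$genes, standardize_map(raw), method = "srr")
    expect_equal(u1, u2, tolerance = 1e-9)
  }
})

test_that("the walking implementation agrees with the naive prefix-sum oracle", {
  for (seed in 111:160) {
    sc <- random_small_scenario(seed)
    for (i in seq_len(nrow(sc$genes))) {
      g <- as.list(sc$genes[i, ])
      u <- extend_gene_srr(sc$genes[i, ], sc$map)
      o <- oracle_extension(g, sc$map, 2, 10000)
      expect_equal(u$fallback_right, o$right$fallback)
      expect_equal(u$fallback_left, o$left$fallback)
      if (!o$right$fallback) {
        expect_equal(u$right, o$right$boundary)
        expect_equal(u$cum_srr_right, o$right$cum, tolerance = 1e-12)
      }
      if (!o$left$fallback) {
        expect_equal(u$left, o$left$boundary)
        expect_equal(u$cum_srr_left, o$left$cum, tolerance = 1e-12)
      }
    }
  }
})

test_that("identical inputs write byte-identical definition files", {
  fx <- make_fixture("staircase")
  u <- build_gene_units(fx$genes, fx$map, method = "srr")
  p1 <- tempfile(); p2 <- tempfile()
  write_gene_units(u, p1)
  write_gene_units(build_gene_units(fx$genes, fx$map, method = "srr"), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_match(readLines(p1)[1], "^# gene units")
  body <- utils::read.table(p1, sep = "\t")
  expect_equal(body[[4]], u$name)
  expect_equal(body[[2]], u$left)
  # 1-based output shifts only the left boundary
  p3 <- tempfile()
  write_gene_units(u, p3, coords = "1-based-inclusive")
  expect_equal(utils::read.table(p3, sep = "\t")[[2]], u$left + 1)
})
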