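# Shared test helpers: tiny map builders and independent oracles.

# Build a standardized one-chromosome map from a rate vector (optionally
# with gaps: NA rates drop the bin).
tiny_map <- function(rates, bin_width = 10000, chrom = "chr1",
                     standardize = TRUE) {
  starts <- seq(0, by = bin_width, length.out = length(rates))
  keep <- !is.na(rates)
  m <- recombination_map(
    data.frame(chrom = chrom, start = starts[keep],
               end = starts[keep] + bin_width, rate = rates[keep]),
    bin_width = bin_width)
  if (standardize) standardize_map(m) else m
}

# Independent oracle for one gene's SRR extension: materialize the full
# outward bin list from the bin table and prefix-sum it. Deliberately naive
# and structured differently from the walking implementation.
oracle_extension <- function(gene, map, threshold, bin_width) {
  b <- map[map$chrom == gene$chrom, , drop = FALSE]
  side <- function(dir) {
    if (dir > 0) {
      first_start <- floor(gene$end / bin_width) * bin_width
      out <- b[b$start >= first_start, , drop = FALSE]
      out <- out[order(out$start), , drop = FALSE]
      anchor <- first_start
    } else {
      if (gene$start == 0) {
        return(list(fallback = FALSE, boundary = 0, cum = 0))
      }
      first_start <- floor((gene$start - 1) / bin_width) * bin_width
      out <- b[b$start <= first_start, , drop = FALSE]
      out <- out[order(-out$start), , drop = FALSE]
      anchor <- first_start
    }
    # contiguity from the anchor bin: stop the usable list at the first gap
    if (nrow(out) == 0L || out$start[1] != anchor) {
      return(list(fallback = TRUE))
    }
    expected <- anchor + dir * bin_width * (seq_len(nrow(out)) - 1)
    n_contig <- which(out$start != expected)[1] - 1
    if (is.na(n_contig)) n_contig <- nrow(out)
    cs <- cumsum(out$srr[seq_len(n_contig)])
    hit <- which(cs >= threshold - 1e-9)[1]
    if (is.na(hit)) return(list(fallback = TRUE))
    list(fallback = FALSE,
         boundary = if (dir > 0) out$end[hit] else out$start[hit],
         cum = cs[hit])
  }
  list(left = side(-1), right = side(+1))
}

# Random small standardized map plus genes inside its covered span.
random_small_scenario <- function(seed) {
  set.seed(seed)
  n <- sample(15:40, 1)
  rates <- ifelse(runif(n) < 0.3, 0, rgamma(n, shape = 0.4, scale = 4))
  if (all(rates == 0)) rates[1] <- 1
  if (runif(1) < 0.3) rates[sample(2:(n - 1), 1)] <- NA  # interior gap
  map <- tiny_map(rates)
  n_genes <- sample(1:3, 1)
  gs <- sort(sample(seq(20000, (n - 3) * 10000, by = 5000), n_genes))
  genes <- gene_records(paste0("G", seq_len(n_genes)), "chr1", "+",
                        start = gs, end = gs + sample(c(5000, 10000, 15000),
                                                      n_genes, replace = TRUE))
  list(map = map, genes = genes)
}

# Brute-force one-tailed Fisher by enumeration over fixed-margin tables.
brute_fisher <- function(a, b, c, d, direction) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  if (direction == "row1_higher") sum(probs[xs >= a]) else sum(probs[xs <= a])
}
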