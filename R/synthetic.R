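# Synthetic recombination maps and gene sets with the statistical structure
# the extension method assumes: a heavily zero-inflated, right-skewed
# per-bin rate distribution with optional hotspot bins and uncovered
# telomere/centromere spans.

#' Parameters of the synthetic recombination map
#'
#' Per-bin rates are drawn from a zero-inflated gamma: a point mass at 0
#' (`zero_fraction`) and `Gamma(shape, scale)` cM/Mb otherwise. Defaults are
#' moment-matched to the three mass points of the human sex-averaged
#' genome-wide SRR distribution (about 42.6% of 10 Kb bins at SRR = 0,
#' 78.4% below 1, 12.9% at or above 2): `zero_fraction = 0.426` fixes the
#' zero mass exactly and `shape = 0.295` is the least-squares fit to the two
#' tail fractions (yielding about 79.0% below 1 and 14.2% at or above 2 —
#' a single shape parameter cannot match both exactly). The default scale
#' puts the genome mean near 1.13 cM/Mb; SRR is invariant to it. Hotspot
#' bins are placed by Poisson thinning at `hotspot_rate` per Mb and their
#' rate multiplied by `hotspot_intensity` (off by default: the gamma tail
#' already carries the hotspot mass matched above).
#'
#' @param n_chrom number of chromosomes (`chr1`, `chr2`, ...).
#' @param chrom_length chromosome length, bp (recycled over chromosomes).
#' @param bin_width bin width, bp.
#' @param zero_fraction probability mass at rate 0, in `[0, 1)`.
#' @param shape,scale gamma parameters of the positive rates (cM/Mb).
#' @param hotspot_rate expected hotspot bins per Mb.
#' @param hotspot_intensity rate multiplier for hotspot bins.
#' @param gap_spec uncovered spans: a list with optional elements
#'   `telomere` (bp dropped from each chromosome end) and `centromere` (bp
#'   dropped from the chromosome middle), or `NULL` for full coverage.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list of class `map_sim_params`.
#' @export
map_sim_params <- function(n_chrom = 2, chrom_length = 5e7, bin_width = 10000,
                           zero_fraction = 0.426, shape = 0.295,
                           scale = 6.673, hotspot_rate = 0,
                           hotspot_intensity = 10, gap_spec = NULL,
                           seed = NULL) {
  if (zero_fraction < 0 || zero_fraction >= 1) {
    stop_("zero_fraction must be in [0, 1)")
  }
  if (shape <= 0 || scale <= 0) stop_("gamma shape and scale must be > 0")
  if (bin_width <= 0) stop_("bin_width must be > 0")
  structure(list(n_chrom = n_chrom,
                 chrom_length = rep_len(chrom_length, n_chrom),
                 bin_width = bin_width, zero_fraction = zero_fraction,
                 shape = shape, scale = scale, hotspot_rate = hotspot_rate,
                 hotspot_intensity = hotspot_intensity, gap_spec = gap_spec,
                 seed = seed),
            class = "map_sim_params")
}

#' Simulate a recombination map
#'
#' @param params a [map_sim_params()].
#' @return an (unstandardized) [recombination_map()]; deterministic given
#'   `params$seed`.
#' @export
simulate_map <- function(params = map_sim_params()) {
  stopifnot(inherits(params, "map_sim_params"))
  with_seed(params$seed, {
    per_chrom <- lapply(seq_len(params$n_chrom), function(i) {
      L <- params$chrom_length[i]
      w <- params$bin_width
      starts <- seq(0, L - 1, by = w)
      ends <- pmin(starts + w, L)
      keep <- rep(TRUE, length(starts))
      gs <- params$gap_spec
      if (!is.null(gs)) {
        tel <- gs$telomere %||% 0
        cen <- gs$centromere %||% 0
        if (2 * tel + cen > L) {
          stop_("gap_spec (telomere %g x2 + centromere %g) exceeds chromosome length %g",
                tel, cen, L)
        }
        if (tel > 0) keep <- keep & starts >= tel & ends <= L - tel
        if (cen > 0) {
          c0 <- (L - cen) / 2
          keep <- keep & (ends <= c0 | starts >= c0 + cen)
        }
      }
      starts <- starts[keep]; ends <- ends[keep]
      n <- length(starts)
      if (n == 0L) stop_("gap_spec leaves no covered bins on chr%d", i)
      rate <- ifelse(stats::runif(n) < params$zero_fraction, 0,
                     stats::rgamma(n, shape = params$shape,
                                   scale = params$scale))
      if (params$hotspot_rate > 0) {
        p_hot <- params$hotspot_rate * params$bin_width / 1e6
        hot <- stats::runif(n) < p_hot
        rate[hot] <- rate[hot] * params$hotspot_intensity
      }
      data.frame(chrom = paste0("chr", i), start = starts, end = ends,
                 rate = rate, stringsAsFactors = FALSE)
    })
    recombination_map(do.call(rbind, per_chrom), bin_width = params$bin_width)
  })
}

#' Parameters of the synthetic gene set
#'
#' Gene lengths are log-normal with a median of about 20 Kb
#' (`meanlog = log(20000)`, `sdlog = 0.9`), a serviceable approximation of
#' the right-skewed human transcript-span distribution.
#'
#' @param n_genes number of genes to place.
#' @param length_meanlog,length_sdlog log-normal parameters of gene length
#'   (bp).
#' @param min_gap minimum distance between placed gene bodies, bp.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list of class `gene_sim_params`.
#' @export
gene_sim_params <- function(n_genes = 100, length_meanlog = log(20000),
                            length_sdlog = 0.9, min_gap = 10000,
                            seed = NULL) {
  if (n_genes < 0) stop_("n_genes must be >= 0")
  structure(list(n_genes = n_genes, length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, min_gap = min_gap, seed = seed),
            class = "gene_sim_params")
}

#' Simulate gene bodies on a map
#'
#' Genes are placed uniformly within the covered spans of the map
#' (allocation across chromosomes proportional to covered length),
#' respecting `min_gap` between bodies, by rejection sampling. Packing that
#' cannot be satisfied raises an error naming the constraint.
#'
#' @param params a [gene_sim_params()].
#' @param map a [recombination_map()] supplying the covered spans.
#' @return a [gene_records()] table; deterministic given `params$seed`.
#' @export
simulate_genes <- function(params = gene_sim_params(), map) {
  stopifnot(inherits(params, "gene_sim_params"), inherits(map, "recmap"))
  if (params$n_genes == 0L) {
    return(gene_records(character(), character(), character(),
                        numeric(), numeric()))
  }
  spans <- covered_spans(map)
  with_seed(params$seed, {
    spans$weight <- spans$end - spans$start
    alloc <- stats::rmultinom(1, params$n_genes,
                              spans$weight / sum(spans$weight))[, 1]
    out <- list()
    gi <- 0L
    for (s in seq_len(nrow(spans))) {
      if (alloc[s] == 0L) next
      placed <- numeric(0)  # interleaved starts/ends, kept sorted
      lo <- spans$start[s]; hi <- spans$end[s]
      for (j in seq_len(alloc[s])) {
        ok <- FALSE
        for (try in 1:200) {
          len <- max(1000, round(stats::rlnorm(1, params$length_meanlog,
                                               params$length_sdlog)))
          if (len >= hi - lo) next
          st <- lo + floor(stats::runif(1) * (hi - lo - len))
          en <- st + len
          if (!length(placed) ||
              !any(st - params$min_gap < placed[c(FALSE, TRUE)] &
                   placed[c(TRUE, FALSE)] < en + params$min_gap)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop_("infeasible packing: %d genes with min_gap %g bp in span %s:[%g,%g)",
                alloc[s], params$min_gap, spans$chrom[s], lo, hi)
        }
        placed <- c(placed, st, en)
        gi <- gi + 1L
        out[[gi]] <- data.frame(
          name = sprintf("GENE%04d", gi), chrom = spans$chrom[s],
          strand = if (stats::runif(1) < 0.5) "+" else "-",
          start = st, end = en, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, out)
    gene_records(df$name, df$chrom, df$strand, df$start, df$end)
  })
}

# Maximal contiguous covered runs of a map, one row per run.
covered_spans <- function(map) {
  w <- attr(map, "bin_width")
  out <- lapply(split(map[c("start", "end")], map$chrom), function(b) {
    brk <- c(TRUE, b$start[-1] != b$end[-nrow(b)])
    run <- cumsum(brk)
    data.frame(start = tapply(b$start, run, min),
               end = tapply(b$end, run, max))
  })
  df <- do.call(rbind, Map(function(ch, d) {
    d$chrom <- ch
    d
  }, names(out), out))
  df <- df[genome_order(df$chrom, df$start), c("chrom", "start", "end")]
  rownames(df) <- NULL
  df
}
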