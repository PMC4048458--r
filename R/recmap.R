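# Recombination maps: reading, validation, standardization (SRR), and
# distribution summaries.

#' Construct a recombination map from per-bin rates
#'
#' A recombination map is a genome grid of fixed-width bins, each carrying a
#' sex-averaged recombination rate in cM/Mb. Coordinates are 0-based
#' half-open. Bins must be non-overlapping and aligned to the grid (start a
#' multiple of `bin_width`); gaps (missing bins) are permitted and are what
#' the extension algorithm later treats as loss of coverage. The final bin of
#' a chromosome may be shorter than `bin_width` (a terminal stub); all other
#' bins must have exactly `bin_width` span.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`, `rate`
#'   (cM/Mb, non-negative).
#' @param bin_width bin width in bp. If `NULL`, inferred as the most common
#'   `end - start` span.
#' @param allow_short_bins allow a short terminal bin per chromosome.
#' @return An object of class `recmap`: the validated, sorted bin table with
#'   attributes `bin_width` and (after [standardize_map()]) `genome_mean_rate`.
#' @seealso [read_recombination_map()], [standardize_map()], [srr_histogram()]
#' @export
recombination_map <- function(bins, bin_width = NULL, allow_short_bins = TRUE) {
  req <- c("chrom", "start", "end", "rate")
  if (!all(req %in% names(bins))) {
    stop_("map bins need columns %s", paste(req, collapse = ", "))
  }
  if (nrow(bins) == 0L) stop_("empty recombination map")
  bins <- as.data.frame(bins)[, c(req, intersect("srr", names(bins)))]
  bins$chrom <- as.character(bins$chrom)
  bins$start <- as.numeric(bins$start)
  bins$end <- as.numeric(bins$end)
  bins$rate <- as.numeric(bins$rate)
  if (anyNA(bins$start) || anyNA(bins$end) || anyNA(bins$rate)) {
    stop_("map bins contain missing coordinates or rates")
  }
  if (any(bins$rate < 0)) {
    stop_("negative recombination rate at row %d", which(bins$rate < 0)[1])
  }
  if (any(bins$end <= bins$start)) {
    stop_("bin with end <= start at row %d", which(bins$end <= bins$start)[1])
  }
  span <- bins$end - bins$start
  if (is.null(bin_width)) {
    tab <- table(span)
    bin_width <- as.numeric(names(tab)[which.max(tab)])
  }
  if (any(bins$start %% bin_width != 0)) {
    bad <- which(bins$start %% bin_width != 0)[1]
    stop_("bin start %g not aligned to %g bp grid (row %d)",
          bins$start[bad], bin_width, bad)
  }
  bins <- bins[genome_order(bins$chrom, bins$start), , drop = FALSE]
  rownames(bins) <- NULL
  # per-chromosome checks: duplicates, overlaps, constant width
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    if (anyDuplicated(b$start)) stop_("duplicate bin on %s", ch)
    if (any(b$start[-1] < b$end[-nrow(b)])) stop_("overlapping bins on %s", ch)
    w <- b$end - b$start
    full <- w == bin_width
    if (!all(full)) {
      short <- which(!full)
      ok <- allow_short_bins && length(short) == 1L && short == nrow(b) &&
        w[short] < bin_width
      if (!ok) {
        stop_("bin width %g on %s differs from map bin width %g",
              w[short[1]], ch, bin_width)
      }
    }
  }
  structure(bins,
    bin_width = bin_width,
    genome_mean_rate = attr(bins, "genome_mean_rate"),
    class = c("recmap", "data.frame"))
}

#' Read a fixed-width-bin recombination map
#'
#' Reads a tab-delimited map of fixed-width genome bins with sex-averaged
#' recombination rates. The default dialect (`"decode-10kb"`) expects columns
#' chrom, start, end, rate (cM/Mb) over a 10 Kb grid, 0-based half-open
#' coordinates. gzip-compressed files are read transparently.
#'
#' @param path path to a tab-delimited file (optionally gzipped). A leading
#'   header line is detected and skipped when its rate field is non-numeric;
#'   lines starting with `#` are ignored.
#' @param dialect `"decode-10kb"` (chrom, start, end, rate on a 10 Kb grid)
#'   or `"custom"` (grid inferred or given via `bin_width`).
#' @param columns integer vector of length 4 naming which file columns hold
#'   chrom, start, end, rate (in that order). Default `1:4`.
#' @param bin_width expected bin width in bp; `NULL` infers it.
#' @param one_based set `TRUE` if starts are 1-based inclusive; they are
#'   shifted to the internal 0-based half-open convention.
#' @param autosomes_only drop non-autosomal records with a warning (default).
#' @param chrom_aliases named character vector resolving non-standard
#'   chromosome names; unresolvable names are an error.
#' @return A [recombination_map()] object.
#' @export
read_recombination_map <- function(path,
                                   dialect = c("decode-10kb", "custom"),
                                   columns = 1:4,
                                   bin_width = NULL,
                                   one_based = FALSE,
                                   autosomes_only = TRUE,
                                   chrom_aliases = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "decode-10kb" && is.null(bin_width)) bin_width <- 10000
  if (!file.exists(path)) stop_("map file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop_("empty map file: %s", path)
  if (ncol(raw) < max(columns)) {
    stop_("map file %s has %d columns, need %d", path, ncol(raw), max(columns))
  }
  # header line: rate field not numeric
  if (is.na(suppressWarnings(as.numeric(raw[1, columns[4]])))) {
    raw <- raw[-1, , drop = FALSE]
    if (nrow(raw) == 0L) stop_("map file %s has a header but no data", path)
  }
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      stop_("cannot parse %s at line %d of %s", what, which(is.na(v))[1], path)
    }
    v
  }
  bins <- data.frame(
    chrom = raw[[columns[1]]],
    start = num(columns[2], "bin start"),
    end = num(columns[3], "bin end"),
    rate = num(columns[4], "recombination rate"),
    stringsAsFactors = FALSE
  )
  if (one_based) bins$start <- bins$start - 1
  bins$chrom <- resolve_chroms(bins$chrom, chrom_aliases, path)
  if (autosomes_only) {
    drop <- !is_autosome(bins$chrom)
    if (any(drop)) {
      warn_("dropping %d non-autosomal bins (%s)", sum(drop),
            paste(unique(bins$chrom[drop]), collapse = ", "))
      bins <- bins[!drop, , drop = FALSE]
      if (nrow(bins) == 0L) stop_("no autosomal bins in %s", path)
    }
  }
  recombination_map(bins, bin_width = bin_width)
}

resolve_chroms <- function(chrom, aliases, path) {
  out <- normalize_chrom(chrom, aliases)
  if (anyNA(out)) {
    bad <- unique(chrom[is.na(out)])
    stop_("unresolvable chromosome name(s) in %s: %s (supply chrom_aliases)",
          path, paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Standardize a recombination map to SRR
#'
#' Divides each bin's recombination rate by the genome-wide mean rate, giving
#' the standardized recombination rate (SRR): SRR = 1 marks a bin with
#' average recombination. The genome mean is the unweighted mean over all
#' bins present in the map, zeros included, missing bins excluded (bins are
#' equal width, so this equals the length-weighted mean). By construction
#' the mean SRR over bins with data is exactly 1; the operation is
#' idempotent and invariant to rescaling all rates by a positive constant.
#'
#' @param map a [recombination_map()].
#' @return The map with an `srr` column and the `genome_mean_rate` attribute
#'   (cM/Mb) recorded.
#' @export
standardize_map <- function(map) {
  stopifnot(inherits(map, "recmap"))
  m <- mean(map$rate)
  if (!is.finite(m) || m <= 0) {
    stop_("cannot standardize: genome mean rate is %g (all-zero map?)", m)
  }
  map$srr <- map$rate / m
  attr(map, "genome_mean_rate") <- m
  map
}

is_standardized <- function(map) "srr" %in% names(map)

require_srr <- function(map) {
  if (!is_standardized(map)) {
    stop_("map is not standardized; call standardize_map() first")
  }
  invisible(map)
}

#' Summarize the genome-wide SRR distribution
#'
#' Bins of the (standardized) map are counted into half-open SRR intervals
#' `[e_i, e_{i+1})`, reproducing the usual histogram view of how unevenly
#' recombination is spread along a genome: a large point mass at SRR = 0, a
#' majority of bins below the genome average, and a long upper tail where
#' hotspots concentrate most recombination.
#'
#' @param map a standardized [recombination_map()].
#' @param interval_edges strictly increasing SRR breakpoints; the last edge
#'   may be `Inf` (and is extended to `Inf` automatically if data exceed it).
#' @param threshold SRR threshold reported as `fraction_at_least_threshold`
#'   (default 2, the gene-extension stopping threshold).
#' @return An object of class `srr_histogram`: interval edges, per-interval
#'   counts and fractions, and the spot fractions `fraction_zero` (SRR
#'   exactly 0), `fraction_below_one` and `fraction_at_least_threshold`.
#' @export
srr_histogram <- function(map,
                          interval_edges = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 10, Inf),
                          threshold = 2) {
  require_srr(map)
  edges <- as.numeric(interval_edges)
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop_("interval_edges must be strictly increasing with >= 2 values")
  }
  x <- map$srr
  if (min(x) < edges[1]) stop_("SRR value below first interval edge")
  if (is.finite(edges[length(edges)]) && max(x) >= edges[length(edges)]) {
    edges <- c(edges, Inf)
  }
  k <- length(edges) - 1L
  idx <- findInterval(x, edges)          # half-open [e_i, e_{i+1})
  counts <- tabulate(idx, nbins = k)
  structure(list(
    interval_edges = edges,
    bin_counts = counts,
    fractions = counts / length(x),
    fraction_zero = mean(x == 0),
    fraction_below_one = mean(x < 1),
    fraction_at_least_threshold = mean(x >= threshold),
    threshold = threshold,
    n_bins = length(x)
  ), class = "srr_histogram")
}

#' @export
print.srr_histogram <- function(x, ...) {
  cat(sprintf("SRR distribution over %d bins\n", x$n_bins))
  cat(sprintf("  SRR = 0        : %.1f%%\n", 100 * x$fraction_zero))
  cat(sprintf("  SRR < 1        : %.1f%%\n", 100 * x$fraction_below_one))
  cat(sprintf("  SRR >= %-3g     : %.1f%%\n", x$threshold,
              100 * x$fraction_at_least_threshold))
  invisible(x)
}

#' Write an SRR histogram as a tab-delimited table
#'
#' @param hist an [srr_histogram()] result.
#' @param path output path. Columns: interval_start, interval_end, count,
#'   fraction.
#' @export
write_srr_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "srr_histogram"))
  e <- hist$interval_edges
  df <- data.frame(interval_start = e[-length(e)], interval_end = e[-1],
                   count = hist$bin_counts, fraction = hist$fractions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.recmap <- function(x, ...) {
  cat(sprintf("recombination map: %d bins (%g bp) on %d chromosome(s)\n",
              nrow(x), attr(x, "bin_width"), length(unique(x$chrom))))
  if (is_standardized(x)) {
    cat(sprintf("  standardized; genome mean rate %.4f cM/Mb\n",
                attr(x, "genome_mean_rate")))
  } else {
    cat("  raw rates (not standardized)\n")
  }
  NextMethod()
}

# First/last covered coordinate per chromosome.
#' Covered span per chromosome
#' @param map a [recombination_map()].
#' @return data.frame with chrom, first covered coordinate, last covered
#'   coordinate, and number of bins.
#' @export
chrom_spans <- function(map) {
  stopifnot(inherits(map, "recmap"))
  sp <- do.call(rbind, lapply(split(map, map$chrom), function(b) {
    data.frame(chrom = b$chrom[1], first = min(b$start), last = max(b$end),
               n_bins = nrow(b), stringsAsFactors = FALSE)
  }))
  sp <- sp[genome_order(sp$chrom, sp$first), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}
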