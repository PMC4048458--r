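# Core algorithm: gene units by cumulative SRR, the fixed-distance
# comparator, the telomere/centromere median fallback, and the 4-column
# definition file.

#' Parameters of the gene-extension rules
#'
#' @param srr_threshold cumulative SRR at which an extension stops
#'   (unitless, default 2: the walk has accumulated twice the genome-average
#'   recombination of one bin width).
#' @param fixed_distance extension length of the fixed-physical-distance
#'   comparator, bp (default 50,000, the conventional +/- 50 Kb rule).
#' @param bin_width map bin width, bp (default 10,000).
#' @return list of class `extension_params`.
#' @export
extension_params <- function(srr_threshold = 2, fixed_distance = 50000,
                             bin_width = 10000) {
  if (!is.numeric(srr_threshold) || srr_threshold <= 0) {
    stop_("srr_threshold must be > 0")
  }
  if (!is.numeric(fixed_distance) || fixed_distance < 0) {
    stop_("fixed_distance must be >= 0")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) stop_("bin_width must be > 0")
  structure(list(srr_threshold = srr_threshold,
                 fixed_distance = fixed_distance,
                 bin_width = bin_width),
            class = "extension_params")
}

# Cumulative-SRR stop uses a small tolerance: standardizing a uniform map
# can leave srr at 1 +/- 1 ulp and the exact-threshold case (e.g. two srr=1
# bins at threshold 2) must still stop at the second bin.
SRR_EPS <- 1e-9

# Per-chromosome grid index: srr and bin-end vectors addressed by bin number
# (start / bin_width), NA where the map has no bin. Short terminal bins keep
# their true end.
build_map_index <- function(map, bin_width) {
  lapply(split(map[c("start", "end", "srr")], map$chrom), function(b) {
    first <- b$start[1] / bin_width
    last <- b$start[nrow(b)] / bin_width
    n <- last - first + 1
    srr <- rep(NA_real_, n)
    ends <- rep(NA_real_, n)
    at <- b$start / bin_width - first + 1
    srr[at] <- b$srr
    ends[at] <- b$end
    list(first = first, last = last, srr = srr, ends = ends)
  })
}

# Walk outward from bin number b0 (direction +1 right / -1 left),
# accumulating srr until the threshold is reached or coverage runs out.
# Returns n_bins (0 on immediate fallback), cum, the stop bin number, and
# the fallback flag.
walk_bins <- function(ix, b0, dir, threshold) {
  if (b0 < ix$first || b0 > ix$last) {
    return(list(n = 0L, cum = 0, stop_bin = NA_real_, fallback = TRUE))
  }
  rel0 <- b0 - ix$first + 1
  slice <- if (dir > 0) ix$srr[rel0:length(ix$srr)] else ix$srr[rel0:1]
  gap <- which(is.na(slice))[1]
  usable <- if (is.na(gap)) slice else slice[seq_len(gap - 1L)]
  if (length(usable)) {
    cs <- cumsum(usable)
    hit <- which(cs >= threshold - SRR_EPS)[1]
  } else {
    cs <- numeric(0)
    hit <- NA_integer_
  }
  if (!is.na(hit)) {
    list(n = hit, cum = cs[hit], stop_bin = b0 + dir * (hit - 1L),
         fallback = FALSE)
  } else {
    list(n = length(usable),
         cum = if (length(usable)) cs[length(usable)] else 0,
         stop_bin = if (length(usable)) b0 + dir * (length(usable) - 1L)
                    else NA_real_,
         fallback = TRUE)
  }
}

unit_row <- function(gene, left, right, method, ext_left, ext_right,
                     cum_left = NA_real_, cum_right = NA_real_,
                     fb_left = FALSE, fb_right = FALSE) {
  data.frame(name = gene$name, chrom = gene$chrom, strand = gene$strand,
             gene_start = gene$start, gene_end = gene$end,
             left = left, right = right, method = method,
             ext_left = ext_left, ext_right = ext_right,
             cum_srr_left = cum_left, cum_srr_right = cum_right,
             fallback_left = fb_left, fallback_right = fb_right,
             stringsAsFactors = FALSE)
}

#' Extend one gene by cumulative SRR
#'
#' For each side independently, the map is walked outward in bins starting
#' from the bin containing the first base beyond the gene boundary (bins
#' lying entirely within the gene body are never counted; the first counted
#' bin counts in full even when it partially overlaps the gene), summing SRR
#' until the cumulative sum reaches `srr_threshold`. The unit boundary is
#' that bin's outer edge — its start on the left side, its end on the right —
#' so an extension measured from the gene boundary can be shorter than one
#' bin width. A gene boundary lying exactly on a bin edge starts the walk at
#' the next full bin outward. If a coverage gap or the end of the mapped
#' chromosome is reached first, the side is flagged for the median fallback
#' ([apply_fallback()]) and its boundary left provisionally at the last
#' covered edge.
#'
#' @param gene one-row [gene_records()] slice (or list with name, chrom,
#'   strand, start, end).
#' @param map a standardized [recombination_map()].
#' @param params [extension_params()].
#' @return one-row `gene_units` data.frame (see [build_gene_units()]).
#' @export
extend_gene_srr <- function(gene, map, params = extension_params()) {
  require_srr(map)
  gene <- as.list(gene[c("name", "chrom", "strand", "start", "end")])
  idx <- build_map_index(map, params$bin_width)
  if (!gene$chrom %in% names(idx)) {
    stop_("gene %s: chromosome %s absent from map", gene$name, gene$chrom)
  }
  extend_gene_srr_indexed(gene, idx[[gene$chrom]], params)
}

extend_gene_srr_indexed <- function(gene, ix, params) {
  w <- params$bin_width
  th <- params$srr_threshold
  # right: first base beyond the gene is at coordinate gene$end
  r <- walk_bins(ix, floor(gene$end / w), +1L, th)
  if (!r$fallback) {
    right <- ix$ends[r$stop_bin - ix$first + 1]
  } else {
    right <- if (is.na(r$stop_bin)) gene$end
             else max(gene$end, ix$ends[r$stop_bin - ix$first + 1])
  }
  # left: first base beyond the gene is at coordinate gene$start - 1
  if (gene$start == 0) {
    l <- list(n = 0L, cum = 0, stop_bin = NA_real_, fallback = FALSE)
    left <- 0
  } else {
    l <- walk_bins(ix, floor((gene$start - 1) / w), -1L, th)
    if (!l$fallback) {
      left <- l$stop_bin * w
    } else {
      left <- if (is.na(l$stop_bin)) gene$start
              else min(gene$start, l$stop_bin * w)
    }
  }
  unit_row(gene, left, right, "srr",
           ext_left = gene$start - left, ext_right = right - gene$end,
           cum_left = l$cum, cum_right = r$cum,
           fb_left = l$fallback, fb_right = r$fallback)
}

#' Replace incomplete extensions by the per-chromosome median
#'
#' Genes near telomeres and centromeres are incompletely covered by the map;
#' their flagged sides get the median length of all completed (non-fallback)
#' extensions on the same chromosome, pooling left and right sides. The
#' substituted boundary is recomputed from the gene edge and clipped at
#' coordinate 0. A chromosome with no completed extension falls back to the
#' genome-wide median, with a warning.
#'
#' @param units `gene_units` table from the SRR method (may span
#'   chromosomes; medians are computed within each).
#' @param params [extension_params()] (unused lengths kept for signature
#'   stability).
#' @return the units with every flagged side replaced; fallback flags are
#'   retained, attained `cum_srr` of replaced sides set to `NA`.
#' @export
apply_fallback <- function(units, params = extension_params()) {
  stopifnot(is.data.frame(units))
  if (nrow(units) == 0L) return(units)
  if (!all(units$method == "srr")) stop_("fallback applies to srr units only")
  done <- c(units$ext_left[!units$fallback_left],
            units$ext_right[!units$fallback_right])
  genome_median <- if (length(done)) stats::median(done) else NA_real_
  for (ch in unique(units$chrom)) {
    sel <- units$chrom == ch
    u <- units[sel, , drop = FALSE]
    pool <- c(u$ext_left[!u$fallback_left], u$ext_right[!u$fallback_right])
    med <- if (length(pool)) stats::median(pool) else {
      if (is.na(genome_median)) {
        stop_("no completed extensions anywhere; cannot apply fallback")
      }
      warn_("chromosome %s has no completed extensions; using genome-wide median",
            ch)
      genome_median
    }
    fl <- sel & units$fallback_left
    if (any(fl)) {
      units$left[fl] <- pmax(0, units$gene_start[fl] - med)
      units$ext_left[fl] <- units$gene_start[fl] - units$left[fl]
      units$cum_srr_left[fl] <- NA_real_
    }
    fr <- sel & units$fallback_right
    if (any(fr)) {
      units$right[fr] <- units$gene_end[fr] + med
      units$ext_right[fr] <- med
      units$cum_srr_right[fr] <- NA_real_
    }
  }
  units
}

#' Extend one gene by a fixed physical distance
#'
#' The conventional comparator: the gene body plus `fixed_distance` bp in
#' each direction, clipped at 0 and, when known, at the chromosome length.
#'
#' @param gene one-row [gene_records()] slice.
#' @param params [extension_params()].
#' @param chrom_length chromosome length in bp, or `NA` to leave the right
#'   side unclipped.
#' @return one-row `gene_units` data.frame.
#' @export
extend_gene_fixed <- function(gene, params = extension_params(),
                              chrom_length = NA_real_) {
  gene <- as.list(gene[c("name", "chrom", "strand", "start", "end")])
  left <- max(0, gene$start - params$fixed_distance)
  right <- gene$end + params$fixed_distance
  if (!is.na(chrom_length)) right <- min(right, chrom_length)
  unit_row(gene, left, right, "fixed",
           ext_left = gene$start - left, ext_right = right - gene$end)
}

#' Build gene units for a catalogue
#'
#' Runs one of the two definitions over a gene table: `method = "srr"`
#' applies [extend_gene_srr()] to every gene and then the per-chromosome
#' median fallback; `method = "fixed"` applies [extend_gene_fixed()]. Output
#' rows are ordered deterministically by chromosome, left boundary, then
#' name.
#'
#' @param genes a [gene_records()] table (one record per gene; run
#'   [collapse_transcripts()] first on transcript-level input).
#' @param map standardized [recombination_map()]; required for `"srr"`.
#' @param params [extension_params()].
#' @param method `"srr"` or `"fixed"`.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   clipping fixed units.
#' @param on_error `"stop"` (default) or `"skip"`: a gene whose chromosome
#'   is absent from the map either aborts with its name or is dropped with a
#'   warning.
#' @return data.frame of class `gene_units` with one row per gene: the gene
#'   body, unit boundaries `[left, right)`, per-side extension lengths,
#'   attained cumulative SRR, and fallback flags; attributes `method` and
#'   `params`.
#' @export
build_gene_units <- function(genes, map = NULL, params = extension_params(),
                             method = c("srr", "fixed"),
                             chrom_lengths = NULL,
                             on_error = c("stop", "skip")) {
  method <- match.arg(method)
  on_error <- match.arg(on_error)
  stopifnot(is.data.frame(genes))
  empty <- unit_row(list(name = "x", chrom = "x", strand = "+", start = 0,
                         end = 1), 0, 1, method, 0, 0)[0, ]
  if (nrow(genes) == 0L) {
    return(structure(empty, method = method, params = params,
                     class = c("gene_units", "data.frame")))
  }
  if (method == "srr") {
    if (is.null(map)) stop_("srr method needs a recombination map")
    require_srr(map)
    idx <- build_map_index(map, params$bin_width)
    missing_chrom <- !(genes$chrom %in% names(idx))
    if (any(missing_chrom)) {
      msg <- sprintf("chromosome absent from map for gene(s): %s",
                     paste(utils::head(genes$name[missing_chrom], 5),
                           collapse = ", "))
      if (on_error == "stop") stop_("%s", msg)
      warn_("skipping %d genes; %s", sum(missing_chrom), msg)
      genes <- genes[!missing_chrom, , drop = FALSE]
      if (nrow(genes) == 0L) {
        return(structure(empty, method = method, params = params,
                         class = c("gene_units", "data.frame")))
      }
    }
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      g <- as.list(genes[i, c("name", "chrom", "strand", "start", "end")])
      extend_gene_srr_indexed(g, idx[[g$chrom]], params)
    })
    units <- do.call(rbind, rows)
    units <- apply_fallback(units, params)
  } else {
    cl <- if (is.null(chrom_lengths)) rep(NA_real_, nrow(genes))
          else unname(chrom_lengths[genes$chrom])
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, , drop = FALSE]
      extend_gene_fixed(g, params, chrom_length = cl[i])
    })
    units <- do.call(rbind, rows)
  }
  units <- units[genome_order(units$chrom, units$left, units$name), ,
                 drop = FALSE]
  rownames(units) <- NULL
  structure(units, method = method, params = params,
            class = c("gene_units", "data.frame"))
}

#' @export
print.gene_units <- function(x, ...) {
  cat(sprintf("gene units (%s method): %d genes, %d with a fallback side\n",
              attr(x, "method") %||% unique(x$method), nrow(x),
              sum(x$fallback_left | x$fallback_right)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene-unit definition file
#'
#' Reads the 4-column definition file written by [write_gene_units()]
#' (chrom, left, right, name) back into a minimal unit table suitable for
#' the overlap, containment and concordance operations. Gene-body
#' coordinates, extension lengths and cumulative SRR are not stored in the
#' file and come back as `NA`.
#'
#' @param path definition file (`#` header tolerated).
#' @param method method tag to record on the table.
#' @return data.frame of class `gene_units`.
#' @export
read_gene_units <- function(path, method = "srr") {
  if (!file.exists(path)) stop_("definition file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop_("definition file needs 4 columns")
  df <- data.frame(name = raw[[4]], chrom = raw[[1]], strand = NA_character_,
                   gene_start = NA_real_, gene_end = NA_real_,
                   left = as.numeric(raw[[2]]), right = as.numeric(raw[[3]]),
                   method = method, ext_left = NA_real_, ext_right = NA_real_,
                   cum_srr_left = NA_real_, cum_srr_right = NA_real_,
                   fallback_left = NA, fallback_right = NA,
                   stringsAsFactors = FALSE)
  if (anyNA(df$left) || anyNA(df$right)) stop_("bad boundary in %s", path)
  structure(df, method = method, class = c("gene_units", "data.frame"))
}

#' Write gene-unit definitions
#'
#' The definition file is tabulated plain text, one row per gene with
#' columns chromosome, left boundary, right boundary, gene name, preceded by
#' a `#` header line recording the coordinate convention. Identical inputs
#' produce byte-identical files.
#'
#' @param units a `gene_units` table.
#' @param path output path.
#' @param coords `"0-based-half-open"` (internal convention, default) or
#'   `"1-based-inclusive"` (left boundary shifted by +1).
#' @param format `"genedef"` (chrom, left, right, name) or `"bed"` (BED4).
#' @export
write_gene_units <- function(units, path,
                             coords = c("0-based-half-open", "1-based-inclusive"),
                             format = c("genedef", "bed")) {
  coords <- match.arg(coords)
  format <- match.arg(format)
  stopifnot(is.data.frame(units))
  left <- if (coords == "1-based-inclusive" && format == "genedef") {
    units$left + 1
  } else units$left
  df <- data.frame(chrom = units$chrom,
                   left = format(left, scientific = FALSE, trim = TRUE),
                   right = format(units$right, scientific = FALSE, trim = TRUE),
                   name = units$name, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "genedef") {
    writeLines(sprintf("# gene units (%s); coordinates: %s; columns: chrom, left, right, name",
                       attr(units, "method") %||% unique(units$method), coords),
               con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
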