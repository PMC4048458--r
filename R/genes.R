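# Gene catalogues: reading refGene-style and BED files, normalizing to one
# record per gene.

#' Construct a validated gene record table
#'
#' @param name gene symbols or accessions (non-empty).
#' @param chrom chromosome identifiers (canonical `chrN`).
#' @param strand `"+"` or `"-"`; recorded but not used by the extension
#'   algorithm, which works on genomic left/right.
#' @param start,end 0-based half-open transcript span, `start < end`.
#' @return data.frame of class `gene_records`, sorted by genome position.
#' @export
gene_records <- function(name, chrom, strand = "+", start, end) {
  df <- data.frame(name = as.character(name), chrom = as.character(chrom),
                   strand = as.character(strand), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    if (any(!nzchar(df$name)) || anyNA(df$name)) stop_("empty gene name")
    bad <- which(!(df$start < df$end))
    if (length(bad)) {
      stop_("gene %s has start >= end (%g >= %g)",
            df$name[bad[1]], df$start[bad[1]], df$end[bad[1]])
    }
    if (any(df$start < 0)) stop_("negative gene start")
    if (!all(df$strand %in% c("+", "-"))) stop_("strand must be '+' or '-'")
    df <- df[genome_order(df$chrom, df$start, df$name), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("gene_records", "data.frame")
  df
}

#' Read a gene catalogue
#'
#' Supports two dialects: UCSC refGene-style tables (columns `name`,
#' `chrom`, `strand`, `txStart`, `txEnd`, located by header names when a
#' header is present, otherwise taken as the first five columns, with an
#' optional leading UCSC `bin` column auto-detected) and BED4/BED6. The
#' transcript span (txStart-txEnd) is taken as the gene body to be extended.
#' BED records without a strand field default to `"+"`.
#'
#' @param path tab-delimited file, optionally gzipped; `#` lines ignored.
#' @param format `"refgene"` or `"bed"`.
#' @param one_based set `TRUE` if starts are 1-based inclusive (converted to
#'   0-based half-open internally). UCSC refGene and BED are natively
#'   0-based, so the default is `FALSE`.
#' @param autosomes_only drop non-autosomal records with a warning.
#' @param chrom_aliases named character vector for non-standard chromosome
#'   names; unresolvable names are an error.
#' @return A [gene_records()] table, possibly with several transcripts per
#'   gene; see [collapse_transcripts()].
#' @export
read_genes <- function(path, format = c("refgene", "bed"),
                       one_based = FALSE, autosomes_only = TRUE,
                       chrom_aliases = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("gene file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop_("empty gene file: %s", path)
  if (format == "bed") {
    if (ncol(raw) < 4L) stop_("BED gene file needs >= 4 columns")
    df <- data.frame(name = raw[[4]], chrom = raw[[1]],
                     strand = if (ncol(raw) >= 6L) raw[[6]] else "+",
                     start = raw[[2]], end = raw[[3]],
                     stringsAsFactors = FALSE)
  } else {
    cols <- refgene_columns(raw)
    raw <- cols$data
    df <- data.frame(name = raw[[cols$name]], chrom = raw[[cols$chrom]],
                     strand = raw[[cols$strand]], start = raw[[cols$txStart]],
                     end = raw[[cols$txEnd]], stringsAsFactors = FALSE)
  }
  df$start <- suppressWarnings(as.numeric(df$start))
  df$end <- suppressWarnings(as.numeric(df$end))
  if (anyNA(df$start) || anyNA(df$end)) {
    stop_("cannot parse gene coordinates at line %d of %s",
          which(is.na(df$start) | is.na(df$end))[1], path)
  }
  if (one_based) df$start <- df$start - 1
  df$chrom <- resolve_chroms(df$chrom, chrom_aliases, path)
  if (autosomes_only) {
    drop <- !is_autosome(df$chrom)
    if (any(drop)) {
      warn_("dropping %d non-autosomal gene records", sum(drop))
      df <- df[!drop, , drop = FALSE]
      if (nrow(df) == 0L) stop_("no autosomal genes in %s", path)
    }
  }
  gene_records(df$name, df$chrom, df$strand, df$start, df$end)
}

# Locate refGene columns by header names, else positionally (skipping a
# leading integer UCSC `bin` column if present).
refgene_columns <- function(raw) {
  first <- as.character(raw[1, ])
  wanted <- c("name", "chrom", "strand", "txStart", "txEnd")
  if (all(wanted %in% first)) {
    idx <- match(wanted, first)
    data2 <- raw[-1, , drop = FALSE]
    return(list(data = data2, name = idx[1], chrom = idx[2], strand = idx[3],
                txStart = idx[4], txEnd = idx[5]))
  }
  offset <- 0L
  strand_col_no_bin <- if (ncol(raw) >= 3L) raw[[3]] else character()
  if (!all(strand_col_no_bin %in% c("+", "-")) &&
      ncol(raw) >= 4L && all(raw[[4]] %in% c("+", "-"))) {
    offset <- 1L   # leading UCSC bin column
  }
  if (ncol(raw) < 5L + offset) stop_("refGene file needs >= 5 data columns")
  list(data = raw, name = 1L + offset, chrom = 2L + offset,
       strand = 3L + offset, txStart = 4L + offset, txEnd = 5L + offset)
}

#' Collapse transcripts to one record per gene
#'
#' Records sharing a name on the same chromosome are merged to their union
#' span (min start, max end), the reproducible rule for reducing a
#' transcript-level catalogue to one unit per gene. The same name on
#' different chromosomes is kept as separate records with `_chrN` suffixes
#' (warned about). Strand is taken from the first record of each group; a
#' mixed-strand group is warned about. The operation is idempotent and
#' order-independent, and every output span contains every input span of the
#' same gene. Distinct genes that overlap are left untouched: gene units may
#' overlap.
#'
#' @param records a [gene_records()] table.
#' @return A [gene_records()] table with one record per (renamed) gene.
#' @export
collapse_transcripts <- function(records) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records) == 0L) return(gene_records(character(), character(),
                                               character(), numeric(), numeric()))
  multi <- unique(records$name[duplicated(records[c("name")])])
  split_names <- unique(records$name[records$name %in% multi &
    ave(as.integer(factor(records$chrom)), records$name,
        FUN = function(z) length(unique(z))) > 1])
  if (length(split_names)) {
    warn_("gene name(s) on multiple chromosomes, suffixed: %s",
          paste(utils::head(split_names, 5), collapse = ", "))
    sel <- records$name %in% split_names
    records$name[sel] <- paste0(records$name[sel], "_", records$chrom[sel])
  }
  key <- paste(records$name, records$chrom, sep = "\r")
  mixed <- tapply(records$strand, key, function(s) length(unique(s)) > 1)
  if (any(mixed)) {
    warn_("%d gene(s) with transcripts on both strands; first strand kept",
          sum(mixed))
  }
  agg <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(name = g$name[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  gene_records(agg$name, agg$chrom, agg$strand, agg$start, agg$end)
}
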