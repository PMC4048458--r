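# Evaluation machinery: extension-length summaries, boundary concordance,
# gene lists per association region or top SNP, scorecards, and the
# one-tailed Fisher exact test.

#' Summarize gene-extension lengths
#'
#' Statistics are computed over the pooled 5' and 3' extensions (two per
#' gene). Quartiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7). Cutoff fractions are strict:
#' `fraction_below` is the proportion of extensions strictly shorter than a
#' cutoff and `fraction_above` strictly longer.
#'
#' @param units a `gene_units` table (one method).
#' @param cutoffs length cutoffs in Kb (default 10 and 500, the short and
#'   long tails of interest).
#' @return list of class `extension_length_summary`: `median`, `iqr_low`,
#'   `iqr_high` (Kb), and named `fraction_below` / `fraction_above` vectors.
#' @export
extension_length_summary <- function(units, cutoffs = c(10, 500)) {
  stopifnot(is.data.frame(units))
  if (nrow(units) == 0L) stop_("no units to summarize")
  if (length(unique(units$method)) > 1L) {
    stop_("units mix methods; summarize one definition at a time")
  }
  len_kb <- c(units$ext_left, units$ext_right) / 1000
  q <- stats::quantile(len_kb, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(
    median = q[2], iqr_low = q[1], iqr_high = q[3],
    n_extensions = length(len_kb),
    fraction_below = stats::setNames(
      vapply(cutoffs, function(ct) mean(len_kb < ct), numeric(1)),
      paste0("<", cutoffs, "Kb")),
    fraction_above = stats::setNames(
      vapply(cutoffs, function(ct) mean(len_kb > ct), numeric(1)),
      paste0(">", cutoffs, "Kb"))
  ), class = "extension_length_summary")
}

#' @export
print.extension_length_summary <- function(x, ...) {
  cat(sprintf("%d extensions: median %.1f Kb (IQR = %.1f-%.1f Kb)\n",
              x$n_extensions, x$median, x$iqr_low, x$iqr_high))
  for (nm in names(x$fraction_below)) {
    cat(sprintf("  %s: %.1f%%\n", nm, 100 * x$fraction_below[[nm]]))
  }
  for (nm in names(x$fraction_above)) {
    cat(sprintf("  %s: %.1f%%\n", nm, 100 * x$fraction_above[[nm]]))
  }
  invisible(x)
}

#' Boundary concordance between two gene-unit definitions
#'
#' Matches units by gene name and judges each boundary pair (left against
#' left, right against right) concordant when they differ by at most
#' `tolerance` bp. Reported per extension (fraction of single-side
#' comparisons concordant) and per gene (both sides concordant
#' simultaneously). Genes present in only one set are excluded with a
#' warning.
#'
#' @param units_a,units_b `gene_units` tables indexed by the same gene names.
#' @param tolerance bp (default 10,000).
#' @return list of class `concordance_summary` with `tolerance`,
#'   `fraction_per_extension`, `fraction_per_gene`, and `n_genes` compared.
#' @export
boundary_concordance <- function(units_a, units_b, tolerance = 10000) {
  common <- intersect(units_a$name, units_b$name)
  only <- setdiff(union(units_a$name, units_b$name), common)
  if (length(only)) {
    warn_("%d gene(s) present in one set only were excluded", length(only))
  }
  if (!length(common)) stop_("no genes in common")
  a <- units_a[match(common, units_a$name), ]
  b <- units_b[match(common, units_b$name), ]
  left_ok <- abs(a$left - b$left) <= tolerance
  right_ok <- abs(a$right - b$right) <= tolerance
  structure(list(
    tolerance = tolerance,
    fraction_per_extension = mean(c(left_ok, right_ok)),
    fraction_per_gene = mean(left_ok & right_ok),
    n_genes = length(common)
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "boundary concordance (+/- %g bp, %d genes): %.1f%% per extension, %.1f%% per gene\n",
    x$tolerance, x$n_genes, 100 * x$fraction_per_extension,
    100 * x$fraction_per_gene))
  invisible(x)
}

#' Genes whose units overlap an association region
#'
#' Any part of a unit falling inside the region suffices to count the gene.
#' Intervals are 0-based half-open, so a unit that merely touches a region
#' boundary does not overlap.
#'
#' @param units a `gene_units` table.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`
#'   (and optionally `locus`, `expert_genes`).
#' @return sorted character vector of gene names.
#' @export
genes_overlapping_region <- function(units, region) {
  region <- as.list(region)
  hit <- units$chrom == region$chrom &
    units$left < region$end & units$right > region$start
  sort(unique(units$name[hit]))
}

#' Genes whose units contain a position
#'
#' @param units a `gene_units` table.
#' @param snp list or one-row data.frame with `chrom` and `pos` (0-based;
#'   a unit `[left, right)` contains `pos` when `left <= pos < right`).
#' @return sorted character vector of gene names (several when units
#'   overlap).
#' @export
genes_containing_position <- function(units, snp) {
  snp <- as.list(snp)
  hit <- units$chrom == snp$chrom & units$left <= snp$pos & snp$pos < units$right
  sort(unique(units$name[hit]))
}

#' Score gene definitions against expert lists per association region
#'
#' For each labeled region carrying an expert gene list, and for each
#' definition, counts the extra genes (returned by the overlap rule but not
#' in the expert list) and the missing genes (expert genes whose unit does
#' not overlap the region).
#'
#' @param defs named list of `gene_units` tables, one per definition
#'   (e.g. `list(srr = ..., fixed = ...)`).
#' @param regions data.frame with columns `locus`, `chrom`, `start`, `end`
#'   and a list-column `expert_genes` (see [read_regions()]).
#' @return data.frame of class `locus_scorecard`: one row per locus and
#'   method with `n_expert`, `n_extra`, `n_missing` and comma-separated
#'   `extra_genes` / `missing_genes`.
#' @seealso [scorecard_totals()], [scorecard_concordance_table()]
#' @export
locus_scorecard <- function(defs, regions) {
  stopifnot(is.list(defs), !is.null(names(defs)), is.data.frame(regions))
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, , drop = FALSE]
    expert <- unlist(region$expert_genes)
    for (m in names(defs)) {
      got <- genes_overlapping_region(defs[[m]], region)
      extra <- setdiff(got, expert)
      missing <- setdiff(expert, got)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = region$locus, method = m, n_expert = length(expert),
        n_extra = length(extra), n_missing = length(missing),
        extra_genes = paste(extra, collapse = ","),
        missing_genes = paste(missing, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("locus_scorecard", "data.frame")
  out
}

#' Totals of a locus scorecard
#'
#' @param scorecard a [locus_scorecard()] result.
#' @return data.frame with one row per method: total expert genes (counted
#'   once per locus), total extra and total missing genes.
#' @export
scorecard_totals <- function(scorecard) {
  out <- do.call(rbind, lapply(split(scorecard, scorecard$method), function(s) {
    data.frame(method = s$method[1], n_expert = sum(s$n_expert),
               n_extra = sum(s$n_extra), n_missing = sum(s$n_missing),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fully-concordant-locus 2x2 table from a scorecard
#'
#' A locus is fully concordant under a definition when the definition's gene
#' list has no extra and no missing genes relative to the expert list. The
#' returned table has one row per method (concordant, discordant counts),
#' ready for [fisher_exact_one_tailed()].
#'
#' @param scorecard a [locus_scorecard()] result.
#' @param methods the two methods compared, row order of the table.
#' @return 2x2 integer matrix; rows = methods, columns = concordant /
#'   discordant loci.
#' @export
scorecard_concordance_table <- function(scorecard,
                                        methods = unique(scorecard$method)) {
  stopifnot(length(methods) == 2L)
  conc <- vapply(methods, function(m) {
    s <- scorecard[scorecard$method == m, ]
    sum(s$n_extra == 0L & s$n_missing == 0L)
  }, integer(1))
  n_loci <- length(unique(scorecard$locus))
  matrix(c(conc[1], n_loci - conc[1], conc[2], n_loci - conc[2]),
         nrow = 2, byrow = TRUE,
         dimnames = list(methods, c("concordant", "discordant")))
}

#' Score candidate-gene inclusion around top SNPs
#'
#' For each top SNP carrying nominated candidate genes, and for each
#' definition, a candidate is missed when no unit of that name contains the
#' SNP position.
#'
#' @param defs named list of `gene_units` tables.
#' @param snps data.frame with `rsid`, `chrom`, `pos` and list-column
#'   `candidate_genes` (see [read_snps()]).
#' @return data.frame with one row per SNP and method: `n_candidates`,
#'   `n_missed`, comma-separated `missed_genes`.
#' @export
snp_scorecard <- function(defs, snps) {
  stopifnot(is.list(defs), !is.null(names(defs)), is.data.frame(snps))
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    snp <- snps[i, , drop = FALSE]
    cand <- unlist(snp$candidate_genes)
    for (m in names(defs)) {
      got <- genes_containing_position(defs[[m]], snp)
      missed <- setdiff(cand, got)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = snp$rsid, method = m, n_candidates = length(cand),
        n_missed = length(missed),
        missed_genes = paste(missed, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 2x2 miss-comparison table with shared misses excluded
#'
#' Builds the contingency table comparing how many candidates each of two
#' definitions fails to include, after removing candidates missed by both
#' (shared misses carry no information about the difference between the
#' definitions and are excluded from both margins).
#'
#' @param miss_a,miss_b logical vectors over the same candidates: missed by
#'   definition a / b.
#' @return 2x2 integer matrix, rows = definitions, columns = missed /
#'   included, with attribute `n_shared` (excluded shared misses).
#' @export
paired_miss_table <- function(miss_a, miss_b) {
  stopifnot(length(miss_a) == length(miss_b))
  keep <- !(miss_a & miss_b)
  n <- sum(keep)
  tab <- matrix(c(sum(miss_a[keep]), n - sum(miss_a[keep]),
                  sum(miss_b[keep]), n - sum(miss_b[keep])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("missed", "included")))
  attr(tab, "n_shared") <- sum(miss_a & miss_b)
  tab
}

#' One-tailed Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric tail probability with all margins fixed. Writing the
#' table as rows = definitions and `a` the top-left cell, the null
#' distribution of `a` is hypergeometric; `direction = "row1_lower"` sums
#' `P(X <= a)` and `"row1_higher"` sums `P(X >= a)`. Computed with
#' [stats::phyper()] (log-stable, relative error well below 1e-12).
#' Degenerate margins (an empty row or column) return 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @param direction which tail of the top-left cell to sum.
#' @return the exact tail probability, in (0, 1].
#' @export
fisher_exact_one_tailed <- function(table,
                                    direction = c("row1_lower", "row1_higher")) {
  direction <- match.arg(direction)
  if (!is.matrix(table)) {
    if (length(table) != 4L) stop_("table must be 2x2 or length-4 c(a,b,c,d)")
    table <- matrix(as.numeric(table), nrow = 2, byrow = TRUE)
  }
  if (!all(dim(table) == c(2L, 2L))) stop_("table must be 2x2")
  x <- as.numeric(table)
  if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop_("table entries must be non-negative integers")
  }
  if (sum(x) == 0) stop_("table has no observations")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warn_("degenerate margin in 2x2 table; p = 1")
    return(1)
  }
  if (direction == "row1_lower") {
    stats::phyper(a, r1, r2, c1)
  } else {
    stats::phyper(a - 1, r1, r2, c1, lower.tail = FALSE)
  }
}

#' Read association regions (BED4 + optional expert gene lists)
#'
#' @param path BED4 file: chrom, start, end, locus label.
#' @param expert_path optional tab-delimited side file mapping locus label
#'   to a comma-separated expert gene list; loci absent from it get an empty
#'   list.
#' @param chrom_aliases as in [read_genes()].
#' @return data.frame with `locus`, `chrom`, `start`, `end` and list-column
#'   `expert_genes`.
#' @export
read_regions <- function(path, expert_path = NULL, chrom_aliases = NULL) {
  if (!file.exists(path)) stop_("region file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop_("region file needs BED4 columns")
  df <- data.frame(locus = raw[[4]], chrom = resolve_chroms(raw[[1]], chrom_aliases, path),
                   start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop_("region with start >= end")
  expert <- rep(list(character()), nrow(df))
  if (!is.null(expert_path)) {
    ex <- utils::read.table(expert_path, sep = "\t", header = FALSE,
                            colClasses = "character", comment.char = "#",
                            quote = "", stringsAsFactors = FALSE)
    lists <- strsplit(ex[[2]], ",", fixed = TRUE)
    at <- match(df$locus, ex[[1]])
    expert[!is.na(at)] <- lists[at[!is.na(at)]]
  }
  df$expert_genes <- expert
  df
}

#' Read top-SNP positions
#'
#' @param path tab-delimited: chrom, pos, rsid, and optionally a
#'   comma-separated candidate gene list in column 4.
#' @param one_based set `TRUE` for 1-based positions.
#' @param chrom_aliases as in [read_genes()].
#' @return data.frame with `rsid`, `chrom`, `pos` and list-column
#'   `candidate_genes`.
#' @export
read_snps <- function(path, one_based = FALSE, chrom_aliases = NULL) {
  if (!file.exists(path)) stop_("SNP file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", fill = TRUE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop_("SNP file needs columns chrom, pos, rsid")
  pos <- as.numeric(raw[[2]])
  if (anyNA(pos) || any(pos < 0)) stop_("bad SNP position")
  if (one_based) pos <- pos - 1
  df <- data.frame(rsid = raw[[3]],
                   chrom = resolve_chroms(raw[[1]], chrom_aliases, path),
                   pos = pos, stringsAsFactors = FALSE)
  df$candidate_genes <- if (ncol(raw) >= 4L) {
    strsplit(ifelse(is.na(raw[[4]]) | raw[[4]] == "", "", raw[[4]]), ",",
             fixed = TRUE)
  } else rep(list(character()), nrow(df))
  df
}
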