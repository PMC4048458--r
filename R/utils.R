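# Internal helpers shared across modules.

# Run `expr` with a temporarily fixed RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Canonical chromosome naming: "1".."22" -> "chr1".."chr22", case-insensitive
# "chr" prefix honoured, extra names resolved through `aliases`
# (named character vector, names = input, values = canonical).
# Unresolvable names are returned as NA.
normalize_chrom <- function(x, aliases = NULL) {
  x <- as.character(x)
  out <- x
  if (!is.null(aliases)) {
    hit <- match(out, names(aliases))
    out[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  bare <- sub("^[Cc][Hh][Rr]", "", out)
  known <- bare %in% c(as.character(1:22), "X", "Y", "M", "MT")
  out[known] <- paste0("chr", sub("^MT$", "M", bare[known]))
  out[!known & is.na(match(x, names(aliases)))] <- NA_character_
  out
}

is_autosome <- function(chrom) {
  grepl("^chr([1-9]|1[0-9]|2[0-2])$", chrom)
}

# Sort key giving natural chromosome order (chr1, chr2, ..., chr22, chrX, ...).
# Unknown names sort after known ones, alphabetically.
chrom_rank <- function(chrom) {
  bare <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(bare))
  r <- ifelse(!is.na(num), num,
    ifelse(bare == "X", 23L, ifelse(bare == "Y", 24L, ifelse(bare == "M", 25L, NA_integer_))))
  ifelse(is.na(r), 1000L + as.integer(factor(chrom)), r)
}

# Order rows by chromosome (natural order), then by `pos`, then by `name`.
genome_order <- function(chrom, pos, name = NULL) {
  if (is.null(name)) order(chrom_rank(chrom), chrom, pos)
  else order(chrom_rank(chrom), chrom, pos, name)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
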