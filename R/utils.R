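#' @keywords internal
"_PACKAGE"

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Build exon identity keys
#'
#' Exon identity is `(chrom, strand, exon_start, exon_end)` only. Flanking
#' exon coordinates are deliberately excluded: the same cassette exon
#' reported with different flanking pairs must count once in overlap
#' analyses.
#'
#' @param chrom,strand,exon_start,exon_end vectors of equal length.
#' @return character vector of keys, one per exon.
#' @export
exon_key <- function(chrom, strand, exon_start, exon_end) {
  paste(chrom, strand, exon_start, exon_end, sep = ":")
}

exon_key_of <- function(records) {
  exon_key(records$chrom, records$strand, records$exon_start, records$exon_end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("'%s' must be a single number in [%s, %s]", name, lo, hi)
  invisible(x)
}
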