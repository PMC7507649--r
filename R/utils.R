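#' @keywords internal
"_PACKAGE"

# The seven site metrics the QC stage understands, in canonical VCF INFO order.
SITE_METRICS <- c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "FS", "SOR", "DP")

#' Allele and site keys
#'
#' Compact string keys used throughout the package to index alleles
#' (`chrom:pos:ref:alt`) and sites (`chrom:pos`). Keys are the unit of exact
#' matching against panels, so they must always be built from *normalized*
#' alleles (split multiallelics, left-aligned indels, uppercase).
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref,alt Allele strings.
#' @return Character vector of keys.
#' @export
allele_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname allele_key
#' @export
site_key <- function(chrom, pos) {
  paste(chrom, pos, sep = ":")
}

#' Default autosome set
#'
#' Chromosome names treated as autosomal when none are supplied: `1..22` with
#' and without the `chr` prefix.
#'
#' @return Character vector of chromosome names.
#' @export
default_autosomes <- function() {
  c(as.character(1:22), paste0("chr", 1:22))
}

# Integer RNG seed derived from a master seed and a stream label, kept below
# 2^31 so it is always a valid R seed.
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_snv_allele <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
}

stop_popnovel <- function(...) stop(..., call. = FALSE)
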