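# Allele-count spectra across samples and SNV-site densities in fixed-size
# genomic blocks.

#' Allele-count spectrum of single-alt records
#'
#' Counts, per allele, the number of carried copies across all sample
#' genotypes. Sites where any sample lacks a genotype call are excluded and
#' tallied. Alleles recoded away by multiallelic splitting (`other_alt`)
#' contribute 0 copies to the focal allele.
#'
#' @param records List of single-alt [site_record()]s sharing a sample count.
#' @param subset Optional character vector of allele keys to restrict to.
#' @return An `allele_spectrum`: named count vector over copies `1..2N`,
#'   `n_sites_excluded_missing`, and `n_samples`.
#' @export
allele_spectrum <- function(records, subset = NULL) {
  if (!length(records))
    return(structure(list(spectrum = integer(), n_sites_excluded_missing = 0L,
                          n_samples = 0L), class = "allele_spectrum"))
  n_samp <- unique(vapply(records, function(r) length(r$samples), 0L))
  if (length(n_samp) != 1L)
    stop_popnovel("allele_spectrum: records carry different sample counts")
  if (!is.null(subset)) {
    keys <- vapply(records, function(r)
      allele_key(r$chrom, r$pos, r$ref, r$alts[1]), "")
    records <- records[keys %in% subset]
  }
  counts <- integer(2L * n_samp)
  excluded <- 0L
  for (r in records) {
    gts <- lapply(r$samples, `[[`, "gt")
    if (any(vapply(gts, anyNA, TRUE))) {
      excluded <- excluded + 1L
      next
    }
    copies <- sum(vapply(gts, function(g) sum(g == 1L), 0L))
    if (copies >= 1L) counts[copies] <- counts[copies] + 1L
  }
  structure(list(spectrum = stats::setNames(counts, seq_len(2L * n_samp)),
                 n_sites_excluded_missing = excluded, n_samples = n_samp),
            class = "allele_spectrum")
}

#' @export
print.allele_spectrum <- function(x, ...) {
  cat("<allele_spectrum> N =", x$n_samples, "samples;",
      x$n_sites_excluded_missing, "sites excluded for missing genotypes\n")
  print(x$spectrum)
  invisible(x)
}

#' SNV-site density in fixed-size chromosome blocks
#'
#' Block `i` (0-based) covers 1-based positions `[i*block_bp + 1,
#' (i+1)*block_bp]`, so a position at exactly one block size falls in the
#' first block; the final partial block is included.
#'
#' @param sites `data.frame` with `chrom` and `pos` columns (one row per
#'   site).
#' @param chrom_lengths Named vector of chromosome lengths (bp); must cover
#'   every site chromosome.
#' @param block_bp Block size in bp (default 10 Mb).
#' @return A `bin_density`: per-chromosome ordered block counts.
#' @export
bin_density <- function(sites, chrom_lengths, block_bp = 10000000L) {
  missing_chr <- setdiff(unique(sites$chrom), names(chrom_lengths))
  if (length(missing_chr))
    stop_popnovel("bin_density: no length for chromosome(s) ",
                  paste(missing_chr, collapse = ", "))
  counts <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    nb <- max(1L, as.integer(ceiling(len / block_bp)))
    p <- sites$pos[sites$chrom == cn]
    if (length(p) && any(p > len))
      stop_popnovel("bin_density: position beyond length of ", cn)
    blocks <- ((p - 1L) %/% block_bp) + 1L
    tabulate(blocks, nbins = nb)
  })
  structure(list(block_bp = block_bp,
                 counts = stats::setNames(counts, names(chrom_lengths))),
            class = "bin_density")
}

#' Flatten a bin density to a table
#'
#' @param x A [bin_density()] result.
#' @return `data.frame` with chrom, block index (0-based), start/end (1-based
#'   inclusive) and site count.
#' @export
bin_density_table <- function(x) {
  stopifnot(inherits(x, "bin_density"))
  do.call(rbind, lapply(names(x$counts), function(cn) {
    k <- seq_along(x$counts[[cn]]) - 1L
    data.frame(chrom = cn, block = k,
               start = k * x$block_bp + 1,
               end = (k + 1) * x$block_bp,
               count = x$counts[[cn]], stringsAsFactors = FALSE)
  }))
}
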