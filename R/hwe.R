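# Exact test of Hardy-Weinberg equilibrium, conditional on allele counts.

#' Hardy-Weinberg exact test
#'
#' Two-sided exact p-value for deviation from Hardy-Weinberg genotype
#' proportions: under the conditional distribution of the heterozygote count
#' given the observed allele counts, the probabilities of all heterozygote
#' configurations no more probable than the observed one are summed. A
#' monomorphic site has p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_popnovel("hwe_exact_test: negative count")
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop_popnovel("hwe_exact_test: total count is zero")
  m <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)  # minor allele count
  if (m == 0L) return(1)
  hets <- seq.int(m %% 2L, m, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_minor <- (m - h) %/% 2L
    hom_major <- n - h - hom_minor
    lfactorial(n) - lfactorial(hom_minor) - lfactorial(h) -
      lfactorial(hom_major) + h * log(2) +
      lfactorial(m) + lfactorial(2L * n - m) - lfactorial(2L * n)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Vectorised HWE exact test over genotype count rows
#'
#' @param counts Matrix or data frame with columns `n_AA, n_Aa, n_aa`.
#' @return Numeric p-value vector.
#' @export
hwe_exact_test_rows <- function(counts) {
  counts <- as.matrix(counts)
  vapply(seq_len(nrow(counts)), function(i)
    hwe_exact_test(counts[i, 1L], counts[i, 2L], counts[i, 3L]), 0)
}
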