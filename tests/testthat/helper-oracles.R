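# Independent oracles used to validate the implementation by a second route.

# Apply an anchored (pos, ref, alt) edit to a genome string.
apply_edit <- function(G, pos, ref, alt) {
  paste0(substr(G, 1, pos - 1), alt, substr(G, pos + nchar(ref), nchar(G)))
}

# Exhaustive-shift left-alignment oracle: enumerate every anchored indel
# spelling (pos', ref', alt') whose edited sequence equals that of the input
# spelling, and return the one with the smallest position. Pure string
# comparison; independent of the trimming algorithm.
oracle_leftmost_indel <- function(G, pos, ref, alt) {
  target <- apply_edit(G, pos, ref, alt)
  d <- nchar(ref) - nchar(alt)
  stopifnot(d != 0)
  n <- nchar(G)
  for (p in seq_len(n)) {
    if (d > 0) {                     # deletion of d bases after anchor p
      if (p + d > n) next
      cand <- paste0(substr(G, 1, p), substr(G, p + d + 1, n))
      if (cand == target)
        return(list(pos = p, ref = substr(G, p, p + d), alt = substr(G, p, p)))
    } else {                         # insertion of |d| bases after anchor p
      ins <- substr(target, p + 1, p - d)
      cand <- paste0(substr(G, 1, p), ins, substr(G, p + 1, n))
      if (cand == target)
        return(list(pos = p, ref = substr(G, p, p),
                    alt = paste0(substr(G, p, p), ins)))
    }
  }
  stop("oracle_leftmost_indel: no equivalent spelling found")
}

# HWE enumeration oracle via binomial coefficients (no factorial recurrences
# shared with the implementation).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (m == 0) return(1)
  hets <- seq(m %% 2, m, by = 2)
  probs <- vapply(hets, function(h) {
    hom_minor <- (m - h) / 2
    choose(n, hom_minor) * choose(n - hom_minor, h) * 2^h / choose(2 * n, m)
  }, 0)
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hets)]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Brute-force precedence: explicit pairwise comparison loop.
oracle_resolve <- function(classes, ladder) {
  best <- classes[1]
  for (cl in classes)
    if (match(cl, ladder) < match(best, ladder)) best <- cl
  best
}

# Naive per-position mask membership scan over the raw (unmerged) intervals.
oracle_in_mask <- function(intervals, chrom, pos) {
  hit <- intervals$chrom == chrom & intervals$start <= (pos - 1) &
    (pos - 1) < intervals$end
  any(hit)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

lookup_from_string <- function(G, chrom = "chr1") {
  function(ch, p) substr(G, p, p)
}
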