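# Functional characterisation of SNV alleles against transcript models, with
# fixed precedence ladders for sequence class and exonic effect.

#' Precedence ladders
#'
#' Sequence classes and exonic effect classes in decreasing precedence.
#' Within the top tier, exonic ranks above splicing so that every allele
#' resolves to a unique class.
#'
#' @name precedence
NULL

#' @rdname precedence
#' @export
ANNOTATION_CLASSES <- c("exonic", "splicing", "ncRNA_exonic", "ncRNA_splicing",
                        "UTR5", "UTR3", "intronic", "ncRNA_intronic",
                        "upstream", "downstream", "intergenic")

#' @rdname precedence
#' @export
EFFECT_CLASSES <- c("stop_gain", "stop_loss", "nonsynonymous", "synonymous",
                    "unknown")

#' Construct a transcript model
#'
#' Coordinates are 1-based inclusive; exons must be sorted and
#' non-overlapping, and the CDS must lie within the exon span for coding
#' transcripts.
#'
#' @param transcript Transcript id.
#' @param gene Gene symbol.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of exon bounds.
#' @param cds_start,cds_end CDS bounds (`NA` for non-coding).
#' @param coding Logical; protein-coding transcript.
#' @return A `gene_model` object.
#' @export
gene_model <- function(transcript, gene, chrom, strand, exon_starts, exon_ends,
                       cds_start = NA, cds_end = NA, coding = !is.na(cds_start)) {
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) != length(exon_ends) || !length(exon_starts))
    stop_popnovel("gene_model: exon bounds malformed")
  if (any(exon_starts > exon_ends)) stop_popnovel("gene_model: exon start > end")
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(exon_starts[-1] <= exon_ends[-length(exon_ends)]))
    stop_popnovel("gene_model: exons must be sorted and non-overlapping")
  if (!strand %in% c("+", "-")) stop_popnovel("gene_model: strand must be + or -")
  if (coding) {
    if (is.na(cds_start) || is.na(cds_end) || cds_start > cds_end)
      stop_popnovel("gene_model: coding transcript needs cds_start <= cds_end")
    if (cds_start < exon_starts[1] || cds_end > exon_ends[length(exon_ends)])
      stop_popnovel("gene_model: CDS outside exon span")
  }
  structure(list(transcript = transcript, gene = gene, chrom = as.character(chrom),
                 strand = strand, exon_starts = exon_starts,
                 exon_ends = exon_ends,
                 cds_start = if (coding) as.integer(cds_start) else NA_integer_,
                 cds_end = if (coding) as.integer(cds_end) else NA_integer_,
                 coding = coding), class = "gene_model")
}

#' Read/write the 12-column transcript table
#'
#' A refFlat-like tab-separated format with 1-based inclusive coordinates and
#' columns: transcript, gene, chrom, strand, tx_start, tx_end, cds_start,
#' cds_end, n_exons, exon_starts (comma-separated), exon_ends, coding (0/1).
#'
#' @param path File path.
#' @return `read_gene_models`: list of [gene_model()]s.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    gene_model(transcript = r$transcript, gene = r$gene, chrom = r$chrom,
               strand = r$strand,
               exon_starts = as.integer(strsplit(r$exon_starts, ",")[[1]]),
               exon_ends = as.integer(strsplit(r$exon_ends, ",")[[1]]),
               cds_start = if (r$coding == 1) r$cds_start else NA,
               cds_end = if (r$coding == 1) r$cds_end else NA,
               coding = r$coding == 1)
  })
}

#' @rdname read_gene_models
#' @param models List of [gene_model()]s.
#' @export
write_gene_models <- function(models, path) {
  tab <- do.call(rbind, lapply(models, function(m) {
    data.frame(transcript = m$transcript, gene = m$gene, chrom = m$chrom,
               strand = m$strand, tx_start = m$exon_starts[1],
               tx_end = m$exon_ends[length(m$exon_ends)],
               cds_start = if (m$coding) m$cds_start else 0L,
               cds_end = if (m$coding) m$cds_end else 0L,
               n_exons = length(m$exon_starts),
               exon_starts = paste(m$exon_starts, collapse = ","),
               exon_ends = paste(m$exon_ends, collapse = ","),
               coding = as.integer(m$coding), stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Class of a position relative to one transcript, or NA when the position is
# farther than flank_bp from the transcript span.
classify_against_transcript <- function(pos, m, flank_bp) {
  tx_start <- m$exon_starts[1]; tx_end <- m$exon_ends[length(m$exon_ends)]
  if (pos < tx_start) {
    if (tx_start - pos > flank_bp) return(NA_character_)
    return(if (m$strand == "+") "upstream" else "downstream")
  }
  if (pos > tx_end) {
    if (pos - tx_end > flank_bp) return(NA_character_)
    return(if (m$strand == "+") "downstream" else "upstream")
  }
  in_exon <- any(pos >= m$exon_starts & pos <= m$exon_ends)
  if (in_exon) {
    if (!m$coding) return("ncRNA_exonic")
    if (pos >= m$cds_start && pos <= m$cds_end) return("exonic")
    if (pos < m$cds_start) return(if (m$strand == "+") "UTR5" else "UTR3")
    return(if (m$strand == "+") "UTR3" else "UTR5")
  }
  # intronic: find the flanking exon boundaries
  prev_end <- max(m$exon_ends[m$exon_ends < pos])
  next_start <- min(m$exon_starts[m$exon_starts > pos])
  near_edge <- (pos - prev_end) <= 2L || (next_start - pos) <= 2L
  if (m$coding) {
    if (near_edge) "splicing" else "intronic"
  } else {
    if (near_edge) "ncRNA_splicing" else "ncRNA_intronic"
  }
}

#' Annotate one SNV allele against all transcripts
#'
#' Assigns a sequence class per overlapping or flanking transcript: exonic
#' (CDS), UTR5/UTR3, splicing (first or last two bases of an intron of a
#' coding transcript), intronic, the ncRNA analogues for non-coding
#' transcripts, and upstream/downstream within `flank_bp` of the transcript
#' span on the strand-appropriate side. An allele touching no transcript is
#' intergenic.
#'
#' @param allele List or one-row data frame with `chrom, pos, ref, alt`
#'   (a single-base substitution).
#' @param models List of [gene_model()]s.
#' @param flank_bp Flank distance for upstream/downstream (default 1000).
#' @return `data.frame` with one row per qualifying transcript (columns
#'   `transcript, gene, class, coding`); a single `intergenic` row with `NA`
#'   transcript when none qualifies.
#' @export
annotate_allele <- function(allele, models, flank_bp = 1000L) {
  if (!is_snv_allele(allele$ref, allele$alt))
    stop_popnovel("annotate_allele: only single-base substitutions are supported")
  rows <- list()
  for (m in models) {
    if (m$chrom != allele$chrom) next
    cls <- classify_against_transcript(allele$pos, m, flank_bp)
    if (!is.na(cls))
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = m$transcript, gene = m$gene, class = cls,
        coding = m$coding, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(transcript = NA_character_, gene = NA_character_,
                      class = "intergenic", coding = FALSE,
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# CDS genomic positions of a coding transcript, in translation order
# (5' -> 3' of the mRNA).
cds_positions <- function(m) {
  segs <- mapply(function(s, e) {
    s2 <- max(s, m$cds_start); e2 <- min(e, m$cds_end)
    if (s2 > e2) integer() else s2:e2
  }, m$exon_starts, m$exon_ends, SIMPLIFY = FALSE)
  pos <- unlist(segs)
  if (m$strand == "-") rev(pos) else pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Exonic effect of an SNV within a coding transcript
#'
#' Translates the codon containing the allele before and after substitution
#' with the standard genetic code, complementing for minus-strand
#' transcripts. `stop_gain` when the new codon is a stop and the old is not,
#' `stop_loss` for the reverse, `synonymous` for an identical amino acid,
#' otherwise `nonsynonymous`; `unknown` when the codon is incomplete at a
#' CDS edge.
#'
#' @param allele List with `chrom, pos, ref, alt` (SNV inside the CDS).
#' @param model A coding [gene_model()].
#' @param genome_lookup Function `(chrom, pos) -> base` (see
#'   [make_genome_lookup()]).
#' @return One of [EFFECT_CLASSES].
#' @export
effect_of <- function(allele, model, genome_lookup) {
  if (!isTRUE(model$coding)) stop_popnovel("effect_of: model is non-coding")
  pos <- as.integer(allele$pos)
  ref_base <- toupper(genome_lookup(allele$chrom, pos))
  if (ref_base != toupper(allele$ref))
    stop_popnovel("effect_of: reference base mismatch at ", allele$chrom, ":",
                  pos, " (genome ", ref_base, ", allele ref ", allele$ref, ")")
  cpos <- cds_positions(model)
  i <- match(pos, cpos)
  if (is.na(i)) stop_popnovel("effect_of: allele not in CDS of ", model$transcript)
  codon_idx <- (i - 1L) %/% 3L
  span <- (codon_idx * 3L + 1L):(codon_idx * 3L + 3L)
  if (any(span > length(cpos))) return("unknown")  # incomplete terminal codon
  fetch <- function(p) toupper(genome_lookup(allele$chrom, p))
  bases <- vapply(cpos[span], fetch, "")
  alt_base <- toupper(allele$alt)
  if (model$strand == "-") {
    bases <- COMPLEMENT[bases]
    alt_base <- COMPLEMENT[alt_base]
  }
  old_codon <- paste(bases, collapse = "")
  bases[span == i] <- alt_base
  new_codon <- paste(bases, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  if (!old_codon %in% names(gc) || !new_codon %in% names(gc)) return("unknown")
  old_aa <- gc[[old_codon]]; new_aa <- gc[[new_codon]]
  if (old_aa == new_aa) return("synonymous")
  if (new_aa == "*") return("stop_gain")
  if (old_aa == "*") return("stop_loss")
  "nonsynonymous"
}

#' Reference-genome base lookup
#'
#' Builds a `(chrom, pos) -> base` accessor from a FASTA file or a named
#' character vector of chromosome sequences.
#'
#' @param x FASTA path or named character vector.
#' @return Function of `(chrom, pos)` returning one uppercase base.
#' @export
make_genome_lookup <- function(x) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x)
    stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else x
  force(seqs)
  function(chrom, pos) {
    s <- seqs[[chrom]]
    if (is.null(s) || pos < 1L || pos > nchar(s))
      stop_popnovel("genome lookup out of range: ", chrom, ":", pos)
    toupper(substr(s, pos, pos))
  }
}

#' Resolve multiple annotations to a single class and effect
#'
#' The resolved class is the highest-precedence class across transcripts;
#' the resolved effect is the highest-precedence effect across coding-exonic
#' annotations, reported only when the resolved class is exonic. The result
#' is invariant to annotation order and duplication.
#'
#' @param annotations `data.frame` with a `class` column and optionally an
#'   `effect` column (per-transcript effects, `NA` where not applicable).
#' @return List with `class` and `effect` (`NA` unless class is exonic).
#' @export
resolve_precedence <- function(annotations) {
  if (!nrow(annotations)) stop_popnovel("resolve_precedence: empty annotation list")
  idx <- match(annotations$class, ANNOTATION_CLASSES)
  if (anyNA(idx)) stop_popnovel("resolve_precedence: unknown class value")
  cls <- ANNOTATION_CLASSES[min(idx)]
  eff <- NA_character_
  if (cls == "exonic" && "effect" %in% names(annotations)) {
    effs <- annotations$effect[annotations$class == "exonic" &
                               !is.na(annotations$effect)]
    if (length(effs)) eff <- EFFECT_CLASSES[min(match(effs, EFFECT_CLASSES))]
  }
  list(class = cls, effect = eff)
}

#' Annotate a set of normalized SNV alleles
#'
#' Convenience wrapper: per-transcript annotation, per-transcript exonic
#' effects where a genome is supplied, and precedence resolution.
#'
#' @param alleles `data.frame` with `chrom, pos, ref, alt` rows (SNVs).
#' @param models List of [gene_model()]s.
#' @param genome_lookup Optional base lookup for effect calls.
#' @param flank_bp See [annotate_allele()].
#' @return `data.frame`: the input plus `key`, resolved `class` and `effect`.
#' @export
annotate_alleles <- function(alleles, models, genome_lookup = NULL,
                             flank_bp = 1000L) {
  models_by_tx <- stats::setNames(models, vapply(models, `[[`, "", "transcript"))
  out <- alleles
  out$key <- allele_key(alleles$chrom, alleles$pos, alleles$ref, alleles$alt)
  out$class <- rep(NA_character_, nrow(out))
  out$effect <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(alleles))) {
    al <- as.list(alleles[i, ])
    ann <- annotate_allele(al, models, flank_bp = flank_bp)
    ann$effect <- NA_character_
    if (!is.null(genome_lookup)) {
      for (j in seq_len(nrow(ann))) {
        if (!is.na(ann$transcript[j]) && ann$class[j] == "exonic")
          ann$effect[j] <- effect_of(al, models_by_tx[[ann$transcript[j]]],
                                     genome_lookup)
      }
    }
    res <- resolve_precedence(ann)
    out$class[i] <- res$class; out$effect[i] <- res$effect
  }
  out
}

#' Summarise resolved classes across allele subsets
#'
#' @param results Output of [annotate_alleles()] (needs `key`, `class`,
#'   `effect`).
#' @param subsets Named list of allele-key character vectors; `NULL` entries
#'   mean "all alleles". Default is the single subset `all`.
#' @return Long `data.frame`: subset, ladder (`sequence_class` /
#'   `exonic_effect`), level, count, pct. Percentages are over subset alleles
#'   for sequence classes and over exonic subset alleles for effects; empty
#'   subsets yield zero counts, not an error.
#' @export
summarize_classes <- function(results, subsets = list(all = NULL)) {
  rows <- list()
  for (nm in names(subsets)) {
    keys <- subsets[[nm]]
    sub <- if (is.null(keys)) results else results[results$key %in% keys, , drop = FALSE]
    n <- nrow(sub)
    cls_counts <- table(factor(sub$class, levels = ANNOTATION_CLASSES))
    rows[[length(rows) + 1L]] <- data.frame(
      subset = nm, ladder = "sequence_class", level = ANNOTATION_CLASSES,
      count = as.integer(cls_counts),
      pct = if (n) 100 * as.integer(cls_counts) / n else 0,
      stringsAsFactors = FALSE)
    ex <- sub[sub$class == "exonic" & !is.na(sub$effect), , drop = FALSE]
    eff_counts <- table(factor(ex$effect, levels = EFFECT_CLASSES))
    rows[[length(rows) + 1L]] <- data.frame(
      subset = nm, ladder = "exonic_effect", level = EFFECT_CLASSES,
      count = as.integer(eff_counts),
      pct = if (nrow(ex)) 100 * as.integer(eff_counts) / nrow(ex) else 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
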