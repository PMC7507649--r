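# Transcript annotation, codon effects and precedence resolution.

# A deterministic two-transcript toy locus:
#   TXC (+, coding): exons 101-200, 301-400; CDS 131-370
#   TXN (-, non-coding): exons 1001-1100, 1201-1300
toy_models <- function() {
  list(gene_model("TXC", "GC", "chr1", "+", c(101L, 301L), c(200L, 400L),
                  cds_start = 131L, cds_end = 370L, coding = TRUE),
       gene_model("TXN", "GN", "chr1", "-", c(1001L, 1201L), c(1100L, 1300L),
                  coding = FALSE))
}

test_that("positional classes follow the transcript structure", {
  m <- toy_models()
  cls <- function(pos) resolve_precedence(annotate_allele(
    list(chrom = "chr1", pos = pos, ref = "A", alt = "C"), m))$class
  expect_equal(cls(150L), "exonic")
  expect_equal(cls(110L), "UTR5")
  expect_equal(cls(390L), "UTR3")
  expect_equal(cls(201L), "splicing")      # intron base 1
  expect_equal(cls(202L), "splicing")      # intron base 2
  expect_equal(cls(203L), "intronic")      # intron base 3
  expect_equal(cls(299L), "splicing")      # last two intron bases
  expect_equal(cls(1050L), "ncRNA_exonic")
  expect_equal(cls(1101L), "ncRNA_splicing")
  expect_equal(cls(1150L), "ncRNA_intronic")
  expect_equal(cls(50L), "upstream")       # within 1 kb, 5' of + transcript
  expect_equal(cls(900L), "downstream")    # 3' flank of TXC (+) ...
  expect_equal(cls(1350L), "upstream")     # ... and 3' coords of TXN (-)
  expect_equal(cls(5000L), "intergenic")
  expect_error(annotate_allele(list(chrom = "chr1", pos = 1, ref = "AT",
                                    alt = "A"), m), "single-base")
})

test_that("flanking classes respect the flank distance", {
  m <- toy_models()
  far <- annotate_allele(list(chrom = "chr1", pos = 10000L, ref = "A",
                              alt = "C"), m, flank_bp = 1000L)
  expect_equal(far$class, "intergenic")
  near <- annotate_allele(list(chrom = "chr1", pos = 10000L, ref = "A",
                               alt = "C"), m, flank_bp = 10000L)
  expect_true("downstream" %in% near$class)
})

test_that("codon effects: canonical plus- and minus-strand cases", {
  # plus strand: genome CDS 1-9; codon 2 GCT at 4..6
  Gp <- paste0("ATG", "GCT", "TAA")
  mp <- gene_model("T+", "G", "c", "+", 1L, 9L, 1L, 9L, coding = TRUE)
  lk <- function(ch, p) substr(Gp, p, p)
  eff <- function(pos, ref, alt, m, l)
    effect_of(list(chrom = "c", pos = pos, ref = ref, alt = alt), m, l)
  expect_equal(eff(6L, "T", "C", mp, lk), "synonymous")     # GCT -> GCC (Ala)
  expect_equal(eff(4L, "G", "A", mp, lk), "nonsynonymous")  # GCT -> ACT
  expect_equal(eff(9L, "A", "G", mp, lk), "synonymous")     # TAA -> TAG, both stop
  expect_equal(eff(7L, "T", "C", mp, lk), "stop_loss")      # TAA -> CAA (Gln)

  # minus strand: mRNA codon TAT from genomic ATA at 7..9; third codon
  # position is genomic position 7; A->T makes mRNA TAA (stop)
  Gm <- paste0("CAT", "GGG", "ATA")     # mRNA: TAT CCC ATG reversed...
  mm <- gene_model("T-", "G", "c", "-", 1L, 9L, 1L, 9L, coding = TRUE)
  lkm <- function(ch, p) substr(Gm, p, p)
  expect_equal(eff(7L, "A", "T", mm, lkm), "stop_gain")     # TAT -> TAA
  # reference mismatch is a data-inconsistency error
  expect_error(eff(7L, "C", "T", mm, lkm), "mismatch")
})

test_that("incomplete terminal codons are unknown", {
  G <- paste0("ATG", "GC")             # CDS length 5
  m <- gene_model("T", "G", "c", "+", 1L, 5L, 1L, 5L, coding = TRUE)
  lk <- function(ch, p) substr(G, p, p)
  expect_equal(effect_of(list(chrom = "c", pos = 5L, ref = "C", alt = "T"),
                         m, lk), "unknown")
})

test_that("effects agree with the whole-CDS retranslation oracle", {
  cfg <- simulation_config(seed = 123L, gene_model_count = 10L)
  gm <- simulate_gene_models(cfg)
  lk <- make_genome_lookup(gm$genome)
  coding <- Filter(function(m) m$coding, gm$models)
  set.seed(124)
  n_checked <- 0
  while (n_checked < 200) {
    m <- coding[[sample(length(coding), 1)]]
    cpos <- popnovel:::cds_positions(m)
    p <- sample(cpos, 1)
    ref <- lk(m$chrom, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    al <- list(chrom = m$chrom, pos = p, ref = ref, alt = alt)
    expect_equal(effect_of(al, m, lk),
                 effect_by_retranslation(al, m, gm$genome))
    n_checked <- n_checked + 1
  }
})

test_that("precedence resolution matches brute force and is order-invariant", {
  set.seed(125)
  for (i in 1:200) {
    classes <- sample(ANNOTATION_CLASSES, sample(1:6, 1), replace = TRUE)
    ann <- data.frame(class = classes, stringsAsFactors = FALSE)
    got <- resolve_precedence(ann)$class
    expect_equal(got, oracle_resolve(classes, ANNOTATION_CLASSES))
    # order and duplication invariance
    shuf <- data.frame(class = sample(rep(classes, 2)))
    expect_equal(resolve_precedence(shuf)$class, got)
  }
  expect_equal(resolve_precedence(data.frame(class = c("intronic", "exonic")))$class,
               "exonic")
  expect_equal(resolve_precedence(data.frame(class = c("UTR5", "upstream")))$class,
               "UTR5")
  # effect reported only for exonic resolutions, by effect precedence
  ann <- data.frame(class = c("exonic", "exonic", "intronic"),
                    effect = c("synonymous", "stop_gain", NA))
  expect_equal(resolve_precedence(ann)$effect, "stop_gain")
  ann2 <- data.frame(class = c("splicing", "intronic"),
                     effect = c(NA, NA))
  expect_true(is.na(resolve_precedence(ann2)$effect))
})

test_that("planted sequence classes and effects are recovered", {
  cfg <- simulation_config(seed = 126L, n_exonic_known = 150L,
                           n_exonic_novel = 40L, n_per_other_class = 8L)
  gm <- simulate_gene_models(cfg)
  lk <- make_genome_lookup(gm$genome)
  res <- annotate_alleles(gm$alleles[, c("chrom", "pos", "ref", "alt")],
                          gm$models, genome_lookup = lk)
  expect_equal(res$class, gm$alleles$class)
  ex <- gm$alleles$class == "exonic"
  expect_equal(res$effect[ex], gm$alleles$effect[ex])
})

test_that("class summaries normalise within subsets and recover enrichment", {
  cfg <- simulation_config(seed = 127L)
  gm <- simulate_gene_models(cfg)
  lk <- make_genome_lookup(gm$genome)
  res <- annotate_alleles(gm$alleles[, c("chrom", "pos", "ref", "alt")],
                          gm$models, genome_lookup = lk)
  subsets <- list(all = NULL,
                  novel = gm$alleles$key[gm$alleles$stratum %in% "novel"],
                  single = gm$alleles$key[1])
  tab <- summarize_classes(res, subsets)
  for (nm in names(subsets)) {
    seq_rows <- tab[tab$subset == nm & tab$ladder == "sequence_class", ]
    expect_equal(sum(seq_rows$pct), 100)
    expect_equal(sum(seq_rows$count),
                 if (is.null(subsets[[nm]])) nrow(res)
                 else length(subsets[[nm]]))
  }
  one <- tab[tab$subset == "single" & tab$ladder == "sequence_class", ]
  expect_equal(max(one$pct), 100)

  # planted stop-gain enrichment in the novel stratum (rate ratio ~ 4)
  eff <- function(sub) {
    rows <- tab[tab$subset == sub & tab$ladder == "exonic_effect", ]
    rows$pct[rows$level == "stop_gain"] / 100
  }
  r_novel <- eff("novel"); r_all <- eff("all")
  expect_gt(r_novel, r_all)                     # enrichment direction
  expect_gt(r_novel / r_all, 1.5)               # within binomial error of 4
  expect_lt(r_novel / r_all, 12)
  # planted counts themselves within exact binomial 99.5% bounds
  n_novel_ex <- sum(gm$alleles$stratum %in% "novel" & gm$alleles$class == "exonic")
  k_novel <- sum(gm$alleles$effect %in% "stop_gain" &
                 gm$alleles$stratum %in% "novel")
  ci <- stats::qbinom(c(0.0025, 0.9975), n_novel_ex, cfg$novel_nonsense_rate)
  expect_gte(k_novel, ci[1]); expect_lte(k_novel, ci[2])

  # empty subsets yield zero rows, not an error
  none <- summarize_classes(res, list(none = character()))
  expect_true(all(none$count == 0))
})
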