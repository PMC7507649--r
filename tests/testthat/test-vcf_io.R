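# I/O, multiallelic splitting, left alignment and mask handling.

strip_names <- function(recs) {
  lapply(recs, function(r) { r$metrics <- unname(r$metrics); r })
}

random_records <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    type <- sample(c("snv", "multi", "indel"), 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alts <- switch(type,
      snv = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
      multi = sample(setdiff(c("A", "C", "G", "T"), ref), 2),
      indel = paste0(ref, paste(sample(c("A", "C", "G", "T"), 2, TRUE),
                                collapse = "")))
    mets <- c(QD = round(runif(1, 0, 30), 3), MQ = round(runif(1, 20, 60), 3),
              FS = round(runif(1, 0, 10), 3), DP = round(runif(1, 10, 90), 3))
    if (runif(1) < 0.3) mets <- mets[-1]  # QD sometimes absent
    n_all <- length(alts) + 1L
    gts <- replicate(3, if (runif(1) < 0.1) NA
                     else sort(sample(0:(n_all - 1), 2, TRUE)), simplify = FALSE)
    samples <- lapply(gts, function(g)
      sample_call(gt = g, ad = sample(0:40, n_all, TRUE), dp = sample(0:60, 1),
                  gq = if (runif(1) < 0.2) NULL else sample(1:99, 1),
                  rgq = if (runif(1) < 0.5) NULL else sample(1:99, 1)))
    site_record(chrom = sample(c("chr1", "chr2"), 1), pos = 1000L + i * 7L,
                ref = ref, alts = alts,
                qual = round(runif(1, 10, 999), 1), metrics = mets,
                samples = samples)
  })
}

test_that("VCF write/read round-trips records field for field", {
  recs <- random_records(100, seed = 11)
  plain <- withr::local_tempfile(fileext = ".vcf")
  gz <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(recs, plain)
  write_vcf(recs, gz)
  back_plain <- read_vcf(plain)
  back_gz <- read_vcf(gz)
  expect_length(back_plain, 100)
  expect_equal(strip_names(back_plain), strip_names(recs), tolerance = 1e-9)
  # gzip and plain encodings parse to identical structures
  attr(back_plain, "sample_names") <- NULL
  attr(back_gz, "sample_names") <- NULL
  expect_identical(back_gz, back_plain)
})

test_that("missing FORMAT/INFO values map to missing, not zero", {
  rec <- make_rec(metrics = c(MQ = 60, DP = 30), gqs = list(NULL))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(list(rec), path)
  line <- grep("^chr", readLines(path), value = TRUE)
  expect_match(line, ":\\.:")  # null GQ emitted as "."
  back <- read_vcf(path)[[1]]
  expect_false("QD" %in% names(back$metrics))
  expect_null(back$samples[[1]]$gq)
})

test_that("empty record list yields a valid header-only VCF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(list(), path)
  expect_true(any(grepl("^#CHROM", readLines(path))))
  expect_length(suppressWarnings(read_vcf(path)), 0)
})

test_that("a 1-record 3-sample VCF reads into one record with 3 calls", {
  rec <- make_rec(gts = list(c(0L, 1L), c(1L, 1L), c(0L, 0L)))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(list(rec), path)
  back <- read_vcf(path)
  expect_length(back, 1)
  expect_length(back[[1]]$samples, 3)
})

test_that("multiallelic split recodes genotypes relative to the kept alt", {
  rec <- make_rec(ref = "A", alts = c("C", "T"),
                  gts = list(c(1L, 2L)), ads = list(c(2L, 10L, 12L)))
  out <- split_multiallelic(rec)
  expect_length(out, 2)
  # C record: one C allele, other alt flagged
  expect_equal(sum(out[[1]]$samples[[1]]$gt == 1L), 1)
  expect_true(out[[1]]$samples[[1]]$other_alt)
  expect_equal(out[[1]]$samples[[1]]$ad, c(2L, 10L))
  # T record: one T allele
  expect_equal(sum(out[[2]]$samples[[1]]$gt == 1L), 1)
  expect_equal(out[[2]]$samples[[1]]$ad, c(2L, 12L))
  # biallelic input is returned unchanged
  bi <- make_rec()
  expect_identical(split_multiallelic(bi), list(bi))
})

test_that("splitting conserves the total non-reference allele count", {
  set.seed(21)
  for (i in 1:5) {
    n_alt <- sample(2:3, 1)
    alts <- sample(setdiff(c("A", "C", "G", "T"), "A"), n_alt)
    gts <- replicate(4, sort(sample(0:n_alt, 2, TRUE)), simplify = FALSE)
    rec <- make_rec(ref = "A", alts = alts, gts = gts,
                    ads = replicate(4, sample(0:30, n_alt + 1, TRUE),
                                    simplify = FALSE))
    total_nonref <- sum(unlist(gts) > 0)
    split_total <- sum(vapply(split_multiallelic(rec), function(r)
      sum(vapply(r$samples, function(s) sum(s$gt == 1L), 0L)), 0L))
    expect_equal(split_total, total_nonref)
  }
})

test_that("left alignment is position-minimal versus the exhaustive oracle", {
  set.seed(31)
  for (i in 1:120) {
    # repeat-rich context: random flanks around a tandem repeat
    unit <- rand_seq(sample(1:3, 1))
    # leading Ns anchor the context so left shifts terminate inside the string
    G <- paste0("NN", rand_seq(sample(5:15, 1)),
                strrep(unit, sample(3:6, 1)),
                rand_seq(sample(5:15, 1)))
    n <- nchar(G)
    # write an indel at the right edge of the repeat region
    d <- sample(1:3, 1)
    pos <- sample(seq(4, n - d - 1), 1)
    if (runif(1) < 0.5) {
      ref <- substr(G, pos, pos + d); alt <- substr(G, pos, pos)   # deletion
    } else {
      ref <- substr(G, pos, pos)
      alt <- paste0(ref, substr(G, pos + 1, pos + d))              # insertion
    }
    lk <- lookup_from_string(G)
    got <- left_align(list(chrom = "chr1", pos = pos, ref = ref, alt = alt), lk)
    exp <- oracle_leftmost_indel(G, pos, ref, alt)
    # same edit, leftmost anchored spelling
    expect_equal(apply_edit(G, got$pos, got$ref, got$alt),
                 apply_edit(G, pos, ref, alt))
    expect_equal(got$pos, exp$pos)
    # idempotence
    again <- left_align(got, lk)
    expect_identical(again, got)
  }
})

test_that("SNVs are fixed points of left alignment", {
  a <- list(chrom = "chr1", pos = 100L, ref = "C", alt = "T")
  expect_identical(left_align(a), a)
})

test_that("BED masks are 0-based half-open, merged, and match a naive scan", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t5\t20"), path)
  mask <- read_bed(path)
  expect_true(all(in_mask(mask, "chr1", 1:20)))
  expect_false(in_mask(mask, "chr1", 21))
  expect_equal(nrow(mask$regions$chr1), 1)  # overlapping lines merged
  expect_error(mask_regions("chr1", 10, 10), "start >= end")

  set.seed(41)
  start <- sample(0:5000, 1000, replace = TRUE)
  iv <- data.frame(chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                   start = start, end = start + sample(1:50, 1000, TRUE))
  mask <- mask_regions(iv$chrom, iv$start, iv$end)
  probe_pos <- sample(1:5100, 300)
  probe_chr <- sample(c("chr1", "chr2", "chr3"), 300, TRUE)
  got <- in_mask(mask, probe_chr, probe_pos)
  exp <- vapply(seq_len(300), function(i)
    oracle_in_mask(iv, probe_chr[i], probe_pos[i]), TRUE)
  expect_equal(got, exp)
})
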