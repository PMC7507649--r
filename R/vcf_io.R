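# Site/genotype data model, VCF and BED I/O, allele normalization.
#
# External coordinates follow the file standards: VCF positions are 1-based
# inclusive, BED intervals 0-based half-open. All interval arithmetic on masks
# is done half-open; conversion happens only at the API edge.

#' Construct a site record
#'
#' A `site_record` is one VCF data line: location, alleles, the site metrics
#' used by quality control, and one `sample_call` per sample.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (>= 1).
#' @param id Site identifier or `NULL`.
#' @param ref Reference allele (uppercased on input).
#' @param alts Character vector of alternative alleles (non-empty).
#' @param qual Variant quality or `NULL`.
#' @param filter Character vector of FILTER entries (empty means missing).
#' @param metrics Named numeric vector; names must be a subset of
#'   `QD, MQ, MQRankSum, ReadPosRankSum, FS, SOR, DP`. Absent metrics are
#'   simply absent keys, never `NA`.
#' @param samples List of [sample_call()] objects.
#' @return An object of class `site_record`.
#' @export
site_record <- function(chrom, pos, ref, alts, id = NULL, qual = NULL,
                        filter = character(), metrics = numeric(),
                        samples = list()) {
  rec <- structure(
    list(chrom = unname(as.character(chrom)), pos = unname(as.integer(pos)),
         id = unname(id), ref = unname(toupper(ref)),
         alts = unname(toupper(as.character(alts))), qual = unname(qual),
         filter = unname(filter), metrics = metrics, samples = samples),
    class = "site_record")
  validate_site_record(rec)
  rec
}

validate_site_record <- function(rec, where = "site_record") {
  if (rec$pos < 1L) stop_popnovel(where, ": pos must be >= 1")
  if (length(rec$alts) < 1L) stop_popnovel(where, ": at least one alt required")
  ok_dna <- function(x) nchar(x) > 0 & !grepl("[^ACGTN]", x)
  if (!ok_dna(rec$ref) || !all(ok_dna(rec$alts)))
    stop_popnovel(where, ": alleles must be nonempty strings over A,C,G,T,N")
  bad <- setdiff(names(rec$metrics), SITE_METRICS)
  if (length(bad))
    stop_popnovel(where, ": unknown metric(s) ", paste(bad, collapse = ", "))
  n_all <- length(rec$alts) + 1L
  for (s in rec$samples) {
    if (!all(is.na(s$gt)) && any(s$gt < 0L | s$gt >= n_all, na.rm = TRUE))
      stop_popnovel(where, ": genotype allele index out of range")
  }
  invisible(rec)
}

#' Construct a per-sample call
#'
#' @param gt Integer vector of two allele indices (0 = ref), or `NA` for a
#'   missing genotype.
#' @param ad Integer vector of per-allele read depths (ref first) or `NULL`.
#' @param dp,gq,rgq Integer depth / genotype quality / reference genotype
#'   quality, or `NULL` when absent.
#' @param other_alt `TRUE` when, after multiallelic splitting, this sample
#'   carries a non-reference allele other than the record's focal alt.
#' @return An object of class `sample_call`.
#' @export
sample_call <- function(gt = NA, ad = NULL, dp = NULL, gq = NULL, rgq = NULL,
                        other_alt = FALSE) {
  gt <- if (all(is.na(gt))) c(NA_integer_, NA_integer_) else as.integer(gt)
  if (any(c(ad, dp, gq, rgq) < 0)) stop_popnovel("sample_call: depths/qualities must be >= 0")
  structure(list(gt = gt, ad = ad, dp = dp, gq = gq, rgq = rgq,
                 other_alt = isTRUE(other_alt)),
            class = "sample_call")
}

parse_gt_string <- function(x) {
  if (is.na(x) || x %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
  parts <- strsplit(x, "[/|]")[[1]]
  idx <- suppressWarnings(as.integer(parts))
  if (length(idx) == 1L) idx <- c(idx, NA_integer_)  # haploid call kept as one allele
  idx[1:2]
}

format_gt <- function(gt) {
  if (all(is.na(gt))) return("./.")
  paste(ifelse(is.na(gt), ".", gt), collapse = "/")
}

num_or_null <- function(x) {
  if (is.null(x) || is.na(x) || x == ".") NULL else as.numeric(x)
}

#' Read a VCF file into site records
#'
#' Reads a plain or gzipped VCF (v4.x) via \pkg{vcfR} and converts each data
#' line into a [site_record()]. INFO metrics outside the seven QC metrics are
#' dropped; absent fields map to absent keys (INFO) or `NULL`/`NA` (FORMAT).
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return List of `site_record`s, in file order, with attribute
#'   `sample_names`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_popnovel("read_vcf: no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_popnovel("read_vcf: malformed VCF '",
                                                  path, "': ", conditionMessage(e)))
  fix <- v@fix
  n <- nrow(fix)
  samp_names <- if (ncol(v@gt) > 1L) colnames(v@gt)[-1L] else character()
  if (n == 0L) {
    recs <- list()
    attr(recs, "sample_names") <- samp_names
    return(recs)
  }
  info_mat <- sapply(SITE_METRICS, function(m)
    suppressWarnings(vcfR::extract.info(v, element = m, as.numeric = TRUE)))
  info_mat <- matrix(info_mat, nrow = n, dimnames = list(NULL, SITE_METRICS))
  fmt <- list()
  if (length(samp_names)) {
    for (el in c("GT", "AD", "DP", "GQ", "RGQ")) {
      fmt[[el]] <- tryCatch(
        vcfR::extract.gt(v, element = el, IDtoRowNames = FALSE),
        error = function(e) matrix(NA_character_, n, length(samp_names)))
    }
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    metrics <- info_mat[i, ]
    metrics <- metrics[!is.na(metrics)]
    samples <- lapply(seq_along(samp_names), function(j) {
      ad <- fmt$AD[i, j]
      ad <- if (is.na(ad)) NULL else as.integer(strsplit(ad, ",")[[1]])
      sample_call(
        gt = parse_gt_string(fmt$GT[i, j]), ad = ad,
        dp = num_or_null(fmt$DP[i, j]), gq = num_or_null(fmt$GQ[i, j]),
        rgq = num_or_null(fmt$RGQ[i, j]))
    })
    rec <- tryCatch(
      site_record(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                  id = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".") NULL else fix[i, "ID"],
                  ref = fix[i, "REF"],
                  alts = strsplit(fix[i, "ALT"], ",")[[1]],
                  qual = num_or_null(fix[i, "QUAL"]),
                  filter = if (is.na(fix[i, "FILTER"]) || fix[i, "FILTER"] == ".")
                    character() else strsplit(fix[i, "FILTER"], ";")[[1]],
                  metrics = metrics, samples = samples),
      error = function(e) stop_popnovel("read_vcf: record ", i, " of '", path,
                                        "': ", conditionMessage(e)))
    recs[[i]] <- rec
  }
  attr(recs, "sample_names") <- samp_names
  recs
}

format_num <- function(x) {
  if (is.null(x)) return(".")
  format(x, trim = TRUE, scientific = FALSE, digits = 10)
}

#' Write site records to a VCF file
#'
#' Inverse of [read_vcf()] on the supported field set:
#' `read_vcf(write_vcf(x))` reproduces `x` field for field. Output is gzipped
#' when `path` ends in `.gz`.
#'
#' @param records List of [site_record()]s with a consistent sample count.
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @param sample_names Sample column names; defaults to the `sample_names`
#'   attribute of `records` or `S1..Sn`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_names = NULL) {
  n_samp <- if (length(records)) length(records[[1]]$samples) else 0L
  if (length(records) &&
      length(unique(vapply(records, function(r) length(r$samples), 0L))) != 1L)
    stop_popnovel("write_vcf: records carry inconsistent sample counts")
  sample_names <- sample_names %||% attr(records, "sample_names") %||%
    (if (n_samp) paste0("S", seq_len(n_samp)) else character())
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=popnovel",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Site metric %s\">",
            SITE_METRICS, SITE_METRICS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=RGQ,Number=1,Type=Integer,Description=\"Reference genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (n_samp) c("FORMAT", sample_names)), collapse = "\t"))
  body <- vapply(records, function(r) {
    info <- r$metrics[intersect(SITE_METRICS, names(r$metrics))]
    info_str <- if (length(info))
      paste(paste0(names(info), "=", vapply(info, format_num, "")), collapse = ";")
    else "."
    fields <- c(r$chrom, r$pos, r$id %||% ".", r$ref, paste(r$alts, collapse = ","),
                format_num(r$qual),
                if (length(r$filter)) paste(r$filter, collapse = ";") else ".",
                info_str)
    if (n_samp) {
      calls <- vapply(r$samples, function(s) {
        paste(format_gt(s$gt),
              if (is.null(s$ad)) "." else paste(s$ad, collapse = ","),
              format_num(s$dp), format_num(s$gq), format_num(s$rgq),
              sep = ":")
      }, "")
      fields <- c(fields, "GT:AD:DP:GQ:RGQ", calls)
    }
    paste(fields, collapse = "\t")
  }, "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

# ---- multiallelic splitting -------------------------------------------------

#' Split a multiallelic site into per-allele records
#'
#' One record is returned per alternative allele. Genotypes are recoded
#' relative to the kept alt: the focal alt becomes index 1; a different
#' non-reference allele contributes 0 copies of the focal alt and is flagged
#' via the sample's `other_alt` field (it is a call, not a missing genotype).
#' AD vectors are subset to (ref, focal alt).
#'
#' @param site A [site_record()].
#' @return List of `site_record`s, each with a single alt; a biallelic input
#'   is returned as a singleton list, unchanged.
#' @export
split_multiallelic <- function(site) {
  if (length(site$alts) == 1L) return(list(site))
  lapply(seq_along(site$alts), function(j) {
    samples <- lapply(site$samples, function(s) {
      gt <- s$gt
      other <- any(!is.na(gt) & gt != 0L & gt != j)
      gt <- ifelse(is.na(gt), NA_integer_, ifelse(gt == j, 1L, 0L))
      ad <- if (is.null(s$ad) || length(s$ad) <= j) NULL else s$ad[c(1L, j + 1L)]
      sample_call(gt = gt, ad = ad, dp = s$dp, gq = s$gq, rgq = s$rgq,
                  other_alt = other)
    })
    site_record(chrom = site$chrom, pos = site$pos, id = site$id,
                ref = site$ref, alts = site$alts[j], qual = site$qual,
                filter = site$filter, metrics = site$metrics,
                samples = samples)
  })
}

# ---- left alignment ---------------------------------------------------------

#' Left-align and trim an allele to minimal representation
#'
#' Canonicalises an indel spelling: shared trailing bases are trimmed
#' (prepending the previous reference base and decrementing the position when
#' either allele would become empty), then shared leading bases are trimmed
#' while both alleles keep at least one base. The result is the unique
#' minimal, leftmost spelling; SNVs are fixed points, and the operation is
#' idempotent.
#'
#' @param allele List with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param reference_lookup Function `(chrom, pos) -> single base`, required
#'   whenever left extension is needed (i.e. for indels inside repeats).
#' @return The allele in minimal left-aligned form (same list shape).
#' @export
left_align <- function(allele, reference_lookup = NULL) {
  chrom <- allele$chrom; pos <- as.integer(allele$pos)
  ref <- toupper(allele$ref); alt <- toupper(allele$alt)
  if (ref == alt) stop_popnovel("left_align: ref == alt")
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    if (nchar(ref) == 1L && nchar(alt) == 1L) break
    if (last(ref) != last(alt)) break
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos <= 1L)
        stop_popnovel("left_align: ran off chromosome start at ", chrom, ":", pos)
      if (is.null(reference_lookup))
        stop_popnovel("left_align: reference_lookup needed to extend left at ",
                      chrom, ":", pos)
      b <- toupper(reference_lookup(chrom, pos - 1L))
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Normalize site records to atomic alleles
#'
#' Splits multiallelic records and left-aligns every (ref, alt) pair; this is
#' the single decoder used for both cohort and panel VCFs, so complex
#' 1000G-style multiallelic spellings on the two sides always agree after
#' normalization.
#'
#' @param records List of [site_record()]s.
#' @param reference_lookup See [left_align()]; may be `NULL` when all alleles
#'   are SNVs or already minimal.
#' @return `data.frame` with columns `chrom, pos, ref, alt, is_snv, key,
#'   orig_site, record_index`, one row per (record, alt) pair.
#' @export
normalize_records <- function(records, reference_lookup = NULL) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    do.call(rbind, lapply(seq_along(r$alts), function(j) {
      a <- left_align(list(chrom = r$chrom, pos = r$pos, ref = r$ref,
                           alt = r$alts[j]), reference_lookup)
      data.frame(chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), is_snv = logical(), key = character(),
                      orig_site = character(), record_index = integer()))
  }
  n_alt <- vapply(records, function(r) length(r$alts), 0L)
  out$is_snv <- is_snv_allele(out$ref, out$alt)
  out$key <- allele_key(out$chrom, out$pos, out$ref, out$alt)
  out$orig_site <- rep(vapply(records, function(r) site_key(r$chrom, r$pos), ""),
                       n_alt)
  out$record_index <- rep(seq_along(records), n_alt)
  out
}

# ---- BED masks --------------------------------------------------------------

#' Read a BED3 file into a mask
#'
#' Intervals are 0-based half-open per the BED standard and are merged per
#' chromosome on construction.
#'
#' @param path Path to a 3+ column BED file.
#' @return A `mask_regions` object: per-chromosome merged interval table.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop_popnovel("read_bed: expected >= 3 columns")
  mask_regions(tab[[1]], tab[[2]], tab[[3]])
}

#' Construct a mask from intervals
#'
#' @param chrom Chromosome per interval.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @return A `mask_regions` object.
#' @export
mask_regions <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop_popnovel("mask_regions: start >= end")
  if (any(start < 0)) stop_popnovel("mask_regions: negative start")
  by_chrom <- split(data.frame(start = start, end = end), as.character(chrom))
  merged <- lapply(by_chrom, function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  structure(list(regions = merged), class = "mask_regions")
}

#' Test 1-based positions for mask membership
#'
#' @param mask A `mask_regions` object.
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 1-based position(s).
#' @return Logical vector.
#' @export
in_mask <- function(mask, chrom, pos) {
  stopifnot(inherits(mask, "mask_regions"))
  chrom <- rep_len(as.character(chrom), length(pos))
  out <- logical(length(pos))
  for (cn in unique(chrom)) {
    d <- mask$regions[[cn]]
    sel <- chrom == cn
    if (is.null(d)) { out[sel] <- FALSE; next }
    p0 <- pos[sel] - 1L  # to 0-based
    idx <- findInterval(p0, d$start)
    out[sel] <- idx >= 1L & p0 < d$end[pmax(idx, 1L)]
  }
  out
}
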