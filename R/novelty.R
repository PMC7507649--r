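# Novelty determination of normalized SNV alleles against reference variant
# panels, honouring panel quality flags and panel chromosome exclusions.

#' Build a reference panel from a VCF
#'
#' Panel lines are split into atomic alleles and left-aligned through the same
#' normalizer as query data, so complex multiallelic spellings on the two
#' sides always agree. When `use_filter_column` is set, entries whose FILTER
#' is neither `PASS` nor missing are stored with a fail flag; by default a
#' query matching only such an entry counts as novel (the panel excludes
#' quality-failed calls).
#'
#' @param vcf_path Panel VCF path.
#' @param use_filter_column Honour the FILTER column (default `FALSE`).
#' @param excluded_chroms Chromosomes the panel does not assess (queries there
#'   are reported `not_assessed`). Panel entries on these chromosomes are
#'   dropped.
#' @param name Panel display name.
#' @param reference_lookup Optional reference-base lookup for left alignment
#'   of indel entries (see [left_align()]).
#' @return A `reference_panel` object.
#' @export
build_panel <- function(vcf_path, use_filter_column = FALSE,
                        excluded_chroms = character(), name = basename(vcf_path),
                        reference_lookup = NULL) {
  recs <- read_vcf(vcf_path)
  pass <- unlist(lapply(recs, function(r) {
    p <- length(r$filter) == 0L || identical(r$filter, "PASS")
    rep(p, length(r$alts))
  }))
  alleles <- normalize_records(recs, reference_lookup)
  keep <- !alleles$chrom %in% excluded_chroms
  reference_panel(alleles[keep, , drop = FALSE],
                  pass = if (use_filter_column) pass[keep] else rep(TRUE, sum(keep)),
                  excluded_chroms = excluded_chroms, name = name)
}

#' Construct a reference panel from normalized alleles
#'
#' @param alleles `data.frame` with `chrom, pos, ref, alt` columns.
#' @param pass Logical per-entry quality flag (`FALSE` = failed panel QC).
#' @param excluded_chroms Chromosomes the panel does not assess.
#' @param name Panel name.
#' @return A `reference_panel` object.
#' @export
reference_panel <- function(alleles, pass = rep(TRUE, nrow(alleles)),
                            excluded_chroms = character(), name = "panel") {
  stopifnot(length(pass) == nrow(alleles))
  keys <- allele_key(alleles$chrom, alleles$pos, alleles$ref, alleles$alt)
  dup <- duplicated(keys)
  structure(list(
    keys = keys[!dup],
    pass = pass[!dup],
    positions = unique(site_key(alleles$chrom, alleles$pos)),
    excluded_chroms = excluded_chroms,
    name = name), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %s: %d alleles (%d flagged fail)%s\n",
              x$name, length(x$keys), sum(!x$pass),
              if (length(x$excluded_chroms))
                paste0("; excludes ", paste(x$excluded_chroms, collapse = ","))
              else ""))
  invisible(x)
}

#' Assess query alleles for novelty against a reference panel
#'
#' An allele is `known` iff its exact normalized (chrom, pos, ref, alt)
#' matches a qualifying panel entry; alleles on the panel's excluded
#' chromosomes are `not_assessed`; everything else is `novel`. With the
#' default `treat_fail_as = "novel"`, entries flagged fail do not qualify, so
#' a query matching only a quality-failed panel call is still novel.
#'
#' Site-level summaries distinguish novel sites whose position is absent from
#' the panel (`n_novel_sites`) from sites known to the panel but carrying a
#' different allele in the query
#' (`n_sites_known_position_different_allele`).
#'
#' @param query_alleles Normalized allele `data.frame` (from
#'   [normalize_records()]): columns `chrom, pos, ref, alt` (plus optionally
#'   `orig_site` used to flag multiallelic sites).
#' @param panel A [reference_panel()].
#' @param treat_fail_as Status granted by a match to a fail-flagged entry.
#' @return A `novelty_result`: per-allele `alleles` data frame with a
#'   `status` column, and site-level counts.
#' @export
assess_novelty <- function(query_alleles, panel,
                           treat_fail_as = c("novel", "known")) {
  treat_fail_as <- match.arg(treat_fail_as)
  stopifnot(inherits(panel, "reference_panel"))
  q <- query_alleles
  q$key <- allele_key(q$chrom, q$pos, q$ref, q$alt)
  qualifying <- if (treat_fail_as == "known") panel$keys
  else panel$keys[panel$pass]
  status <- ifelse(q$chrom %in% panel$excluded_chroms, "not_assessed",
                   ifelse(q$key %in% qualifying, "known", "novel"))
  q$status <- status
  q$panel <- panel$name
  pos_keys <- site_key(q$chrom, q$pos)
  assessed <- status != "not_assessed"
  novel_pos <- unique(pos_keys[assessed & status == "novel"])
  pos_in_panel <- novel_pos %in% panel$positions
  site_tab <- if ("orig_site" %in% names(q)) table(q$orig_site) else table(pos_keys)
  multi_sites <- names(site_tab)[site_tab > 1L]
  n_novel_multi <- if ("orig_site" %in% names(q))
    length(intersect(unique(q$orig_site[assessed & status == "novel"]), multi_sites))
  else length(intersect(novel_pos, multi_sites))
  structure(list(
    alleles = q,
    n_novel_alleles = sum(status == "novel"),
    n_assessed_alleles = sum(assessed),
    n_novel_sites = sum(!pos_in_panel),
    n_sites_known_position_different_allele = sum(pos_in_panel),
    n_novel_multiallelic_sites = n_novel_multi,
    panel = panel$name), class = "novelty_result")
}

#' @export
print.novelty_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<novelty_result> vs %s: %d/%d assessed alleles novel; %d novel sites, ",
    "%d known-position/different-allele sites, %d multiallelic novel sites\n"),
    x$panel, x$n_novel_alleles, x$n_assessed_alleles, x$n_novel_sites,
    x$n_sites_known_position_different_allele, x$n_novel_multiallelic_sites))
  invisible(x)
}
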