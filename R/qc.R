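# Truth-panel-guided quality control: pre-exclusion, true/other
# classification, filter evaluation by discrimination factor, and the
# sequential QC cascade.

#' Pre-exclusion of uninformative sites
#'
#' Drops records that cannot be quality controlled: QD absent from the site
#' metrics, per-sample DP zero (or absent) for every sample, alternative-
#' allele AD zero for all alternative alleles in all samples, or location
#' outside the autosomes.
#'
#' @param records List of [site_record()]s.
#' @param autosomes Character vector of autosomal chromosome names.
#' @return Filtered list of records (attributes preserved).
#' @export
prefilter_sites <- function(records, autosomes = default_autosomes()) {
  keep <- vapply(records, function(r) {
    if (!r$chrom %in% autosomes) return(FALSE)
    if (!"QD" %in% names(r$metrics)) return(FALSE)
    any_dp <- any(vapply(r$samples, function(s) !is.null(s$dp) && s$dp > 0, TRUE))
    if (!any_dp) return(FALSE)
    any_ad <- any(vapply(r$samples, function(s) {
      !is.null(s$ad) && length(s$ad) > 1L && any(s$ad[-1L] > 0L)
    }, TRUE))
    any_ad
  }, TRUE)
  out <- records[keep]
  attr(out, "sample_names") <- attr(records, "sample_names")
  out
}

#' Build a truth panel from normalized SNV alleles
#'
#' @param alleles `data.frame` with columns `chrom, pos, ref, alt` (normalized
#'   SNVs, e.g. from [normalize_records()] on a panel VCF), or a character
#'   vector of allele keys.
#' @param name Panel name.
#' @return A `truth_panel` object (set of allele keys).
#' @export
truth_panel <- function(alleles, name = "truth") {
  keys <- if (is.character(alleles)) alleles
  else {
    if (!all(is_snv_allele(alleles$ref, alleles$alt)))
      stop_popnovel("truth_panel: all entries must be single-base ref/alt")
    allele_key(alleles$chrom, alleles$pos, alleles$ref, alleles$alt)
  }
  structure(list(keys = unique(keys), name = name), class = "truth_panel")
}

#' Classify sites as true or other against truth panels
#'
#' A record is `"true"` iff any of its alt alleles exactly matches a
#' normalized (chrom, pos, ref, alt) entry in any panel, otherwise
#' `"other"` — the union-of-panels, any-allele rule.
#'
#' @param records List of [site_record()]s (normalized).
#' @param panels List of [truth_panel()]s.
#' @return Character vector (`"true"`/`"other"`) aligned with `records`.
#' @export
classify_sites <- function(records, panels) {
  all_keys <- unique(unlist(lapply(panels, function(p) p$keys)))
  vapply(records, function(r) {
    ks <- allele_key(r$chrom, r$pos, r$ref, r$alts)
    if (any(ks %in% all_keys)) "true" else "other"
  }, "")
}

count_evaluation <- function(labels, keep) {
  is_true <- labels == "true"
  n_tb <- sum(is_true); n_ob <- sum(!is_true)
  if (n_tb == 0L || n_ob == 0L)
    stop_popnovel("evaluate_filter: need at least one true and one other site ",
                  "before filtering (retentions undefined)")
  n_tk <- sum(keep & is_true); n_ok <- sum(keep & !is_true)
  tr <- n_tk / n_tb; or <- n_ok / n_ob
  structure(list(
    n_true_before = n_tb, n_true_kept = n_tk,
    n_other_before = n_ob, n_other_kept = n_ok,
    true_retention = tr, other_retention = or,
    discrimination_factor = if (or > 0) tr / or else Inf),
    class = "filter_evaluation")
}

#' @export
print.filter_evaluation <- function(x, ...) {
  cat(sprintf("<filter_evaluation> true %d/%d (%.4f), other %d/%d (%.4f), DF = %.4f\n",
              x$n_true_kept, x$n_true_before, x$true_retention,
              x$n_other_kept, x$n_other_before, x$other_retention,
              x$discrimination_factor))
  invisible(x)
}

#' Evaluate a filter rule by retention and discrimination factor
#'
#' The discrimination factor is the fraction of true sites kept divided by
#' the fraction of other sites kept — the factor by which the filter
#' increases the true:other ratio. A filter removing every other site gets an
#' `Inf` sentinel.
#'
#' @param records List of [site_record()]s.
#' @param labels `"true"`/`"other"` vector aligned with `records` (from
#'   [classify_sites()]).
#' @param rule A [filter_rule()].
#' @param ... Passed to [rule_keeps()].
#' @return A `filter_evaluation` object: counts, retentions and the
#'   discrimination factor.
#' @export
evaluate_filter <- function(records, labels, rule, ...) {
  stopifnot(length(labels) == length(records))
  count_evaluation(labels, rule_keeps(rule, records, ...))
}

#' Apply a sequential QC cascade
#'
#' Applies the given stages in order to SNV records (non-SNV alleles are
#' excluded up front), computing a `filter_evaluation` for each stage on the
#' stage's input set. Stages are either threshold rules ([filter_rule()]) or
#' a single final mixture-score stage, given as
#' `list(type = "score", metrics, k, threshold, seed)`: the score model is
#' trained on the current survivors labelled true, all survivors are scored,
#' and those with score greater than `threshold` are kept.
#'
#' @param records List of single-alt [site_record()]s (see
#'   [split_multiallelic()]).
#' @param labels `"true"`/`"other"` vector aligned with `records`.
#' @param stages Named list of stages as described above.
#' @param ... Passed to [rule_keeps()] for rule stages.
#' @return A `qc_result`: `kept` records, `report` data frame (one row per
#'   stage), `overall` summary (true retention, ratio increase, fraction of
#'   sites removed), and the fitted `score_model`/`scores` when a score stage
#'   ran. The overall ratio increase equals the product of the stage
#'   discrimination factors exactly.
#' @export
apply_qc_cascade <- function(records, labels, stages, ...) {
  if (!length(stages)) stop_popnovel("apply_qc_cascade: stages must be nonempty")
  snv <- vapply(records, function(r)
    nchar(r$ref) == 1L && all(nchar(r$alts) == 1L), TRUE)
  cur <- records[snv]
  cur_lab <- labels[snv]
  n0 <- length(cur)
  is_true0 <- sum(cur_lab == "true"); is_oth0 <- sum(cur_lab == "other")
  rows <- list(); model <- NULL; scores <- NULL
  stage_names <- names(stages) %||% paste0("stage", seq_along(stages))
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (inherits(st, "filter_rule")) {
      keep <- rule_keeps(st, cur, ...)
    } else if (is.list(st) && identical(st$type, "score")) {
      train <- cur[cur_lab == "true"]
      model <- fit_mixture_model(train,
                                 metrics = st$metrics %||% c("DP", "SOR", "ReadPosRankSum", "FS"),
                                 k = st$k %||% 2L,
                                 max_iterations = st$max_iterations %||% 500L,
                                 tol = st$tol %||% 1e-6,
                                 seed = st$seed,
                                 records_all = cur,
                                 neg_fraction = st$neg_fraction %||% 0.05)
      scores <- score_sites(model, cur)
      keep <- !is.na(scores) & scores > (st$threshold %||% -0.5)
    } else {
      stop_popnovel("apply_qc_cascade: stage ", i,
                    " is neither a filter_rule nor a score stage")
    }
    ev <- count_evaluation(cur_lab, keep)
    rows[[i]] <- data.frame(
      stage = stage_names[i],
      n_true_before = ev$n_true_before, n_true_kept = ev$n_true_kept,
      n_other_before = ev$n_other_before, n_other_kept = ev$n_other_kept,
      true_retention = ev$true_retention, other_retention = ev$other_retention,
      discrimination_factor = ev$discrimination_factor,
      stringsAsFactors = FALSE)
    cur <- cur[keep]; cur_lab <- cur_lab[keep]
  }
  report <- do.call(rbind, rows)
  nt1 <- sum(cur_lab == "true"); no1 <- sum(cur_lab == "other")
  overall <- list(
    n_before = n0, n_kept = length(cur),
    true_retention = nt1 / is_true0,
    other_retention = no1 / is_oth0,
    ratio_increase = if (no1 > 0) (nt1 / no1) / (is_true0 / is_oth0) else Inf,
    fraction_removed = 1 - length(cur) / n0)
  structure(list(kept = cur, labels = cur_lab, report = report,
                 overall = overall, score_model = model, scores = scores),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report, row.names = FALSE)
  with(x$overall, cat(sprintf(
    "overall: kept %d/%d sites; true retention %.4f; ratio increase %.4f; removed %.4f\n",
    n_kept, n_before, true_retention, ratio_increase, fraction_removed)))
  invisible(x)
}

# ---- report arithmetic ------------------------------------------------------

#' Compose stage discrimination factors
#'
#' For stages applied sequentially to the same site set, the overall factor
#' by which the true:other ratio increases is exactly the product of the
#' per-stage discrimination factors.
#'
#' @param dfs Numeric vector of stage discrimination factors.
#' @return Overall ratio-increase factor (e.g. 1.17 for +17%).
#' @export
compose_discrimination_factors <- function(dfs) prod(dfs)

#' Overall site removal implied by retention and ratio increase
#'
#' Given the pre-QC true:other ratio, the overall true-site retention and
#' the overall ratio-increase factor, solves for the other-site retention
#' and the overall fraction of sites removed:
#' `other_retention = true_retention / ratio_increase`, and the removed
#' fraction is the complement of the retention-weighted site average.
#'
#' @param start_ratio Pre-QC ratio of true to other sites.
#' @param true_retention Overall fraction of true sites kept (0..1).
#' @param ratio_increase Overall ratio-increase factor (e.g. 1.17).
#' @return List with `other_retention` and `fraction_removed`.
#' @export
implied_site_removal <- function(start_ratio, true_retention, ratio_increase) {
  other_retention <- true_retention / ratio_increase
  t0 <- start_ratio / (1 + start_ratio)
  kept <- t0 * true_retention + (1 - t0) * other_retention
  list(other_retention = other_retention, fraction_removed = 1 - kept)
}
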