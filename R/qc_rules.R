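# Compound threshold filter rules over site metrics.
#
# Rules are boolean expressions over the seven site metrics, written in R
# syntax with explicit parentheses, e.g.
#   "(MQRankSum > -2.5 & MQRankSum < 1 & QD > 7) |
#    (QD > 0.5 & MQRankSum > -0.01 & MQRankSum < 0.01)"
# Only comparisons (<, >, <=, >=, ==), conjunction, disjunction, parentheses
# and numeric literals are allowed.

RULE_OPS <- c("&", "|", "(", "<", ">", "<=", ">=", "==", "-", "+")

validate_rule_expr <- function(e) {
  if (is.numeric(e)) return(invisible(TRUE))
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!nm %in% SITE_METRICS)
      stop_popnovel("filter_rule: unknown metric '", nm, "'")
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% RULE_OPS)
      stop_popnovel("filter_rule: operator '", op, "' not allowed")
    for (i in seq_along(e)[-1]) validate_rule_expr(e[[i]])
    return(invisible(TRUE))
  }
  stop_popnovel("filter_rule: unsupported expression element")
}

#' Define a site-metric filter rule
#'
#' @param text Rule expression as a string (R syntax, fully parenthesized;
#'   see details in the package vignette). May reference only the metrics
#'   `QD, MQ, MQRankSum, ReadPosRankSum, FS, SOR, DP`.
#' @param name Optional display name.
#' @return A `filter_rule` object.
#' @export
filter_rule <- function(text, name = text) {
  expr <- tryCatch(str2lang(text),
                   error = function(e) stop_popnovel("filter_rule: parse error: ",
                                                     conditionMessage(e)))
  validate_rule_expr(expr)
  mets <- intersect(SITE_METRICS, all.vars(expr))
  structure(list(text = text, name = name, expr = expr, metrics = mets),
            class = "filter_rule")
}

#' @export
print.filter_rule <- function(x, ...) {
  cat("<filter_rule> ", x$text, "\n", sep = "")
  invisible(x)
}

#' Default quality-control rule stages
#'
#' The two packaged threshold stages applied before mixture-model scoring:
#' a joint MQRankSum/QD rule and an MQ/FS rule. The written `X and Y or Z
#' and W` forms are parsed as `(X and Y) or (Z and W)` — two alternative
#' clauses.
#'
#' @return Named list of two [filter_rule()]s.
#' @export
default_qc_rules <- function() {
  list(
    mqranksum_qd = filter_rule(
      "(MQRankSum > -2.5 & MQRankSum < 1 & QD > 7) | (QD > 0.5 & MQRankSum > -0.01 & MQRankSum < 0.01)",
      name = "MQRankSum/QD"),
    mq_fs = filter_rule(
      "(MQ > 50) | (FS == 0 & MQ > 40)",
      name = "MQ/FS"))
}

#' Evaluate a filter rule on site records
#'
#' A record missing a metric referenced by the rule fails the rule
#' (conservative default), except that an absent FS is treated as 0 when
#' `missing_fs_zero = TRUE`, since FS is omitted by some callers at sites
#' where the annotation is exactly zero. Comparisons use exact arithmetic on
#' the parsed decimal values.
#'
#' @param rule A [filter_rule()].
#' @param records List of [site_record()]s.
#' @param missing_fails Whether a missing referenced metric fails the record.
#' @param missing_fs_zero Whether an absent FS metric is read as 0.
#' @return Logical vector: `TRUE` where the record passes (is kept).
#' @export
rule_keeps <- function(rule, records, missing_fails = TRUE,
                       missing_fs_zero = TRUE) {
  stopifnot(inherits(rule, "filter_rule"))
  mm <- metric_matrix(records)
  vals <- as.data.frame(mm)
  if (missing_fs_zero && "FS" %in% rule$metrics)
    vals$FS[is.na(vals$FS)] <- 0
  keep <- eval(rule$expr, vals)
  if (missing_fails) {
    ref_mets <- setdiff(rule$metrics, if (missing_fs_zero) "FS" else character())
    if (length(ref_mets)) {
      miss <- rowSums(is.na(mm[, ref_mets, drop = FALSE])) > 0L
      keep[miss] <- FALSE
    }
  }
  keep[is.na(keep)] <- FALSE
  keep
}

#' Site-metric matrix of a record list
#'
#' @param records List of [site_record()]s.
#' @return Numeric matrix, one row per record, columns the seven site
#'   metrics, `NA` where a metric is absent.
#' @export
metric_matrix <- function(records) {
  mm <- matrix(NA_real_, nrow = length(records), ncol = length(SITE_METRICS),
               dimnames = list(NULL, SITE_METRICS))
  for (i in seq_along(records)) {
    m <- records[[i]]$metrics
    if (length(m)) mm[i, names(m)] <- m
  }
  mm
}
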