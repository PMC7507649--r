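# Ancestry inference: reference-panel site selection, query-side genotype
# filtering, VIF-based LD pruning, centred/scaled PCA and sample projection.

#' Construct a genotype matrix
#'
#' Samples in rows, sites in columns; values are 0/1/2 counts of the
#' alternative allele, `NA` for missing. Column names are normalized allele
#' keys (`chrom:pos:ref:alt`).
#'
#' @param mat Numeric matrix.
#' @param populations Optional per-sample population labels.
#' @return A `genotype_matrix` (a matrix with a `populations` attribute).
#' @export
genotype_matrix <- function(mat, populations = NULL) {
  mat <- as.matrix(mat)
  ok <- mat %in% c(0, 1, 2) | is.na(mat)
  if (!all(ok)) stop_popnovel("genotype_matrix: values must be 0, 1, 2 or NA")
  if (!is.null(populations) && length(populations) != nrow(mat))
    stop_popnovel("genotype_matrix: one population label per sample required")
  attr(mat, "populations") <- populations
  class(mat) <- c("genotype_matrix", class(mat))
  mat
}

key_coords <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[[`, "", 1L),
             pos = as.integer(vapply(parts, `[[`, "", 2L)),
             ref = vapply(parts, function(p) if (length(p) > 2) p[[3]] else NA_character_, ""),
             alt = vapply(parts, function(p) if (length(p) > 3) p[[4]] else NA_character_, ""),
             key = keys, stringsAsFactors = FALSE)
}

#' Site-selection and query-filter configuration
#'
#' Defaults follow the reference-panel selection cascade: minor allele
#' frequency strictly above 5%, exclusion of sites within 5 bp (inclusive) of
#' another SNV or indel, an accessibility mask, a Hardy-Weinberg exact-test
#' floor of 1e-6, LD pruning with a 50-site window sliding by 5 and a VIF
#' ceiling of 2, and query-side thresholds QUAL >= 30, DP >= 10,
#' RGQ >= 20 (hom-ref sites) / GQ >= 20 (variant sites) for all samples.
#'
#' @param maf_min,proximity_bp,hwe_p_min,mask,excluded_regions,ld_window,ld_step,vif_max,qual_min,dp_min,rgq_min,gq_min
#'   See description; `mask` is a [mask_regions()] or `NULL` (no mask stage),
#'   `excluded_regions` a list of `list(chrom, start, end)` 1-based inclusive
#'   spans of extended LD to drop before pruning.
#' @return A `site_selection_config` list.
#' @export
site_selection_config <- function(maf_min = 0.05, proximity_bp = 5L,
                                  hwe_p_min = 1e-6, mask = NULL,
                                  excluded_regions = list(),
                                  ld_window = 50L, ld_step = 5L, vif_max = 2,
                                  qual_min = 30, dp_min = 10, rgq_min = 20,
                                  gq_min = 20) {
  if (ld_window <= ld_step) stop_popnovel("site_selection_config: window must exceed step")
  structure(list(maf_min = maf_min, proximity_bp = as.integer(proximity_bp),
                 hwe_p_min = hwe_p_min, mask = mask,
                 excluded_regions = excluded_regions,
                 ld_window = as.integer(ld_window), ld_step = as.integer(ld_step),
                 vif_max = vif_max, qual_min = qual_min, dp_min = dp_min,
                 rgq_min = rgq_min, gq_min = gq_min),
            class = "site_selection_config")
}

#' Select high-quality reference-panel sites
#'
#' Applies the selection cascade in order: minor allele frequency (strictly
#' greater than `maf_min`), proximity (a site within `proximity_bp` bp,
#' inclusive, of any other catalogue variant is dropped), accessibility mask,
#' and Hardy-Weinberg exact test (`p >= hwe_p_min` kept). Per-stage attrition
#' is reported.
#'
#' @param panel_matrix A [genotype_matrix()] keyed by biallelic site.
#' @param variant_catalog `data.frame` with `chrom, pos` (and ideally
#'   `ref, alt`) of *all* panel variants including indels, used for the
#'   proximity test; defaults to the matrix's own sites.
#' @param config A [site_selection_config()].
#' @return List: `sites` (kept keys, genomic order) and `attrition`
#'   data frame (stage, n_in, n_removed, n_out).
#' @export
select_sites <- function(panel_matrix, variant_catalog = NULL,
                         config = site_selection_config()) {
  keys <- colnames(panel_matrix)
  co <- key_coords(keys)
  ord <- order(co$chrom, co$pos)
  keys <- keys[ord]; co <- co[ord, ]
  attr_rows <- list()
  note <- function(stage, n_in, n_out)
    attr_rows[[length(attr_rows) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_removed = n_in - n_out, n_out = n_out,
      stringsAsFactors = FALSE)

  # 1. minor allele frequency, strict inequality
  af <- colMeans(panel_matrix[, keys, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf > config$maf_min
  note("maf", length(keys), sum(keep))
  keys <- keys[keep]; co <- co[keep, ]

  # 2. proximity to any other catalogue variant (<= proximity_bp)
  cat_df <- if (is.null(variant_catalog)) key_coords(colnames(panel_matrix))
  else variant_catalog
  keep <- !vapply(seq_len(nrow(co)), function(i) {
    same <- cat_df$chrom == co$chrom[i]
    d <- abs(cat_df$pos[same] - co$pos[i])
    near <- d <= config$proximity_bp
    # the site itself (distance 0 with identical alleles) does not count
    if ("ref" %in% names(cat_df)) {
      self <- cat_df$pos[same] == co$pos[i] &
        !is.na(cat_df$ref[same]) & cat_df$ref[same] == co$ref[i] &
        cat_df$alt[same] == co$alt[i]
      near <- near & !self
    } else {
      near <- near & d > 0L
    }
    any(near)
  }, TRUE)
  note("proximity", nrow(co), sum(keep))
  keys <- keys[keep]; co <- co[keep, ]

  # 3. accessibility mask
  if (!is.null(config$mask)) {
    keep <- in_mask(config$mask, co$chrom, co$pos)
  } else keep <- rep(TRUE, nrow(co))
  note("mask", nrow(co), sum(keep))
  keys <- keys[keep]; co <- co[keep, ]

  # 4. Hardy-Weinberg exact test
  if (length(keys)) {
    g <- panel_matrix[, keys, drop = FALSE]
    cnt <- cbind(n_AA = colSums(g == 0, na.rm = TRUE),
                 n_Aa = colSums(g == 1, na.rm = TRUE),
                 n_aa = colSums(g == 2, na.rm = TRUE))
    pvals <- hwe_exact_test_rows(cnt)
    keep <- pvals >= config$hwe_p_min
  } else keep <- logical()
  note("hwe", length(keys), sum(keep))
  keys <- keys[keep]

  if (!length(keys)) stop_popnovel("select_sites: no sites survive the cascade")
  list(sites = keys, attrition = do.call(rbind, attr_rows))
}

#' Drop sites inside excluded regions
#'
#' @param sites Character vector of site keys.
#' @param regions List of `list(chrom, start, end)` 1-based inclusive spans
#'   (e.g. extended-LD regions).
#' @return Filtered key vector.
#' @export
exclude_regions <- function(sites, regions) {
  if (!length(regions)) return(sites)
  co <- key_coords(sites)
  drop <- rep(FALSE, length(sites))
  for (r in regions)
    drop <- drop | (co$chrom == r$chrom & co$pos >= r$start & co$pos <= r$end)
  sites[!drop]
}

#' Apply query-side genotype filters at selected sites
#'
#' Keeps a selected site only when the query cohort supports it: every sample
#' genotyped (uncalled sites excluded); hom-ref sites need site QUAL >=
#' `qual_min` and DP >= `dp_min`, RGQ >= `rgq_min` for all samples; variant
#' sites need DP >= `dp_min` and GQ >= `gq_min` for all samples; the query
#' alt must equal the panel alt; and sites within `proximity_bp` of another
#' query variant are excluded. Surviving sites define both the query genotype
#' matrix and the model site list, so model and query always share one site
#' list.
#'
#' @param query_records List of single-alt [site_record()]s covering the
#'   selected sites (hom-ref sites included, carrying the panel alt).
#' @param selected_sites Character vector of panel site keys.
#' @param config A [site_selection_config()].
#' @return List: `matrix` (query [genotype_matrix()] over kept sites),
#'   `kept_sites`, and `excluded` data frame (key, reason).
#' @export
apply_query_filters <- function(query_records, selected_sites,
                                config = site_selection_config()) {
  rec_keys <- vapply(query_records, function(r)
    allele_key(r$chrom, r$pos, r$ref, r$alts[1]), "")
  rec_pos_keys <- vapply(query_records, function(r) site_key(r$chrom, r$pos), "")
  # positions of query variant calls, for the query-side proximity test
  is_variant <- vapply(query_records, function(r)
    any(vapply(r$samples, function(s) any(!is.na(s$gt) & s$gt != 0L) || s$other_alt,
               TRUE)), TRUE)
  var_chrom <- vapply(query_records[is_variant], `[[`, "", "chrom")
  var_pos <- vapply(query_records[is_variant], function(r) r$pos, 0L)

  sel <- key_coords(selected_sites)
  n_samp <- if (length(query_records)) length(query_records[[1]]$samples) else 0L
  rows <- matrix(NA_real_, nrow = n_samp, ncol = 0L)
  kept <- character(); excl <- list()
  fail <- function(key, reason)
    excl[[length(excl) + 1L]] <<- data.frame(key = key, reason = reason,
                                             stringsAsFactors = FALSE)
  for (i in seq_along(selected_sites)) {
    key <- selected_sites[i]
    j <- match(site_key(sel$chrom[i], sel$pos[i]), rec_pos_keys)
    if (is.na(j)) { fail(key, "uncalled"); next }
    r <- query_records[[j]]
    if (rec_keys[j] != key) { fail(key, "different_alt"); next }
    gts <- lapply(r$samples, `[[`, "gt")
    if (any(vapply(gts, anyNA, TRUE))) { fail(key, "uncalled"); next }
    dp <- vapply(r$samples, function(s) s$dp %||% -1, 0)
    variant <- any(vapply(gts, function(g) any(g != 0L), TRUE)) ||
      any(vapply(r$samples, `[[`, TRUE, "other_alt"))
    if (variant) {
      gq <- vapply(r$samples, function(s) s$gq %||% -1, 0)
      if (!all(dp >= config$dp_min & gq >= config$gq_min)) {
        fail(key, "variant_quality"); next
      }
    } else {
      rgq <- vapply(r$samples, function(s) s$rgq %||% -1, 0)
      if (is.null(r$qual) || r$qual < config$qual_min ||
          !all(dp >= config$dp_min & rgq >= config$rgq_min)) {
        fail(key, "homref_quality"); next
      }
    }
    near <- var_chrom == r$chrom & abs(var_pos - r$pos) <= config$proximity_bp &
      !(var_pos == r$pos)
    if (any(near)) { fail(key, "query_proximity"); next }
    g <- vapply(gts, function(x) sum(x == 1L), 0L)
    rows <- cbind(rows, g)
    kept <- c(kept, key)
  }
  colnames(rows) <- kept
  samp <- attr(query_records, "sample_names") %||% paste0("S", seq_len(n_samp))
  rownames(rows) <- samp
  list(matrix = genotype_matrix(rows), kept_sites = kept,
       excluded = if (length(excl)) do.call(rbind, excl)
       else data.frame(key = character(), reason = character()))
}

# ---- LD pruning -------------------------------------------------------------

# VIFs of the columns of X: diagonal of the inverse correlation matrix, with
# a per-column regression fallback when the correlation matrix is singular
# (perfectly predictable columns get Inf).
window_vifs <- function(X) {
  p <- ncol(X)
  if (p == 1L) return(1)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    v <- rep(1, p)  # constant columns carry no LD information
    ok <- sds > 0
    if (sum(ok) > 1L) v[ok] <- window_vifs(X[, ok, drop = FALSE])
    return(v)
  }
  R <- stats::cor(X)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(inv) && all(diag(inv) > 0)) return(diag(inv))
  vapply(seq_len(p), function(i) {
    fit <- stats::lm.fit(cbind(1, X[, -i, drop = FALSE]), X[, i])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, i] - mean(X[, i]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

#' LD pruning by variance inflation factor
#'
#' Sliding windows of `window` sites advance by `step` along the genomically
#' ordered list of currently retained sites. Within each window, while any
#' site's VIF (1/(1-R^2) from regressing its genotypes on the other retained
#' sites of the window) exceeds `vif_max`, the site with the highest VIF is
#' removed (ties broken toward the lower genomic position). Passes repeat
#' until no window removes a site, so pruning an already pruned set is a
#' no-op and every window of the retained sequence satisfies the VIF bound.
#'
#' @param matrix A [genotype_matrix()] with no missing values, sites in
#'   genomic order.
#' @param window Window size in sites (default 50; must be >= 2).
#' @param step Window shift in sites (default 5).
#' @param vif_max VIF ceiling (default 2).
#' @return Character vector of retained site keys, in genomic order.
#' @export
ld_prune <- function(matrix, window = 50L, step = 5L, vif_max = 2) {
  if (window < 2L) stop_popnovel("ld_prune: window must be >= 2")
  if (anyNA(matrix)) stop_popnovel("ld_prune: missing genotypes; impute or drop first")
  p <- ncol(matrix)
  retained <- rep(TRUE, p)
  repeat {
    changed <- FALSE
    cur_sites <- which(retained)
    if (length(cur_sites) < 2L) break
    starts <- seq.int(1L, max(1L, length(cur_sites) - 1L), by = step)
    for (s in starts) {
      idx <- cur_sites[s:min(s + window - 1L, length(cur_sites))]
      idx <- idx[retained[idx]]
      while (length(idx) >= 2L) {
        vifs <- window_vifs(matrix[, idx, drop = FALSE])
        if (max(vifs) <= vif_max) break
        # highest VIF first; ties toward the lowest genomic position
        retained[idx[which.max(vifs)]] <- FALSE
        idx <- idx[retained[idx]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  colnames(matrix)[retained]
}

#' Audit VIFs of a pruned site set
#'
#' Recomputes, by direct regression, the maximum VIF over sliding windows of
#' the given (already pruned) matrix — the post-hoc check that [ld_prune()]'s
#' bound holds.
#'
#' @param matrix Genotype matrix restricted to the retained sites, in genomic
#'   order.
#' @param window,step Window scheme, as in [ld_prune()].
#' @return Maximum VIF observed over all windows (1 when no window has two
#'   sites).
#' @export
vif_audit <- function(matrix, window = 50L, step = 5L) {
  p <- ncol(matrix)
  worst <- 1
  for (s in seq.int(1L, max(1L, p - 1L), by = step)) {
    idx <- s:min(s + window - 1L, p)
    if (length(idx) < 2L) next
    worst <- max(worst, max(window_vifs(matrix[, idx, drop = FALSE])))
  }
  worst
}

# ---- PCA --------------------------------------------------------------------

#' Mean-impute missing genotypes
#'
#' @param matrix A [genotype_matrix()].
#' @return The matrix with each missing value replaced by its column mean.
#' @export
impute_mean <- function(matrix) {
  for (j in seq_len(ncol(matrix))) {
    miss <- is.na(matrix[, j])
    if (any(miss)) matrix[miss, j] <- mean(matrix[, j], na.rm = TRUE)
  }
  matrix
}

#' Fit a centred, scaled PCA on a reference genotype matrix
#'
#' Columns are centred by their mean and divided by their sample standard
#' deviation (n-1 denominator); loadings are the top-k right singular vectors
#' of the standardized matrix (via [stats::prcomp()]). Reference sample
#' scores are stored for later comparison with projected queries.
#'
#' @param matrix A [genotype_matrix()]; no missing values, >= 2 samples, all
#'   sites polymorphic.
#' @param k Number of components to retain (default 2).
#' @return A `pca_model`: site keys, per-site `center` and `scale`, `rotation`
#'   loadings, reference `scores`, singular-value standard deviations `sdev`
#'   and reference `populations`.
#' @export
fit_pca <- function(matrix, k = 2L) {
  if (anyNA(matrix)) stop_popnovel("fit_pca: missing genotypes; impute first")
  if (nrow(matrix) < 2L) stop_popnovel("fit_pca: need >= 2 samples")
  sds <- apply(matrix, 2L, stats::sd)
  if (any(sds == 0))
    stop_popnovel("fit_pca: zero-variance site(s): ",
                  paste(utils::head(colnames(matrix)[sds == 0], 5L),
                        collapse = ", "))
  k <- min(k, nrow(matrix) - 1L, ncol(matrix))
  pr <- stats::prcomp(matrix, center = TRUE, scale. = TRUE)
  structure(list(sites = colnames(matrix), center = pr$center,
                 scale = pr$scale,
                 rotation = pr$rotation[, seq_len(k), drop = FALSE],
                 scores = pr$x[, seq_len(k), drop = FALSE],
                 sdev = pr$sdev[seq_len(k)],
                 populations = attr(matrix, "populations")),
            class = "pca_model")
}

#' Project query samples onto a fitted PCA model
#'
#' Scores are `((genotype - center) / scale) %*% rotation` — the stored
#' model is applied without refitting.
#'
#' @param model A [fit_pca()] result.
#' @param query_matrix Genotype matrix whose columns cover the model's site
#'   list.
#' @return Score matrix (samples x components).
#' @export
project_samples <- function(model, query_matrix) {
  missing_sites <- setdiff(model$sites, colnames(query_matrix))
  if (length(missing_sites))
    stop_popnovel("project_samples: query lacks model site(s): ",
                  paste(utils::head(missing_sites, 5L), collapse = ", "),
                  if (length(missing_sites) > 5L) " ...")
  X <- query_matrix[, model$sites, drop = FALSE]
  if (anyNA(X)) stop_popnovel("project_samples: missing genotypes in query")
  scale(X, center = model$center, scale = model$scale) %*% model$rotation
}
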