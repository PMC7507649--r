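# Synthetic-data generation with known ground truth for every pipeline stage:
# a small multi-sample cohort VCF with class-conditional site metrics, truth
# and reference panels with planted novel fractions, Balding-Nichols admixed
# populations, and a toy genome with transcript models and planted functional
# alleles.
#
# All generators are deterministic under the configuration seed; each draws
# from its own derived RNG stream so the pieces can be generated
# independently or together.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a 3-sample cohort,
#' truth/error site-metric mixtures separated enough that the packaged QC
#' rules discriminate, a 1000G-like reference panel covering 93% of cohort
#' alleles (7% planted novel), a gnomAD-like panel using FILTER flags and
#' omitting chrY, and two source populations (100 samples each, F = 0.1)
#' with admixed query samples at five mixing proportions.
#'
#' @param seed Integer master seed (required).
#' @param n_samples Cohort samples (default 3).
#' @param n_sites Cohort sites (default 10000).
#' @param chrom_lengths Named chromosome lengths; `chrG` hosts the gene
#'   models, `chrX`/`chrY` exercise the autosome prefilter.
#' @param true_fraction Fraction of SNV sites drawn from the truth metric
#'   model (default 0.42, matching a pre-QC true:other ratio near 0.72).
#' @param metric_models Per-class per-metric (mean, sd); QD, MQ, FS, SOR and
#'   DP are truncated at 0.
#' @param indel_fraction,multiallelic_fraction Minority variant types.
#' @param missing_rate Per-sample-call missing genotype rate.
#' @param qd_absent_fraction,dp_zero_fraction,ad_zero_fraction Planted
#'   prefilter deficiencies.
#' @param depth_mean Mean sequencing depth for the read-depth model.
#' @param panel_overlap Fraction of eligible cohort alleles present in the
#'   1000G-like panel (novel fraction = 1 - overlap, planted exactly).
#' @param panel_overlap_b Same for the gnomAD-like panel.
#' @param panel_fail_fraction Fraction of gnomAD-like entries flagged as
#'   quality-failed.
#' @param panel_excluded_chrom Chromosome absent from the gnomAD-like panel.
#' @param panel_extra_fraction Panel-only alleles, relative to cohort allele
#'   count.
#' @param diff_alt_fraction Fraction of planted-novel alleles whose position
#'   gets a panel entry with a different alt.
#' @param fst Balding-Nichols divergence between the two source populations.
#' @param n_pop_samples Samples per source population.
#' @param n_pop_sites Population panel sites.
#' @param maf_floor Ancestral-frequency floor.
#' @param admixture_alphas Query admixture proportions (one query sample per
#'   value).
#' @param hwe_violation_fraction,prox_violation_fraction,mask_gap_fraction
#'   Planted site-selection violations (inbred genotypes, a neighbouring
#'   indel, an accessibility-mask gap).
#' @param query_fail_fraction,query_uncalled_fraction,query_diffalt_fraction
#'   Planted query-side filter triggers.
#' @param gene_model_count Transcripts on the toy chromosome (half coding).
#' @param gene_chrom_length Toy chromosome length.
#' @param flank_bp Flank used when planting upstream/downstream alleles.
#' @param n_exonic_known,n_exonic_novel Planted exonic alleles per novelty
#'   stratum.
#' @param novel_nonsense_rate Stop-gain rate planted in the novel stratum.
#' @param nonsense_enrichment Ratio of the novel-stratum stop-gain rate to
#'   the all-allele rate (default 4); the known-stratum rate is derived.
#' @param n_per_other_class Planted alleles per non-exonic sequence class.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_samples = 3L,
                              n_sites = 10000L,
                              chrom_lengths = c(chr1 = 60e6, chr2 = 50e6,
                                                chr3 = 40e6, chrG = 2e5,
                                                chrX = 30e6, chrY = 20e6),
                              true_fraction = 0.42,
                              metric_models = default_metric_models(),
                              indel_fraction = 0.03,
                              multiallelic_fraction = 0.03,
                              missing_rate = 0.0035,
                              qd_absent_fraction = 0.01,
                              dp_zero_fraction = 0.005,
                              ad_zero_fraction = 0.005,
                              depth_mean = 30,
                              panel_overlap = 0.93,
                              panel_overlap_b = 0.975,
                              panel_fail_fraction = 0.05,
                              panel_excluded_chrom = "chrY",
                              panel_extra_fraction = 0.5,
                              diff_alt_fraction = 0.3,
                              fst = 0.1,
                              n_pop_samples = 100L,
                              n_pop_sites = 5000L,
                              maf_floor = 0.05,
                              admixture_alphas = c(0, 0.25, 0.5, 0.75, 1),
                              hwe_violation_fraction = 0.01,
                              prox_violation_fraction = 0.01,
                              mask_gap_fraction = 0.01,
                              query_fail_fraction = 0.005,
                              query_uncalled_fraction = 0.001,
                              query_diffalt_fraction = 0.002,
                              gene_model_count = 24L,
                              gene_chrom_length = 200000L,
                              flank_bp = 1000L,
                              n_exonic_known = 1280L,
                              n_exonic_novel = 320L,
                              novel_nonsense_rate = 0.05,
                              nonsense_enrichment = 4,
                              n_per_other_class = 40L) {
  if (missing(seed) || is.null(seed))
    stop_popnovel("simulation_config: field 'seed' is required")
  cfg <- as.list(environment())
  bad <- c()
  fracs <- c("true_fraction", "indel_fraction", "multiallelic_fraction",
             "missing_rate", "panel_overlap", "panel_overlap_b",
             "panel_fail_fraction", "maf_floor")
  for (f in fracs) if (cfg[[f]] < 0 || cfg[[f]] > 1) bad <- c(bad, f)
  if (cfg$fst <= 0 || cfg$fst >= 1) bad <- c(bad, "fst")
  if (length(bad))
    stop_popnovel("simulation_config: invalid field(s): ",
                  paste(bad, collapse = ", "))
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_metric_models <- function() {
  list(
    true = list(QD = c(18, 6), MQ = c(60, 2), MQRankSum = c(0, 0.4),
                ReadPosRankSum = c(0, 0.8), FS = c(2, 2), SOR = c(1, 0.4),
                DP = c(60, 15)),
    error = list(QD = c(5, 4), MQ = c(45, 8), MQRankSum = c(-2, 1.5),
                 ReadPosRankSum = c(-1.5, 1.5), FS = c(12, 10),
                 SOR = c(2.5, 1.2), DP = c(35, 20)))
}

TRUNCATED_METRICS <- c("QD", "MQ", "FS", "SOR", "DP")

draw_metrics <- function(n, class, models) {
  m <- models[[class]]
  out <- sapply(SITE_METRICS, function(met) {
    x <- stats::rnorm(n, m[[met]][1], m[[met]][2])
    if (met %in% TRUNCATED_METRICS) x <- pmax(0, x)
    round(x, 3)
  })
  matrix(out, nrow = n, dimnames = list(NULL, SITE_METRICS))
}

rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
}

# Genotypes, depths and qualities for one site given per-sample allele-count
# vectors over (ref, alt1[, alt2]).
build_sample_calls <- function(gt_pairs, depth_mean, missing_rate,
                               dp_zero = FALSE, ad_zero = FALSE,
                               n_alleles = 2L) {
  lapply(gt_pairs, function(g) {
    if (stats::runif(1) < missing_rate)
      return(sample_call(gt = NA, dp = stats::rpois(1, depth_mean)))
    n_all <- max(n_alleles, max(g) + 1L)
    dp <- if (dp_zero) 0L else stats::rpois(1, depth_mean) + 1L
    frac <- tabulate(g + 1L, nbins = n_all) / 2
    ad <- as.integer(round(dp * (0.96 * frac + 0.04 / n_all)))
    if (ad_zero) ad[-1L] <- 0L
    homref <- all(g == 0L)
    sample_call(gt = g, ad = ad, dp = dp,
                gq = sample(30:99, 1L),
                rgq = if (homref) sample(30:99, 1L) else NULL)
  })
}

#' Simulate the cohort VCF
#'
#' Generates `n_sites` variant records (SNVs plus configured minorities of
#' indels and multiallelic sites) with class-conditional site metrics and a
#' consistent depth model, plus any caller-supplied planted alleles (used to
#' tie the gene-model alleles into the cohort). Deterministic under the
#' configuration seed.
#'
#' @param config A [simulation_config()].
#' @param path Optional output VCF path; when `NULL`, no file is written.
#' @param planted Optional `data.frame` with `chrom, pos, ref, alt` and a
#'   `stratum` column (`"novel"`/`"known"`) of extra SNV alleles to include
#'   as true-class records.
#' @return List: `records`, `truth` (per-allele ground-truth data frame with
#'   site class labels, planted deficiencies and forced panel strata) and
#'   `path`.
#' @export
simulate_cohort_vcf <- function(config, path = NULL, planted = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  cl <- config$chrom_lengths
  main_chroms <- setdiff(names(cl), c("chrG", "chrX", "chrY"))
  sex_chroms <- intersect(c("chrX", "chrY"), names(cl))
  n <- config$n_sites
  n_sex <- if (length(sex_chroms)) round(0.02 * n) else 0L
  n_main <- n - n_sex
  w <- cl[main_chroms] / sum(cl[main_chroms])
  chroms <- c(sample(main_chroms, n_main, replace = TRUE, prob = w),
              if (n_sex) sample(sex_chroms, n_sex, replace = TRUE))
  pos <- integer(n)
  for (cn in unique(chroms)) {
    sel <- chroms == cn
    pos[sel] <- sort(sample.int(cl[[cn]] - 10L, sum(sel)))
  }
  # variant types
  type <- rep("snv", n)
  type[sample.int(n, round(config$indel_fraction * n))] <- "indel"
  is_snv_site <- type == "snv"
  multi <- rep(FALSE, n)
  multi[sample(which(is_snv_site), round(config$multiallelic_fraction * n))] <- TRUE
  cls <- ifelse(stats::runif(n) < config$true_fraction, "true", "error")
  cls[!is_snv_site] <- "error"  # truth panels carry SNVs only
  met_true <- draw_metrics(n, "true", config$metric_models)
  met_err <- draw_metrics(n, "error", config$metric_models)
  qd_absent <- stats::runif(n) < config$qd_absent_fraction
  dp_zero <- stats::runif(n) < config$dp_zero_fraction
  ad_zero <- stats::runif(n) < config$ad_zero_fraction

  recs <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- rand_base(1L)
    if (type[i] == "snv") {
      alts <- other_base(ref)
      if (multi[i]) alts <- c(alts, setdiff(c("A", "C", "G", "T"), c(ref, alts))[1])
    } else {
      ins <- stats::runif(1) < 0.5
      unit <- paste(rand_base(sample(1:3, 1L)), collapse = "")
      if (ins) alts <- paste0(ref, unit)
      else { ref <- paste0(ref, unit); alts <- substr(ref, 1L, 1L) }
    }
    n_all <- length(alts) + 1L
    af <- stats::runif(n_all - 1L, 0.1, 0.6)
    probs <- c(max(0.05, 1 - sum(af)), af)
    gt_pairs <- replicate(config$n_samples,
                          sort(sample.int(n_all, 2L, replace = TRUE,
                                          prob = probs) - 1L),
                          simplify = FALSE)
    if (!any(unlist(gt_pairs) > 0L)) gt_pairs[[1]] <- c(0L, 1L)
    samples <- build_sample_calls(gt_pairs, config$depth_mean,
                                  config$missing_rate,
                                  dp_zero = dp_zero[i], ad_zero = ad_zero[i],
                                  n_alleles = n_all)
    metrics <- if (cls[i] == "true") met_true[i, ] else met_err[i, ]
    if (qd_absent[i]) metrics <- metrics[setdiff(names(metrics), "QD")]
    recs[[i]] <- site_record(chrom = chroms[i], pos = pos[i], ref = ref,
                             alts = alts, qual = round(stats::runif(1, 50, 2000), 1),
                             metrics = metrics, samples = samples)
    truth_rows[[i]] <- data.frame(
      chrom = chroms[i], pos = pos[i], ref = ref, alt = alts,
      site_class = cls[i], is_snv = is_snv_allele(ref, alts),
      qd_absent = qd_absent[i], dp_zero = dp_zero[i], ad_zero = ad_zero[i],
      forced_novel = NA, stringsAsFactors = FALSE)
  }

  if (!is.null(planted) && nrow(planted)) {
    met_pl <- draw_metrics(nrow(planted), "true", config$metric_models)
    for (i in seq_len(nrow(planted))) {
      gt_pairs <- replicate(config$n_samples,
                            sort(stats::rbinom(2L, 1L, stats::runif(1, 0.2, 0.8))),
                            simplify = FALSE)
      if (!any(unlist(gt_pairs) > 0L)) gt_pairs[[1]] <- c(0L, 1L)
      samples <- build_sample_calls(gt_pairs, config$depth_mean, 0)
      recs[[length(recs) + 1L]] <- site_record(
        chrom = planted$chrom[i], pos = planted$pos[i], ref = planted$ref[i],
        alts = planted$alt[i], qual = round(stats::runif(1, 200, 2000), 1),
        metrics = met_pl[i, ], samples = samples)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        chrom = planted$chrom[i], pos = planted$pos[i], ref = planted$ref[i],
        alt = planted$alt[i], site_class = "true", is_snv = TRUE,
        qd_absent = FALSE, dp_zero = FALSE, ad_zero = FALSE,
        forced_novel = planted$stratum[i] == "novel", stringsAsFactors = FALSE)
    }
  }
  ord <- order(vapply(recs, `[[`, "", "chrom"), vapply(recs, `[[`, 0L, "pos"))
  recs <- recs[ord]
  truth <- do.call(rbind, truth_rows[ord])  # truth rows are per-site blocks
  truth$key <- allele_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  truth$site <- site_key(truth$chrom, truth$pos)
  attr(recs, "sample_names") <- paste0("S", seq_len(config$n_samples))
  if (!is.null(path)) write_vcf(recs, path)
  list(records = recs, truth = truth, path = path)
}

write_panel_vcf <- function(entries, path) {
  # entries: data.frame chrom, pos, ref, alt, pass (logical)
  if (!nrow(entries)) {
    write_vcf(list(), path)
    return(invisible(path))
  }
  grp <- paste(entries$chrom, entries$pos, entries$ref, entries$pass)
  recs <- lapply(split(seq_len(nrow(entries)), grp), function(ix) {
    e <- entries[ix, , drop = FALSE]
    site_record(chrom = e$chrom[1], pos = e$pos[1], ref = e$ref[1],
                alts = unique(e$alt),
                filter = if (e$pass[1]) "PASS" else "RF")
  })
  ord <- order(vapply(recs, `[[`, "", "chrom"), vapply(recs, `[[`, 0L, "pos"))
  write_vcf(recs[ord], path)
}

#' Simulate truth and reference panels
#'
#' The two truth panels jointly contain exactly the true-labelled SNV
#' alleles (each allele lands in at least one). The 1000G-like panel (`kg`)
#' omits an exactly-counted novel fraction of eligible cohort alleles plus
#' all forced-novel planted alleles, and carries extra panel-only alleles
#' and different-alt entries at some novel positions. The gnomAD-like panel
#' (`gnm`) honours FILTER flags (a planted fraction fail) and omits a
#' chromosome entirely.
#'
#' @param config A [simulation_config()].
#' @param truth Ground-truth data frame from [simulate_cohort_vcf()].
#' @param dir Output directory for the panel VCFs.
#' @return List of paths (`truth_hapmap`, `truth_omni`, `kg`, `gnm`) plus the
#'   `truth` table augmented with expected per-allele panel statuses
#'   (`kg_status`, `gnm_status`, `gnm_fail_match`) and `novel_fraction_kg`,
#'   the exactly planted novel fraction among eligible alleles.
#' @export
simulate_panels <- function(config, truth, dir) {
  set.seed(derive_seed(config$seed, "panels"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snv <- truth[truth$is_snv, , drop = FALSE]

  # truth panels: union = true-labelled SNV alleles
  tr <- snv[snv$site_class == "true", , drop = FALSE]
  in_hap <- stats::runif(nrow(tr)) < 0.8
  in_omni <- stats::runif(nrow(tr)) < 0.8
  in_hap[!in_hap & !in_omni] <- TRUE
  p_hap <- file.path(dir, "truth_hapmap.vcf")
  p_omni <- file.path(dir, "truth_omni.vcf")
  write_panel_vcf(cbind(tr[in_hap, c("chrom", "pos", "ref", "alt")], pass = TRUE),
                  p_hap)
  write_panel_vcf(cbind(tr[in_omni, c("chrom", "pos", "ref", "alt")], pass = TRUE),
                  p_omni)

  # 1000G-like panel: exact planted novel fraction among eligible alleles
  eligible <- which(is.na(snv$forced_novel))
  n_novel <- round((1 - config$panel_overlap) * length(eligible))
  novel_idx <- eligible[sample.int(length(eligible), n_novel)]
  kg_member <- rep(FALSE, nrow(snv))
  kg_member[setdiff(eligible, novel_idx)] <- TRUE
  kg_member[which(snv$forced_novel %in% FALSE)] <- TRUE
  kg_status <- ifelse(kg_member, "known", "novel")

  # extra panel-only alleles at fresh positions
  n_extra <- round(config$panel_extra_fraction * nrow(snv))
  cl <- config$chrom_lengths
  extra_chrom <- sample(names(cl), n_extra, replace = TRUE,
                        prob = cl / sum(cl))
  extra_pos <- vapply(extra_chrom, function(cn) sample.int(cl[[cn]], 1L), 0L)
  extra_ref <- rand_base(n_extra)
  extra <- data.frame(chrom = extra_chrom, pos = extra_pos, ref = extra_ref,
                      alt = other_base(extra_ref), stringsAsFactors = FALSE)
  extra <- extra[!site_key(extra$chrom, extra$pos) %in% snv$site, , drop = FALSE]

  # different-alt entries at a fraction of novel positions; the substituted
  # alt must not equal any cohort allele at that site (multiallelic sites)
  diff_idx <- novel_idx[sample.int(length(novel_idx),
                                   round(config$diff_alt_fraction * length(novel_idx)))]
  diff_ent <- snv[diff_idx, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  site_alts <- split(snv$alt, snv$site)
  diff_ent$alt <- vapply(seq_len(nrow(diff_ent)), function(i) {
    taken <- c(diff_ent$ref[i],
               site_alts[[site_key(diff_ent$chrom[i], diff_ent$pos[i])]])
    free <- setdiff(c("A", "C", "G", "T"), taken)
    if (length(free)) free[1] else NA_character_
  }, "")
  diff_ent <- diff_ent[!is.na(diff_ent$alt), , drop = FALSE]
  kg_entries <- rbind(snv[kg_member, c("chrom", "pos", "ref", "alt")],
                      extra[, c("chrom", "pos", "ref", "alt")], diff_ent)
  kg_entries$pass <- TRUE
  p_kg <- file.path(dir, "panel_kg.vcf")
  write_panel_vcf(kg_entries, p_kg)

  # gnomAD-like panel: FILTER flags, excluded chromosome
  not_y <- snv$chrom != config$panel_excluded_chrom
  elig_b <- which(not_y & is.na(snv$forced_novel))
  n_novel_b <- round((1 - config$panel_overlap_b) * length(elig_b))
  novel_b <- elig_b[sample.int(length(elig_b), n_novel_b)]
  gnm_member <- rep(FALSE, nrow(snv))
  gnm_member[setdiff(elig_b, novel_b)] <- TRUE
  gnm_member[which(snv$forced_novel %in% FALSE & not_y)] <- TRUE
  gnm_fail <- gnm_member & stats::runif(nrow(snv)) < config$panel_fail_fraction
  gnm_entries <- snv[gnm_member, c("chrom", "pos", "ref", "alt")]
  gnm_entries$pass <- !gnm_fail[gnm_member]
  p_gnm <- file.path(dir, "panel_gnm.vcf")
  write_panel_vcf(gnm_entries, p_gnm)

  snv$kg_status <- kg_status
  snv$gnm_fail_match <- gnm_fail
  snv$gnm_status <- ifelse(!not_y, "not_assessed",
                           ifelse(gnm_member & !gnm_fail, "known", "novel"))
  list(truth_hapmap = p_hap, truth_omni = p_omni, kg = p_kg, gnm = p_gnm,
       truth = snv, novel_fraction_kg = n_novel / length(eligible))
}

#' Simulate two diverged populations and admixed query samples
#'
#' Ancestral allele frequencies are uniform on `[maf_floor, 1 - maf_floor]`;
#' each population's frequency is Balding-Nichols distributed,
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`; panel genotypes are binomial(2, freq).
#' Each query sample mixes the populations at its alpha:
#' genotype ~ binomial(2, alpha p1 + (1-alpha) p2). Site-selection and
#' query-side violations (inbred genotypes, close indels, mask gaps, low
#' qualities, uncalled and different-alt sites) are planted at configured
#' fractions and recorded in the ground truth.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (genotype/sample/catalog TSVs, mask
#'   BED and query VCF are written when given).
#' @return List: `panel` ([genotype_matrix()] with population labels),
#'   `query` (ideal query genotype matrix), `query_records` (query
#'   [site_record()]s with planted quality defects), `catalog` (all panel
#'   variants incl. planted indels), `mask`, `sites` ground-truth table and
#'   `paths`.
#' @export
simulate_populations <- function(config, dir = NULL) {
  set.seed(derive_seed(config$seed, "populations"))
  m <- config$n_pop_sites
  n_pop <- config$n_pop_samples
  alphas <- config$admixture_alphas
  chrom <- "chr1"
  pos <- cumsum(sample(500:1500, m, replace = TRUE)) + 1000L
  ref <- rand_base(m)
  alt <- other_base(ref)
  keys <- allele_key(chrom, pos, ref, alt)

  p_anc <- stats::runif(m, config$maf_floor, 1 - config$maf_floor)
  F <- config$fst
  shp <- (1 - F) / F
  p1 <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
  p2 <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
  p1 <- pmin(pmax(p1, 0.01), 0.99); p2 <- pmin(pmax(p2, 0.01), 0.99)

  hwe_vio <- stats::runif(m) < config$hwe_violation_fraction
  draw_pop <- function(p) {
    g <- matrix(stats::rbinom(n_pop * m, 2L, rep(p, each = n_pop)), nrow = n_pop)
    g
  }
  g1 <- draw_pop(p1); g2 <- draw_pop(p2)
  # planted HWE violations: inbreeding coefficient 0.5 in both populations
  for (j in which(hwe_vio)) {
    f_is <- 0.5
    gen <- function(p) {
      probs <- c((1 - p)^2 + f_is * p * (1 - p),
                 2 * p * (1 - p) * (1 - f_is),
                 p^2 + f_is * p * (1 - p))
      sample(0:2, n_pop, replace = TRUE, prob = probs)
    }
    g1[, j] <- gen(p1[j]); g2[, j] <- gen(p2[j])
  }
  panel <- rbind(g1, g2)
  rownames(panel) <- c(paste0("POP1_", seq_len(n_pop)),
                       paste0("POP2_", seq_len(n_pop)))
  colnames(panel) <- keys
  panel <- genotype_matrix(panel, populations = rep(c("POP1", "POP2"),
                                                    each = n_pop))

  # planted indels within proximity_bp of some sites
  prox_vio <- stats::runif(m) < config$prox_violation_fraction
  indel_pos <- pos[prox_vio] + sample(1:5, sum(prox_vio), replace = TRUE)
  indel_ref <- rand_base(sum(prox_vio))
  catalog <- rbind(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, type = "snv",
               stringsAsFactors = FALSE),
    data.frame(chrom = chrom, pos = indel_pos, ref = indel_ref,
               alt = paste0(indel_ref, rand_base(sum(prox_vio))),
               type = "indel", stringsAsFactors = FALSE))

  # accessibility mask: whole span minus planted gaps
  mask_vio <- stats::runif(m) < config$mask_gap_fraction
  gap_start <- pos[mask_vio] - 1L  # 0-based, one-position gaps
  span_end <- max(pos) + 10000L
  bounds <- sort(unique(c(0L, gap_start, gap_start + 1L, span_end)))
  iv <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  iv <- iv[!iv$start %in% gap_start, , drop = FALSE]
  mask <- mask_regions(rep(chrom, nrow(iv)), iv$start, iv$end)

  # query samples
  n_q <- length(alphas)
  p_mix <- outer(p1, alphas) + outer(p2, 1 - alphas)  # m x n_q
  query <- t(matrix(stats::rbinom(m * n_q, 2L, as.vector(p_mix)), nrow = m))
  rownames(query) <- paste0("Q", seq_len(n_q))
  colnames(query) <- keys

  q_fail <- stats::runif(m) < config$query_fail_fraction
  q_uncalled <- stats::runif(m) < config$query_uncalled_fraction
  q_diffalt <- stats::runif(m) < config$query_diffalt_fraction
  query_records <- lapply(seq_len(m), function(j) {
    alt_j <- if (q_diffalt[j])
      setdiff(c("A", "C", "G", "T"), c(ref[j], alt[j]))[1] else alt[j]
    homref <- all(query[, j] == 0L)
    samples <- lapply(seq_len(n_q), function(s) {
      g <- query[s, j]
      if (q_uncalled[j]) return(sample_call(gt = NA))
      gt <- c(if (g == 2L) 1L else 0L, if (g >= 1L) 1L else 0L)
      gq <- sample(40:99, 1L)
      rgq <- if (homref) sample(40:99, 1L) else NULL
      if (q_fail[j] && s == 1L) { gq <- 15L; rgq <- if (homref) 10L else NULL }
      sample_call(gt = sort(gt), ad = NULL, dp = stats::rpois(1, 30) + 11L,
                  gq = gq, rgq = rgq)
    })
    site_record(chrom = chrom, pos = pos[j], ref = ref[j], alts = alt_j,
                qual = if (q_fail[j] && homref) 20 else round(stats::runif(1, 60, 900), 1),
                samples = samples)
  })
  attr(query_records, "sample_names") <- rownames(query)

  sites <- data.frame(key = keys, chrom = chrom, pos = pos, ref = ref,
                      alt = alt, p_anc = p_anc, p1 = p1, p2 = p2,
                      hwe_violation = hwe_vio, prox_violation = prox_vio,
                      mask_violation = mask_vio, query_fail = q_fail,
                      query_uncalled = q_uncalled, query_diffalt = q_diffalt,
                      stringsAsFactors = FALSE)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      panel_genotypes = file.path(dir, "pop_panel_genotypes.tsv"),
      panel_samples = file.path(dir, "pop_panel_samples.tsv"),
      catalog = file.path(dir, "pop_catalog.tsv"),
      mask = file.path(dir, "strict_mask.bed"),
      query_vcf = file.path(dir, "query.vcf"))
    write_genotype_matrix(panel, paths$panel_genotypes)
    utils::write.table(
      data.frame(sample = rownames(panel),
                 population = attr(panel, "populations")),
      paths$panel_samples, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(catalog, paths$catalog, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(chrom = chrom, start = iv$start, end = iv$end),
      paths$mask, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    write_vcf(query_records, paths$query_vcf)
  }
  list(panel = panel, query = query, query_records = query_records,
       catalog = catalog, mask = mask, sites = sites, alphas = alphas,
       paths = paths)
}

#' Effect of a CDS substitution by whole-CDS retranslation
#'
#' Validation oracle for [effect_of()]: rebuilds the full coding sequence
#' with and without the substitution, translates both with
#' [Biostrings::translate()], and compares the affected amino acid.
#'
#' @param allele List with `chrom, pos, ref, alt`.
#' @param model A coding [gene_model()].
#' @param genome Named character vector of chromosome sequences.
#' @return One of [EFFECT_CLASSES].
#' @export
effect_by_retranslation <- function(allele, model, genome) {
  cpos <- cds_positions(model)
  seq_chr <- genome[[model$chrom]]
  bases <- vapply(cpos, function(p) substr(seq_chr, p, p), "")
  i <- match(allele$pos, cpos)
  if (is.na(i)) stop_popnovel("effect_by_retranslation: allele not in CDS")
  new_bases <- bases
  new_bases[i] <- allele$alt
  if (model$strand == "-") {
    bases <- COMPLEMENT[bases]; new_bases <- COMPLEMENT[new_bases]
  }
  L <- 3L * (length(bases) %/% 3L)
  ci <- (i - 1L) %/% 3L + 1L
  if (ci > L %/% 3L) return("unknown")
  tr <- function(b) as.character(Biostrings::translate(
    Biostrings::DNAString(paste(b[seq_len(L)], collapse = ""))))
  old_aa <- substr(tr(bases), ci, ci)
  new_aa <- substr(tr(new_bases), ci, ci)
  if (old_aa == new_aa) return("synonymous")
  if (new_aa == "*") return("stop_gain")
  if (old_aa == "*") return("stop_loss")
  "nonsynonymous"
}

#' Simulate transcript models, a toy genome and planted functional alleles
#'
#' Places non-overlapping coding and non-coding transcripts on a toy
#' chromosome and plants SNV alleles with known sequence classes (one batch
#' per class) and known exonic effects, with a configurable stop-gain
#' enrichment in the "novel" stratum relative to all exonic alleles.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (`genes.tsv`, `genome.fa` written
#'   when given).
#' @return List: `models`, `genome` (named character vector), `alleles`
#'   (planted data frame: chrom, pos, ref, alt, class, effect, stratum) and
#'   `paths`.
#' @export
simulate_gene_models <- function(config, dir = NULL) {
  set.seed(derive_seed(config$seed, "genes"))
  chrom <- "chrG"
  glen <- config$gene_chrom_length
  genome_chars <- rand_base(glen)
  genome <- stats::setNames(paste(genome_chars, collapse = ""), chrom)
  base_at <- function(p) genome_chars[p]

  models <- list()
  cursor <- 3000L
  for (i in seq_len(config$gene_model_count)) {
    coding <- i %% 2L == 1L
    n_ex <- sample(3:4, 1L)
    ex_len <- sample(250:450, n_ex, replace = TRUE)
    in_len <- sample(300:800, n_ex - 1L, replace = TRUE)
    starts <- integer(n_ex); ends <- integer(n_ex)
    p <- cursor
    for (e in seq_len(n_ex)) {
      starts[e] <- p; ends[e] <- p + ex_len[e] - 1L
      p <- ends[e] + 1L + if (e < n_ex) in_len[e] else 0L
    }
    cds_start <- cds_end <- NA
    if (coding) {
      cds_start <- starts[1] + sample(40:80, 1L)
      cds_end <- ends[n_ex] - sample(40:80, 1L)
      tmp <- gene_model(paste0("TX", i), paste0("G", i), chrom,
                        sample(c("+", "-"), 1L), starts, ends,
                        cds_start, cds_end, coding = TRUE)
      extra <- length(cds_positions(tmp)) %% 3L
      cds_end <- cds_end - extra
      strand <- tmp$strand
    } else strand <- sample(c("+", "-"), 1L)
    models[[i]] <- gene_model(paste0("TX", i), paste0("G", i), chrom, strand,
                              starts, ends, cds_start, cds_end,
                              coding = coding)
    cursor <- ends[n_ex] + sample(2300:4500, 1L)
    if (cursor > glen - 8000L) break
  }

  used <- new.env(hash = TRUE)
  claim <- function(p) {
    k <- as.character(p)
    if (!is.null(used[[k]])) return(FALSE)
    used[[k]] <- TRUE
    TRUE
  }
  # (positions are claimed exactly once so planted allele keys never collide)
  plant <- function(p, class, effect = NA_character_, stratum = NA_character_) {
    ref <- base_at(p)
    data.frame(chrom = chrom, pos = p, ref = ref, alt = other_base(ref),
               class = class, effect = effect, stratum = stratum,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  coding_models <- Filter(function(m) m$coding, models)
  nonc_models <- Filter(function(m) !m$coding, models)
  nper <- config$n_per_other_class
  # per-class planting positions derived from transcript structure
  for (b in seq_len(nper)) {
    mc <- coding_models[[1L + (b - 1L) %% length(coding_models)]]
    mn <- nonc_models[[1L + (b - 1L) %% length(nonc_models)]]
    cands <- list(
      splicing = mc$exon_ends[1] + sample(1:2, 1L),
      intronic = (mc$exon_ends[1] + mc$exon_starts[2]) %/% 2L,
      UTR5 = if (mc$strand == "+") mc$exon_starts[1] + sample(5:20, 1L)
             else mc$exon_ends[length(mc$exon_ends)] - sample(5:20, 1L),
      UTR3 = if (mc$strand == "+") mc$exon_ends[length(mc$exon_ends)] - sample(5:20, 1L)
             else mc$exon_starts[1] + sample(5:20, 1L),
      ncRNA_exonic = mn$exon_starts[1] + sample(10:100, 1L),
      ncRNA_splicing = mn$exon_ends[1] + sample(1:2, 1L),
      ncRNA_intronic = (mn$exon_ends[1] + mn$exon_starts[2]) %/% 2L,
      upstream = if (mc$strand == "+") mc$exon_starts[1] - sample(3:900, 1L)
                 else mc$exon_ends[length(mc$exon_ends)] + sample(3:900, 1L),
      downstream = if (mc$strand == "+") mc$exon_ends[length(mc$exon_ends)] + sample(3:900, 1L)
                   else mc$exon_starts[1] - sample(3:900, 1L))
    for (cl in names(cands)) {
      p <- cands[[cl]]
      if (p < 1L || p > glen || !claim(p)) next
      rows[[length(rows) + 1L]] <- plant(p, cl, stratum =
        if (stats::runif(1) < 0.2) "novel" else "known")
    }
    # intergenic: midpoint of the gap after transcript mc where wide enough
    mi <- match(mc$transcript, vapply(models, `[[`, "", "transcript"))
    if (mi < length(models)) {
      gap_s <- models[[mi]]$exon_ends[length(models[[mi]]$exon_ends)]
      gap_e <- models[[mi + 1L]]$exon_starts[1]
      if (gap_e - gap_s > 2L * config$flank_bp + 200L) {
        p <- (gap_s + gap_e) %/% 2L
        if (claim(p))
          rows[[length(rows) + 1L]] <- plant(p, "intergenic", stratum =
            if (stats::runif(1) < 0.2) "novel" else "known")
      }
    }
  }

  # exonic alleles with designed effects and stop-gain enrichment
  f <- config$n_exonic_novel / (config$n_exonic_novel + config$n_exonic_known)
  r_n <- config$novel_nonsense_rate
  r_k <- r_n * (1 / config$nonsense_enrichment - f) / (1 - f)
  if (r_k < 0)
    stop_popnovel("simulation_config: nonsense enrichment unattainable at ",
                  "this novel-stratum share; lower n_exonic_novel")
  plant_exonic <- function(n_alleles, rate, stratum) {
    out <- vector("list", n_alleles)
    for (a in seq_len(n_alleles)) {
      want_stop <- stats::runif(1) < rate
      mc <- coding_models[[1L + (a - 1L) %% length(coding_models)]]
      cpos <- cds_positions(mc)
      cpos <- cpos[seq_len(3L * (length(cpos) %/% 3L))]
      done <- FALSE
      for (try in seq_len(300L)) {
        p <- sample(cpos, 1L)
        if (!is.null(used[[as.character(p)]])) next
        ref <- base_at(p)
        alts <- sample(setdiff(c("A", "C", "G", "T"), ref))
        for (alt in alts) {
          eff <- effect_by_retranslation(list(chrom = chrom, pos = p,
                                              ref = ref, alt = alt),
                                         mc, genome)
          if ((eff == "stop_gain") == want_stop) {
            used[[as.character(p)]] <- TRUE
            out[[a]] <- data.frame(chrom = chrom, pos = p, ref = ref,
                                   alt = alt, class = "exonic", effect = eff,
                                   stratum = stratum, stringsAsFactors = FALSE)
            done <- TRUE
            break
          }
        }
        if (done) break
      }
    }
    do.call(rbind, out)
  }
  ex_known <- plant_exonic(config$n_exonic_known, r_k, "known")
  ex_novel <- plant_exonic(config$n_exonic_novel, r_n, "novel")
  alleles <- rbind(do.call(rbind, rows), ex_known, ex_novel)
  alleles <- alleles[order(alleles$pos), , drop = FALSE]
  rownames(alleles) <- NULL
  alleles$key <- allele_key(alleles$chrom, alleles$pos, alleles$ref, alleles$alt)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genes = file.path(dir, "genes.tsv"),
                  genome = file.path(dir, "genome.fa"))
    write_gene_models(models, paths$genes)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome), paths$genome)
  }
  list(models = models, genome = genome, alleles = alleles, paths = paths)
}

#' Generate the complete synthetic input bundle
#'
#' Orchestrates [simulate_gene_models()], [simulate_cohort_vcf()] (with the
#' planted gene-region alleles merged in), [simulate_panels()] and
#' [simulate_populations()], writing every pipeline input file to `dir`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return List: `paths` (all written files), `truth` (cohort/panel/gene/
#'   population ground truth) and `config`.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- simulate_gene_models(config, dir)
  cohort <- simulate_cohort_vcf(config, path = file.path(dir, "cohort.vcf"),
                                planted = genes$alleles)
  panels <- simulate_panels(config, cohort$truth, dir)
  pops <- simulate_populations(config, dir)
  lengths_path <- file.path(dir, "lengths.tsv")
  utils::write.table(
    data.frame(chrom = names(config$chrom_lengths),
               length = as.integer(config$chrom_lengths)),
    lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(paths = c(list(cohort = cohort$path, lengths = lengths_path,
                      genes = genes$paths$genes, genome = genes$paths$genome),
                 panels[c("truth_hapmap", "truth_omni", "kg", "gnm")],
                 pops$paths),
       truth = list(cohort = cohort$truth, panels = panels$truth,
                    novel_fraction_kg = panels$novel_fraction_kg,
                    genes = genes, populations = pops),
       autosomes = setdiff(names(config$chrom_lengths), c("chrX", "chrY")),
       config = config)
}
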