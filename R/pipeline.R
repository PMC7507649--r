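# End-to-end orchestration: normalize -> prefilter -> QC cascade -> novelty
# -> annotation -> spectra/bins -> ancestry, with a run manifest.

#' Read/write a genotype matrix TSV
#'
#' Samples in rows (first column `sample`), site keys as remaining column
#' names.
#'
#' @param matrix A [genotype_matrix()].
#' @param path File path.
#' @param populations_path Optional two-column (sample, population) TSV used
#'   to restore population labels on read.
#' @export
write_genotype_matrix <- function(matrix, path) {
  df <- data.frame(sample = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path, populations_path = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$sample
  pops <- NULL
  if (!is.null(populations_path)) {
    ps <- utils::read.table(populations_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    pops <- ps$population[match(rownames(mat), ps$sample)]
  }
  genotype_matrix(mat, populations = pops)
}

read_chrom_lengths <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$length), tab$chrom)
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration consumed by [run_pipeline()].
#' `inputs` are file paths as produced by [simulate_inputs()] (or real
#' equivalents); `params` tunes the stages.
#'
#' @param seed Integer seed for the stochastic stages (mixture-model
#'   initialisation); required.
#' @param outdir Output directory.
#' @param inputs Named list of paths: `cohort`, `truth_hapmap`, `truth_omni`,
#'   `kg`, `gnm`, `genes`, `genome`, `lengths`, `panel_genotypes`,
#'   `panel_samples`, `catalog`, `mask`, `query_vcf`. Ancestry and
#'   annotation stages are skipped when their inputs are `NULL`.
#' @param params Named list overriding defaults: `autosomes`,
#'   `score_threshold` (-0.5), `score_metrics`, `mixture_k` (2), `flank_bp`
#'   (1000), `block_bp` (1e7), `pca_k` (2), `excluded_regions`,
#'   `gnm_excluded_chroms` ("chrY"), plus any [site_selection_config()]
#'   field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, outdir, inputs, params = list()) {
  if (missing(seed) || is.null(seed))
    stop_popnovel("pipeline_config: seed is required")
  defaults <- list(autosomes = default_autosomes(),
                   score_threshold = -0.5,
                   score_metrics = c("DP", "SOR", "ReadPosRankSum", "FS"),
                   mixture_k = 2L, flank_bp = 1000L, block_bp = 10000000,
                   pca_k = 2L,
                   excluded_regions = list(),
                   gnm_excluded_chroms = "chrY")
  params <- utils::modifyList(defaults, params)
  for (nm in names(inputs)) {
    p <- inputs[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop_popnovel("pipeline_config: input '", nm, "' does not exist: ", p)
  }
  structure(list(seed = as.integer(seed), outdir = outdir, inputs = inputs,
                 params = params), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with top-level `seed`, `outdir`, `inputs`, `params`.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(seed = y$seed, outdir = y$outdir, inputs = y$inputs,
                  params = y$params %||% list())
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes normalize, prefilter, the QC cascade, novelty assessment against
#' both reference panels, functional annotation, allele-count spectra,
#' block densities and the ancestry projection, writing one TSV per result
#' plus a JSON run manifest (seed, input digests, output digests). Reruns
#' with identical inputs and seed are byte-stable.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Invisibly, a list with the in-memory results (`qc`, `novelty`,
#'   `annotation`, `spectra`, `bins`, `ancestry`, `manifest`, `outputs`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  inp <- config$inputs; par <- config$params
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  out_path <- function(f) file.path(config$outdir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_popnovel("pipeline stage '", name, "' failed: ",
                    conditionMessage(e)))
  }

  # --- normalize + prefilter + QC -------------------------------------------
  records <- stage("read", read_vcf(inp$cohort))
  sample_names <- attr(records, "sample_names")
  pre <- stage("prefilter", prefilter_sites(records, autosomes = par$autosomes))
  split_recs <- stage("normalize", {
    s <- unlist(lapply(pre, split_multiallelic), recursive = FALSE)
    attr(s, "sample_names") <- sample_names
    s
  })
  truth_panels <- stage("truth_panels", lapply(
    c(inp$truth_hapmap, inp$truth_omni), function(p)
      truth_panel(normalize_records(read_vcf(p)), name = basename(p))))
  labels <- stage("classify", classify_sites(split_recs, truth_panels))
  if (isTRUE(par$skip_qc)) {
    # pass-through: downstream stages consume the prefiltered SNV set unchanged
    snv <- vapply(split_recs, function(r)
      nchar(r$ref) == 1L && all(nchar(r$alts) == 1L), TRUE)
    qc <- list(kept = split_recs[snv], labels = labels[snv],
               report = data.frame(), overall = list(
                 n_before = sum(snv), n_kept = sum(snv),
                 true_retention = 1, other_retention = 1,
                 ratio_increase = 1, fraction_removed = 0),
               score_model = NULL, scores = NULL)
    qc_tab <- data.frame(stage = "skipped")
  } else {
    stages <- c(default_qc_rules(),
                list(vqslod = list(type = "score", metrics = par$score_metrics,
                                   k = par$mixture_k,
                                   threshold = par$score_threshold,
                                   seed = derive_seed(config$seed, "mixture"))))
    qc <- stage("qc", apply_qc_cascade(split_recs, labels, stages))
    overall <- qc$overall
    qc_tab <- rbind(qc$report,
                    data.frame(stage = "overall",
                               n_true_before = qc$report$n_true_before[1],
                               n_true_kept = sum(qc$labels == "true"),
                               n_other_before = qc$report$n_other_before[1],
                               n_other_kept = sum(qc$labels == "other"),
                               true_retention = overall$true_retention,
                               other_retention = overall$other_retention,
                               discrimination_factor = overall$ratio_increase))
  }
  outputs$qc_report <- write_tsv(qc_tab, out_path("qc_report.tsv"))

  kept <- qc$kept
  attr(kept, "sample_names") <- sample_names
  alleles <- stage("normalize_kept", normalize_records(kept))

  # --- novelty ---------------------------------------------------------------
  novelty <- list()
  if (!is.null(inp$kg)) {
    panel_kg <- stage("panel_kg", build_panel(inp$kg, use_filter_column = FALSE,
                                              name = "kg"))
    novelty$kg <- assess_novelty(alleles, panel_kg)
  }
  if (!is.null(inp$gnm)) {
    panel_gnm <- stage("panel_gnm", build_panel(
      inp$gnm, use_filter_column = TRUE,
      excluded_chroms = par$gnm_excluded_chroms, name = "gnm"))
    novelty$gnm <- assess_novelty(alleles, panel_gnm)
  }
  if (length(novelty)) {
    nov_tab <- do.call(rbind, lapply(novelty, function(nv)
      nv$alleles[, c("chrom", "pos", "ref", "alt", "panel", "status")]))
    rownames(nov_tab) <- NULL
    outputs$novelty <- write_tsv(nov_tab, out_path("novelty.tsv"))
  }

  # --- annotation ------------------------------------------------------------
  annotation <- NULL
  if (!is.null(inp$genes) && !is.null(inp$genome)) {
    models <- stage("genes", read_gene_models(inp$genes))
    lookup <- make_genome_lookup(inp$genome)
    model_chroms <- unique(vapply(models, `[[`, "", "chrom"))
    ann_alleles <- alleles[alleles$is_snv & alleles$chrom %in% model_chroms, ,
                           drop = FALSE]
    annotation <- stage("annotate", annotate_alleles(
      ann_alleles[, c("chrom", "pos", "ref", "alt")], models,
      genome_lookup = lookup, flank_bp = par$flank_bp))
    subsets <- list(all = NULL)
    for (nm in names(novelty)) {
      nv <- novelty[[nm]]$alleles
      subsets[[paste0("novel_", nm)]] <- nv$key[nv$status == "novel"]
    }
    summary_tab <- summarize_classes(annotation, subsets)
    outputs$annotation <- write_tsv(summary_tab, out_path("annot_summary.tsv"))
  }

  # --- spectra and bins ------------------------------------------------------
  snv_kept <- kept[vapply(kept, function(r)
    nchar(r$ref) == 1L && nchar(r$alts[1]) == 1L, TRUE)]
  spec_subsets <- c(list(all = NULL),
                    stats::setNames(lapply(novelty, function(nv)
                      nv$alleles$key[nv$alleles$status == "novel"]),
                      paste0("novel_", names(novelty))))
  spectra <- lapply(spec_subsets, function(s) allele_spectrum(snv_kept, subset = s))
  spec_tab <- do.call(rbind, lapply(names(spectra), function(nm)
    data.frame(subset = nm, copies = names(spectra[[nm]]$spectrum),
               count = as.integer(spectra[[nm]]$spectrum),
               stringsAsFactors = FALSE)))
  outputs$spectra <- write_tsv(spec_tab, out_path("spectra.tsv"))

  bins <- NULL
  if (!is.null(inp$lengths)) {
    chrom_lengths <- read_chrom_lengths(inp$lengths)
    sites_df <- unique(data.frame(
      chrom = vapply(snv_kept, `[[`, "", "chrom"),
      pos = vapply(snv_kept, function(r) r$pos, 0L)))
    bins <- stage("bins", bin_density(sites_df,
                                      chrom_lengths[names(chrom_lengths) %in%
                                                    c(par$autosomes, unique(sites_df$chrom))],
                                      block_bp = par$block_bp))
    outputs$bins <- write_tsv(bin_density_table(bins), out_path("bins.tsv"))
  }

  # --- ancestry --------------------------------------------------------------
  ancestry <- NULL
  if (!is.null(inp$panel_genotypes)) {
    ancestry <- stage("ancestry", {
      panel <- read_genotype_matrix(inp$panel_genotypes, inp$panel_samples)
      catalog <- utils::read.table(inp$catalog, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
      mask <- if (!is.null(inp$mask)) read_bed(inp$mask) else NULL
      cfg <- site_selection_config(mask = mask,
                                   excluded_regions = par$excluded_regions)
      sel <- select_sites(panel, catalog, cfg)
      query_records <- read_vcf(inp$query_vcf)
      qf <- apply_query_filters(query_records, sel$sites, cfg)
      sites2 <- exclude_regions(qf$kept_sites, cfg$excluded_regions)
      panel2 <- impute_mean(panel[, sites2, drop = FALSE])
      pruned <- ld_prune(panel2, window = cfg$ld_window, step = cfg$ld_step,
                         vif_max = cfg$vif_max)
      model <- fit_pca(panel2[, pruned, drop = FALSE], k = par$pca_k)
      scores <- project_samples(model, qf$matrix[, pruned, drop = FALSE])
      list(selection = sel, query_filter = qf, pruned = pruned, model = model,
           scores = scores)
    })
    ref_scores <- data.frame(sample = rownames(ancestry$model$scores),
                             population = ancestry$model$populations %||% "REF",
                             ancestry$model$scores, check.names = FALSE)
    q_scores <- data.frame(sample = rownames(ancestry$scores),
                           population = "QUERY", ancestry$scores,
                           check.names = FALSE)
    outputs$pca_scores <- write_tsv(rbind(ref_scores, q_scores),
                                    out_path("pca_scores.tsv"))
    outputs$attrition <- write_tsv(ancestry$selection$attrition,
                                   out_path("site_attrition.tsv"))
  }

  # --- manifest --------------------------------------------------------------
  in_files <- unlist(Filter(Negate(is.null), inp))
  manifest <- list(
    package = "popnovel",
    version = as.character(utils::packageVersion("popnovel")),
    seed = config$seed,
    inputs = as.list(tools::md5sum(in_files)),
    outputs = as.list(tools::md5sum(unlist(outputs))))
  manifest_path <- out_path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  outputs$manifest <- manifest_path

  invisible(list(qc = qc, novelty = novelty, annotation = annotation,
                 spectra = spectra, bins = bins, ancestry = ancestry,
                 manifest = manifest, outputs = outputs))
}
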