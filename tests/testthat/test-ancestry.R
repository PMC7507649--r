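# HWE exact test, site-selection cascade, query filters, LD pruning and PCA.

test_that("HWE exact test: boundary tables and enumeration oracle", {
  # two individuals, two A and two a alleles, both heterozygous
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  # monomorphic sites are not testable
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "total")
  set.seed(141)
  for (i in 1:200) {
    n <- sample(1:10, 3, replace = TRUE)  # totals up to 30
    expect_equal(hwe_exact_test(n[1], n[2], n[3]),
                 oracle_hwe(n[1], n[2], n[3]), tolerance = 1e-10)
  }
})

test_that("site selection applies MAF/proximity/mask/HWE boundaries", {
  set.seed(142)
  n_s <- 60
  # 10 samples; column 1 has MAF exactly 0.05 (1 alt allele in 20)
  g <- matrix(rbinom(10 * n_s, 2, 0.4), nrow = 10)
  g[, 1] <- c(1, rep(0, 9))
  pos <- seq(100L, by = 100L, length.out = n_s)
  colnames(g) <- allele_key("chr1", pos, "A", "C")
  gm <- genotype_matrix(g)
  # an indel exactly 5 bp from site 2 (inclusive boundary -> excluded)
  catalog <- rbind(data.frame(chrom = "chr1", pos = pos, ref = "A",
                              alt = "C", type = "snv"),
                   data.frame(chrom = "chr1", pos = pos[2] + 5L, ref = "T",
                              alt = "TA", type = "indel"))
  sel <- select_sites(gm, catalog, site_selection_config())
  expect_false(colnames(g)[1] %in% sel$sites)   # MAF 0.05 is not > 0.05
  expect_false(colnames(g)[2] %in% sel$sites)   # within 5 bp of an indel
  # attrition sums to input minus output
  expect_equal(sum(sel$attrition$n_removed), n_s - length(sel$sites))
  # a mask covering only the first half drops the rest
  mask <- mask_regions("chr1", 0, pos[30])
  sel2 <- select_sites(gm, catalog, site_selection_config(mask = mask))
  expect_true(all(popnovel:::key_coords(sel2$sites)$pos <= pos[30]))
})

test_that("planted HWE violators are removed from a large panel", {
  cfg <- simulation_config(seed = 143L, n_pop_samples = 250L,
                           n_pop_sites = 600L)
  pop <- simulate_populations(cfg)
  sel <- select_sites(pop$panel, pop$catalog, site_selection_config())
  truth <- pop$sites
  # violators that reached the HWE stage (passed MAF + proximity) must be gone
  reached <- truth$key[truth$hwe_violation &
                       pmin(truth$p1, 1 - truth$p1) > 0.1 &
                       pmin(truth$p2, 1 - truth$p2) > 0.1 &
                       !truth$prox_violation]
  expect_true(all(!reached %in% sel$sites))
  # and most clean common sites survive
  common_clean <- truth$key[!truth$hwe_violation & !truth$prox_violation &
                            !truth$mask_violation &
                            pmin((truth$p1 + truth$p2) / 2,
                                 1 - (truth$p1 + truth$p2) / 2) > 0.15]
  expect_gt(mean(common_clean %in% sel$sites), 0.9)
})

test_that("query-side filters enforce the quality thresholds", {
  cfg <- site_selection_config()
  sel_keys <- allele_key("chr1", c(100L, 200L, 300L, 400L), "A", "C")
  mk_q <- function(pos, gts, qual, dps, gqs, rgqs) {
    r <- make_rec(pos = pos, gts = gts, qual = qual, dps = dps, gqs = gqs,
                  rgqs = rgqs)
    r
  }
  recs <- list(
    # hom-ref with QUAL 29 -> excluded
    mk_q(100L, list(c(0L, 0L), c(0L, 0L)), 29, list(30, 30),
         list(90, 90), list(50, 50)),
    # variant with one GQ 19 -> excluded
    mk_q(200L, list(c(0L, 1L), c(0L, 0L)), 500, list(30, 30),
         list(19, 90), list(NULL, 50)),
    # good variant -> kept
    mk_q(300L, list(c(0L, 1L), c(1L, 1L)), 500, list(30, 30),
         list(90, 90), list(NULL, NULL)),
    # good hom-ref -> kept
    mk_q(400L, list(c(0L, 0L), c(0L, 0L)), 100, list(30, 30),
         list(90, 90), list(50, 50)))
  attr(recs, "sample_names") <- c("Q1", "Q2")
  res <- apply_query_filters(recs, sel_keys, cfg)
  expect_equal(res$kept_sites, sel_keys[3:4])
  expect_setequal(res$excluded$reason, c("homref_quality", "variant_quality"))
  expect_equal(unname(res$matrix[, 1]), c(1, 2))
})

test_that("query filters agree with the generator's planted ground truth", {
  cfg <- simulation_config(seed = 144L, n_pop_sites = 800L,
                           n_pop_samples = 30L)
  pop <- simulate_populations(cfg)
  truth <- pop$sites
  res <- apply_query_filters(pop$query_records, truth$key,
                             site_selection_config())
  bad <- truth$query_fail | truth$query_uncalled | truth$query_diffalt
  expect_true(all(!truth$key[bad] %in% res$kept_sites))
  expect_true(all(truth$key[!bad] %in% res$kept_sites))
  # surviving genotypes equal the simulated query matrix
  expect_equal(unname(res$matrix),
               unname(pop$query[, res$kept_sites, drop = FALSE]))
})

test_that("LD pruning: forced removal, independents kept, audited bound", {
  set.seed(145)
  # two perfectly correlated sites -> exactly one retained
  base <- rbinom(60, 2, 0.5)
  g2 <- cbind(base, base)
  colnames(g2) <- allele_key("chr1", c(10L, 20L), "A", "C")
  kept <- ld_prune(genotype_matrix(g2), window = 10, step = 2, vif_max = 2)
  expect_length(kept, 1)

  # mutually independent sites are all retained
  gi <- sapply(1:40, function(j) rbinom(80, 2, 0.5))
  colnames(gi) <- allele_key("chr1", seq_len(40) * 10L, "A", "C")
  expect_length(ld_prune(genotype_matrix(gi), window = 10, step = 2,
                         vif_max = 2), 40)
  expect_error(ld_prune(genotype_matrix(gi), window = 1), "window")

  # random correlated matrices: post-hoc audit and idempotence
  for (s in 1:3) {
    set.seed(145 + s)
    n <- 100; p <- 200
    latent <- matrix(rbinom(n * 20, 2, 0.5), nrow = n)
    g <- sapply(1:p, function(j) {
      src <- latent[, sample(20, 1)]
      flip <- rbinom(n, 1, 0.15)
      pmin(2, pmax(0, ifelse(flip == 1, rbinom(n, 2, 0.5), src)))
    })
    colnames(g) <- allele_key("chr1", seq_len(p) * 50L, "A", "C")
    g <- genotype_matrix(g)
    kept <- ld_prune(g, window = 50, step = 5, vif_max = 2)
    expect_lte(vif_audit(g[, kept, drop = FALSE], window = 50, step = 5),
               2 + 1e-8)
    kept2 <- ld_prune(g[, kept, drop = FALSE], window = 50, step = 5,
                      vif_max = 2)
    expect_identical(kept2, kept)
  }
})

test_that("PCA centring, projection consistency and score covariance", {
  # two antipodal samples: PC1 scores symmetric about 0
  g <- rbind(c(0, 0, 2, 2), c(2, 2, 0, 0))
  colnames(g) <- allele_key("chr1", 1:4 * 10L, "A", "C")
  rownames(g) <- c("a", "b")
  model <- fit_pca(genotype_matrix(g), k = 1)
  expect_equal(sum(model$scores[, 1]), 0, tolerance = 1e-12)

  set.seed(146)
  gm <- matrix(rbinom(30 * 120, 2, 0.4), nrow = 30)
  gm[, 1] <- c(rep(0, 15), rep(2, 15))  # keep every column polymorphic
  colnames(gm) <- allele_key("chr1", seq_len(120) * 10L, "A", "C")
  rownames(gm) <- paste0("s", 1:30)
  gm <- genotype_matrix(gm)
  model <- fit_pca(gm, k = 5)
  # training-score reproduction through project_samples
  proj <- project_samples(model, gm)
  expect_lt(max(abs(proj - model$scores)), 1e-8)
  # covariance of scores is diagonal with singular-value variances
  cv <- stats::cov(model$scores)
  expect_equal(unname(diag(cv)), model$sdev^2, tolerance = 1e-10)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  # the per-site mean genotype projects to the origin
  mean_q <- matrix(model$center, nrow = 1,
                   dimnames = list("m", names(model$center)))
  expect_equal(max(abs(project_samples(model, mean_q))), 0, tolerance = 1e-12)
  # zero-variance sites are refused by name
  gz <- gm; gz[, 2] <- 1
  expect_error(fit_pca(genotype_matrix(gz)), "zero-variance")
  # missing model sites are reported
  expect_error(project_samples(model, gm[, -1, drop = FALSE]), "lacks")
})

test_that("extended-LD regions are excluded by coordinates", {
  sites <- allele_key("chr6", c(24999999L, 25000000L, 30000000L, 35000001L),
                      "A", "C")
  out <- exclude_regions(sites, list(list(chrom = "chr6", start = 25000000,
                                          end = 35000000)))
  expect_equal(out, sites[c(1, 4)])
})
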