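# Pre-exclusion, true/other classification, filter evaluation and cascade.

test_that("prefilter applies the three exclusion rules and the autosome set", {
  # direct rule checks
  on_x <- make_rec(chrom = "chrX")
  no_qd <- make_rec(metrics = c(MQ = 60, DP = 30))
  dp0 <- make_rec(dps = list(0))
  ad0 <- make_rec(ads = list(c(10L, 0L)))
  ok <- make_rec(ads = list(c(10L, 5L)))
  kept <- prefilter_sites(list(on_x, no_qd, dp0, ad0, ok))
  expect_length(kept, 1)
  expect_identical(kept[[1]], ok)

  # 200 randomized records versus a naive triple-condition scan
  set.seed(52)
  recs <- lapply(1:200, function(i) {
    mets <- c(QD = 10, MQ = 60, DP = 30)
    if (runif(1) < 0.3) mets <- mets[-1]
    make_rec(chrom = sample(c("chr1", "chrX"), 1, prob = c(0.8, 0.2)),
             pos = i * 5L, metrics = mets,
             dps = list(sample(c(0, 30), 1, prob = c(0.2, 0.8))),
             ads = list(c(10L, sample(c(0L, 8L), 1))))
  })
  naive <- vapply(recs, function(r) {
    r$chrom %in% paste0("chr", 1:22) && "QD" %in% names(r$metrics) &&
      any(vapply(r$samples, function(s) isTRUE(s$dp > 0), TRUE)) &&
      any(vapply(r$samples, function(s) any(s$ad[-1] > 0), TRUE))
  }, TRUE)
  expect_identical(prefilter_sites(recs), recs[naive])
})

test_that("classification is the any-allele union over truth panels", {
  p1 <- truth_panel(data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "C"),
                    name = "p1")
  p2 <- truth_panel(data.frame(chrom = "chr1", pos = 20L, ref = "G", alt = "T"),
                    name = "p2")
  r_only_p2 <- make_rec(pos = 20L, ref = "G", alts = "T")
  r_multi <- make_rec(pos = 10L, ref = "A", alts = c("G", "C"),
                      gts = list(c(1L, 2L)), ads = list(c(1L, 5L, 5L)))
  r_miss <- make_rec(pos = 30L, ref = "A", alts = "C")
  expect_equal(classify_sites(list(r_only_p2, r_multi, r_miss), list(p1, p2)),
               c("true", "true", "other"))
})

test_that("classification recovers generator labels exactly", {
  cfg <- simulation_config(seed = 77L, n_sites = 800L, qd_absent_fraction = 0,
                           dp_zero_fraction = 0, ad_zero_fraction = 0,
                           true_fraction = 0.6)
  sim <- simulate_cohort_vcf(cfg)
  panels <- simulate_panels(cfg, sim$truth, withr::local_tempdir())
  tps <- lapply(c(panels$truth_hapmap, panels$truth_omni), function(p)
    truth_panel(normalize_records(read_vcf(p))))
  split_recs <- unlist(lapply(sim$records, split_multiallelic),
                       recursive = FALSE)
  labels <- classify_sites(split_recs, tps)
  # expected: the site-level class of each split allele's parent site
  keys <- vapply(split_recs, function(r)
    allele_key(r$chrom, r$pos, r$ref, r$alts[1]), "")
  truth_snv <- sim$truth[sim$truth$is_snv, ]
  site_true <- tapply(truth_snv$site_class == "true", truth_snv$site, any)
  exp_lab <- ifelse(!is.na(site_true[vapply(split_recs, function(r)
    site_key(r$chrom, r$pos), "")]) &
      site_true[vapply(split_recs, function(r) site_key(r$chrom, r$pos), "")],
    "true", "other")
  expect_equal(unname(labels), as.character(exp_lab))
})

test_that("filter evaluation: no-op, boundary and counting behaviour", {
  co <- rand_cohort(400, seed = 61)
  noop <- filter_rule("DP >= 0")
  ev <- evaluate_filter(co$records, co$labels, noop)
  expect_equal(ev$true_retention, 1)
  expect_equal(ev$other_retention, 1)
  expect_equal(ev$discrimination_factor, 1)

  # a rule keeping no other-labelled sites yields the +Inf sentinel
  recs <- c(lapply(1:5, function(i) make_rec(pos = i, metrics = c(QD = 30))),
            lapply(6:10, function(i) make_rec(pos = i, metrics = c(QD = 1))))
  labs <- rep(c("true", "other"), each = 5)
  ev2 <- evaluate_filter(recs, labs, filter_rule("QD > 20"))
  expect_equal(ev2$other_retention, 0)
  expect_identical(ev2$discrimination_factor, Inf)

  # retention at a stated quantile threshold matches direct counting
  thr <- round(stats::quantile(metric_matrix(co$records)[, "QD"], 0.3), 3)
  ev3 <- evaluate_filter(co$records, co$labels,
                         filter_rule(paste0("QD > ", thr)))
  mm <- metric_matrix(co$records)
  expect_equal(ev3$n_true_kept,
               sum(mm[, "QD"] > thr & co$labels == "true"))
  expect_equal(ev3$n_other_kept,
               sum(mm[, "QD"] > thr & co$labels == "other"))

  expect_error(evaluate_filter(recs, rep("true", 10), noop), "at least one")
})

test_that("rule parsing restricts metrics/operators and handles missingness", {
  expect_error(filter_rule("QD > 1 & BAD < 2"), "unknown metric")
  expect_error(filter_rule("system('ls')"), "not allowed")
  rules <- default_qc_rules()
  expect_length(rules, 2)
  # records missing a referenced metric fail that rule
  r_missing <- make_rec(metrics = c(QD = 30, MQ = 60))
  expect_false(rule_keeps(rules$mqranksum_qd, list(r_missing)))
  # absent FS is read as zero for the FS rule by default, not as a failure
  r_fs <- make_rec(metrics = c(QD = 10, MQ = 45, MQRankSum = 0))
  expect_true(rule_keeps(rules$mq_fs, list(r_fs)))
  expect_false(rule_keeps(rules$mq_fs, list(r_fs), missing_fs_zero = FALSE))
})

test_that("nested rules: a stricter rule never keeps more true sites", {
  co <- rand_cohort(500, seed = 62)
  loose <- filter_rule("QD > 5")
  strict <- filter_rule("QD > 5 & MQ > 50")
  ev_l <- evaluate_filter(co$records, co$labels, loose)
  ev_s <- evaluate_filter(co$records, co$labels, strict)
  expect_lte(ev_s$true_retention, ev_l$true_retention)
})

test_that("discrimination factor is invariant to duplicating every record", {
  co <- rand_cohort(300, seed = 63)
  rule <- filter_rule("QD > 8")
  ev1 <- evaluate_filter(co$records, co$labels, rule)
  ev2 <- evaluate_filter(c(co$records, co$records), rep(co$labels, 2), rule)
  expect_equal(ev2$discrimination_factor, ev1$discrimination_factor)
})

test_that("EM recovers a single Gaussian and keeps the likelihood monotone", {
  set.seed(71)
  n <- 5000
  mu <- c(DP = 50, SOR = 2, ReadPosRankSum = 0.5, FS = 4)
  X <- sapply(mu, function(m) rnorm(n, m, 2))
  recs <- records_from_metrics(X)
  fit <- fit_mixture_model(recs, k = 1, seed = 5)
  # recovered mean on the standardized scale, back-transformed
  est <- fit$pos$means[[1]] * fit$scale + fit$center
  se <- 2 / sqrt(n)  # sd of the simulated metrics / sqrt(n)
  expect_true(all(abs(est - mu) < 3 * se))
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("EM separates two planted clusters with the right weights", {
  set.seed(72)
  n1 <- 1400; n2 <- 600
  X <- rbind(
    sapply(1:4, function(j) rnorm(n1, 0, 1)),
    sapply(1:4, function(j) rnorm(n2, 8, 1)))
  colnames(X) <- c("DP", "SOR", "ReadPosRankSum", "FS")
  fit <- fit_mixture_model(records_from_metrics(X), k = 2, seed = 6)
  w <- sort(fit$pos$weights)
  expect_lt(abs(w[1] - 0.3), 0.05)
  expect_lt(abs(w[2] - 0.7), 0.05)
})

test_that("EM fit agrees with an independent mixture implementation", {
  set.seed(74)
  X <- rbind(sapply(1:4, function(j) rnorm(900, 0, 1)),
             sapply(1:4, function(j) rnorm(600, 6, 1.2)))
  colnames(X) <- c("DP", "SOR", "ReadPosRankSum", "FS")
  fit <- fit_mixture_model(records_from_metrics(X), k = 2, seed = 8)
  ours <- utils::tail(fit$loglik_trace, 1) * nrow(X)
  Xs <- scale(X)
  mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the calling frame
  ref <- mclust::Mclust(Xs, G = 2, modelNames = "VVV", verbose = FALSE)
  # same data, same model class: log-likelihoods agree to within 0.5%
  expect_lt(abs(ours - ref$loglik) / abs(ref$loglik), 0.005)
  # and the recovered mixing weights match
  expect_equal(sort(fit$pos$weights), sort(ref$parameters$pro),
               tolerance = 0.02)
})

test_that("mixture scores order true above error and are antisymmetric", {
  set.seed(73)
  mk <- function(n, m) {
    X <- sapply(1:4, function(j) rnorm(n, m, 1.5))
    colnames(X) <- c("DP", "SOR", "ReadPosRankSum", "FS")
    X
  }
  Xt <- mk(1500, 5); Xe <- mk(1500, 0)
  recs_all <- records_from_metrics(rbind(Xt, Xe))
  fit <- fit_mixture_model(records_from_metrics(Xt), k = 1, seed = 7,
                           records_all = recs_all, neg_fraction = 0.3)
  held_true <- records_from_metrics(mk(300, 5))
  held_err <- records_from_metrics(mk(300, 0))
  expect_gt(mean(score_sites(fit, held_true)), mean(score_sites(fit, held_err)))

  # swapping positive and negative mixtures negates the score
  swapped <- fit
  swapped$pos <- fit$neg; swapped$neg <- fit$pos
  s1 <- score_sites(fit, held_true)
  s2 <- score_sites(swapped, held_true)
  expect_equal(s2, -s1)

  # a record missing a model metric fails (or drops) per configuration
  r_na <- make_rec(metrics = c(QD = 10, MQ = 60))
  expect_identical(score_sites(fit, list(r_na)), -Inf)
  expect_true(is.na(score_sites(fit, list(r_na), missing = "drop")))
})

test_that("cascade: no-op stage, DF product identity and SNV-only scope", {
  co <- rand_cohort(400, seed = 64)
  res <- apply_qc_cascade(co$records, co$labels,
                          list(noop = filter_rule("DP >= 0")))
  expect_equal(res$overall$fraction_removed, 0)
  expect_equal(res$overall$ratio_increase, 1)

  # overall ratio increase equals the product of stage DFs, exactly
  stages <- list(a = filter_rule("QD > 4"), b = filter_rule("MQ > 48"),
                 c = filter_rule("FS < 15"))
  res2 <- apply_qc_cascade(co$records, co$labels, stages)
  expect_equal(res2$overall$ratio_increase,
               prod(res2$report$discrimination_factor), tolerance = 1e-12)

  # indel records are excluded before stage 1
  indel <- make_rec(ref = "AT", alts = "A")
  res3 <- apply_qc_cascade(c(co$records, list(indel)), c(co$labels, "other"),
                           list(noop = filter_rule("DP >= 0")))
  expect_equal(res3$overall$n_before, 400)
})

test_that("report arithmetic composes stage factors and implied removal", {
  expect_equal(compose_discrimination_factors(c(2, 1.5)), 3)
  imp <- implied_site_removal(start_ratio = 1, true_retention = 1,
                              ratio_increase = 2)
  # all true kept, ratio doubled => half the other sites kept
  expect_equal(imp$other_retention, 0.5)
  expect_equal(imp$fraction_removed, 0.25)
})
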