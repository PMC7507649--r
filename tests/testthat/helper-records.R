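# Small in-code fixture builders.

make_rec <- function(chrom = "chr1", pos = 100L, ref = "A", alts = "C",
                     metrics = c(QD = 15, MQ = 60, MQRankSum = 0,
                                 ReadPosRankSum = 0, FS = 1, SOR = 1, DP = 50),
                     gts = list(c(0L, 1L)), dps = NULL, ads = NULL,
                     gqs = NULL, rgqs = NULL, qual = 100) {
  samples <- lapply(seq_along(gts), function(i) {
    sample_call(gt = gts[[i]],
                ad = if (is.null(ads)) NULL else ads[[i]],
                dp = if (is.null(dps)) 30 else dps[[i]],
                gq = if (is.null(gqs)) 60 else gqs[[i]],
                rgq = if (is.null(rgqs)) NULL else rgqs[[i]])
  })
  site_record(chrom = chrom, pos = pos, ref = ref, alts = alts, qual = qual,
              metrics = metrics, samples = samples)
}

# Records with given metric rows only (no samples), for mixture/score tests.
records_from_metrics <- function(mm) {
  lapply(seq_len(nrow(mm)), function(i) {
    m <- mm[i, ]
    site_record(chrom = "chr1", pos = i, ref = "A", alts = "C",
                metrics = m[!is.na(m)])
  })
}

# A labelled random cohort with class-separated metrics, for QC property
# tests (truth-metric sites labelled "true").
rand_cohort <- function(n, seed, true_frac = 0.5) {
  set.seed(seed)
  labels <- ifelse(runif(n) < true_frac, "true", "other")
  recs <- lapply(seq_len(n), function(i) {
    tr <- labels[i] == "true"
    metrics <- c(QD = max(0, rnorm(1, if (tr) 18 else 5, 4)),
                 MQ = max(0, rnorm(1, if (tr) 60 else 45, 4)),
                 MQRankSum = rnorm(1, if (tr) 0 else -2, 1),
                 ReadPosRankSum = rnorm(1, if (tr) 0 else -1.5, 1),
                 FS = max(0, rnorm(1, if (tr) 2 else 12, 4)),
                 SOR = max(0, rnorm(1, if (tr) 1 else 2.5, 0.8)),
                 DP = max(0, rnorm(1, if (tr) 60 else 35, 12)))
    site_record(chrom = "chr1", pos = i * 10L, ref = "A", alts = "C",
                metrics = metrics,
                samples = list(sample_call(gt = c(0L, 1L), ad = c(10L, 10L),
                                           dp = 20, gq = 60)))
  })
  list(records = recs, labels = labels)
}
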