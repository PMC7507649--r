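# Gaussian-mixture recalibration score (a VQSLOD-style statistic).
#
# A positive multivariate Gaussian mixture is fitted by EM to the
# standardized site metrics of truth-matching sites; a negative mixture is
# fitted to the worst-scoring fraction of all sites under the positive model.
# The recalibration score of a site is the log density ratio
# log f_pos(x) - log f_neg(x).

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Multivariate normal log-density via Cholesky; S must be positive-definite.
logdens_mvn <- function(X, mu, S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop_popnovel("fit_mixture_model: singular component covariance; ",
                  "increase the covariance regularization (reg)")
  Y <- sweep(X, 2L, mu)
  W <- backsolve(ch, t(Y), transpose = TRUE)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(W^2))
}

# Per-observation log density of a K-component mixture (list with weights,
# means, covs) evaluated on standardized data.
logdens_mixture <- function(mix, X) {
  comp <- sapply(seq_along(mix$weights), function(j)
    log(mix$weights[j]) + logdens_mvn(X, mix$means[[j]], mix$covs[[j]]))
  comp <- matrix(comp, nrow = nrow(X))
  logsumexp_rows(comp)
}

fit_gmm_em <- function(X, k, max_iterations, tol, reg) {
  n <- nrow(X); d <- ncol(X)
  if (n < 10L * k)
    stop_popnovel("fit_mixture_model: need at least 10*k training sites with ",
                  "all metrics present (have ", n, ", k = ", k, ")")
  # k-means initialisation; covariances start from within-cluster scatter
  km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = 5L,
                                       iter.max = 50L))
  mix <- list(
    weights = as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n,
    means = lapply(seq_len(k), function(j) km$centers[j, ]),
    covs = lapply(seq_len(k), function(j) {
      sub <- X[km$cluster == j, , drop = FALSE]
      S <- if (nrow(sub) > d) stats::cov(sub) else stats::cov(X)
      S + diag(reg, d)
    }))
  mix$weights[mix$weights == 0] <- 1e-12
  mix$weights <- mix$weights / sum(mix$weights)
  trace <- numeric()
  for (it in seq_len(max_iterations)) {
    comp <- sapply(seq_len(k), function(j)
      log(mix$weights[j]) + logdens_mvn(X, mix$means[[j]], mix$covs[[j]]))
    comp <- matrix(comp, nrow = n)
    lse <- logsumexp_rows(comp)
    ll <- mean(lse)
    trace <- c(trace, ll)
    resp <- exp(comp - lse)
    nk <- colSums(resp)
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * X) / nk[j]
      Y <- sweep(X, 2L, mu)
      S <- crossprod(Y * sqrt(resp[, j])) / nk[j] + diag(reg, d)
      mix$means[[j]] <- mu
      mix$covs[[j]] <- S
    }
    mix$weights <- nk / n
    if (it > 1L && trace[it] - trace[it - 1L] < tol) break
  }
  list(mix = mix, loglik_trace = trace, iterations = length(trace))
}

#' Fit the Gaussian-mixture recalibration model
#'
#' Fits the positive mixture by EM on the standardized metrics of the given
#' truth-matching records, then fits the negative mixture on the
#' `neg_fraction` of `records_all` scoring lowest under the positive model.
#' Records lacking any of the requested metrics are excluded from training.
#' The per-iteration mean log-likelihood is non-decreasing up to `tol`.
#'
#' @param records_true_subset Training records (truth-matching sites).
#' @param metrics Metric names used as model dimensions (default the
#'   recalibration set `DP, SOR, ReadPosRankSum, FS`).
#' @param k Number of mixture components (default 2).
#' @param max_iterations EM iteration cap (default 500).
#' @param tol Convergence tolerance on the mean log-likelihood (default 1e-6).
#' @param seed Integer seed for the k-means initialisation (required).
#' @param records_all Records from which the negative-model training subset is
#'   drawn; defaults to `records_true_subset`.
#' @param neg_fraction Fraction of `records_all` (lowest positive-model
#'   density) used to train the negative model (default 0.05).
#' @param reg Diagonal covariance regularization (default 1e-6).
#' @return A `mixture_score_model`: metric names, per-metric standardization,
#'   positive and negative mixtures, and fit diagnostics.
#' @export
fit_mixture_model <- function(records_true_subset,
                              metrics = c("DP", "SOR", "ReadPosRankSum", "FS"),
                              k = 2L, max_iterations = 500L, tol = 1e-6,
                              seed, records_all = records_true_subset,
                              neg_fraction = 0.05, reg = 1e-6) {
  if (missing(seed) || is.null(seed))
    stop_popnovel("fit_mixture_model: a seed is required")
  mm <- metric_matrix(records_true_subset)[, metrics, drop = FALSE]
  complete <- stats::complete.cases(mm)
  X <- mm[complete, , drop = FALSE]
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  if (any(scale == 0))
    stop_popnovel("fit_mixture_model: zero-variance metric in training data")
  Xs <- scale(X, center = center, scale = scale)
  set.seed(seed)
  pos_fit <- fit_gmm_em(Xs, k = k, max_iterations = max_iterations,
                        tol = tol, reg = reg)
  mm_all <- metric_matrix(records_all)[, metrics, drop = FALSE]
  ok_all <- stats::complete.cases(mm_all)
  Xa <- scale(mm_all[ok_all, , drop = FALSE], center = center, scale = scale)
  pos_ll <- logdens_mixture(pos_fit$mix, Xa)
  n_neg <- max(10L, ceiling(neg_fraction * nrow(Xa)))
  worst <- order(pos_ll)[seq_len(min(n_neg, nrow(Xa)))]
  k_neg <- max(1L, min(k, floor(length(worst) / 10L)))
  neg_fit <- fit_gmm_em(Xa[worst, , drop = FALSE], k = k_neg,
                        max_iterations = max_iterations, tol = tol, reg = reg)
  structure(list(metrics = metrics, center = center, scale = scale,
                 pos = pos_fit$mix, neg = neg_fit$mix,
                 loglik_trace = pos_fit$loglik_trace,
                 iterations = pos_fit$iterations,
                 neg_loglik_trace = neg_fit$loglik_trace),
            class = "mixture_score_model")
}

#' Score sites under a fitted mixture model
#'
#' The score of a record is `log f_pos(x) - log f_neg(x)` on its standardized
#' metrics: positive at sites resembling truth-matching sites, negative at
#' sites resembling the error stratum.
#'
#' @param model A [fit_mixture_model()] result.
#' @param records List of [site_record()]s.
#' @param missing How to score records lacking a model metric:
#'   `"fail"` assigns `-Inf` (they fail any threshold), `"drop"` assigns
#'   `NA`.
#' @return Numeric score vector aligned with `records`.
#' @export
score_sites <- function(model, records, missing = c("fail", "drop")) {
  missing <- match.arg(missing)
  stopifnot(inherits(model, "mixture_score_model"))
  mm <- metric_matrix(records)[, model$metrics, drop = FALSE]
  ok <- stats::complete.cases(mm)
  out <- rep(if (missing == "fail") -Inf else NA_real_, length(records))
  if (any(ok)) {
    Xs <- scale(mm[ok, , drop = FALSE], center = model$center,
                scale = model$scale)
    out[ok] <- logdens_mixture(model$pos, Xs) - logdens_mixture(model$neg, Xs)
  }
  out
}
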