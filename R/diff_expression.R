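#' Size factors from total linear mapped reads
#'
#' Library-size normalization for circRNA and lncRNA matrices is anchored to
#' each sample's total *linear* mapped read count rather than to the matrix
#' itself (BSJ matrices are too sparse to self-normalize). Factors are
#' proportional to the totals and rescaled so their geometric mean is 1,
#' which makes them invariant to a global rescaling of the totals.
#'
#' @param totals positive numeric vector of total linear mapped reads,
#'   named by sample id.
#' @return positive numeric vector of size factors, geometric mean 1.
#' @export
estimate_size_factors <- function(totals) {
  bad <- which(!is.finite(totals) | totals <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-positive total linear mapped reads for sample '%s'",
                 if (!is.null(names(totals))) names(totals)[bad[1L]]
                 else as.character(bad[1L])))
  totals / exp(mean(log(totals)))
}

# Profile NB log-likelihood machinery ----------------------------------------
# Model per feature: y_j ~ NB(mu_j, alpha), log mu_j = log sf_j + theta_g(j),
# one free log-mean theta per group. Group parameters are orthogonal, so the
# group effect beta = theta_1 - theta_0 has Var = 1/I_0 + 1/I_1 with expected
# information I_g = sum_j mu_j / (1 + alpha * mu_j).

nb_theta_mle <- function(y, sf, alpha, tol = 1e-10, max_iter = 25L) {
  s <- sum(y)
  if (s == 0) return(-Inf)
  theta <- log(s / sum(sf))
  for (i in seq_len(max_iter)) {
    mu <- sf * exp(theta)
    r <- alpha * mu / (1 + alpha * mu)
    score <- sum(y) - sum((y + 1 / alpha) * r)
    hess <- -sum((y + 1 / alpha) * r / (1 + alpha * mu))
    step <- score / hess
    theta <- theta - step
    if (abs(step) < tol) break
  }
  theta
}

nb_loglik <- function(y, mu, alpha) {
  ok <- mu > 0
  sum(lgamma(y[ok] + 1 / alpha) - lgamma(1 / alpha) - lgamma(y[ok] + 1) +
        y[ok] * log(alpha * mu[ok]) -
        (y[ok] + 1 / alpha) * log(1 + alpha * mu[ok]))
}

# Cox-Reid adjusted profile log-likelihood in alpha: maximize over the
# per-group thetas, then subtract half the log-determinant of the observed
# information (here block-diagonal across groups). The adjustment corrects
# the downward bias of the plain ML dispersion when the group means are
# estimated from few samples; without it the Wald test is anti-conservative.
nb_profile <- function(log_alpha, y, sf, grp_idx) {
  alpha <- exp(log_alpha)
  ll <- 0
  for (g in grp_idx) {
    theta <- nb_theta_mle(y[g], sf[g], alpha)
    if (is.finite(theta)) {
      mu <- sf[g] * exp(theta)
      ll <- ll + nb_loglik(y[g], mu, alpha) -
        0.5 * log(sum(mu / (1 + alpha * mu)))
    }
    # an all-zero group contributes 0 at its boundary MLE
  }
  ll
}

# Fit one feature: gene-wise ML dispersion (method-of-moments bracket,
# floored at 1e-8), per-group log means, Wald statistic for the group effect.
fit_nb_feature <- function(y, sf, grp_idx, beta_cap = 10) {
  q <- y / sf
  mom <- 0
  for (g in grp_idx) {
    m <- mean(q[g])
    if (m > 0 && length(g) > 1L)
      mom <- max(mom, (stats::var(q[g]) - m) / m^2)
  }
  lo <- log(1e-8)
  hi <- log(max(100, mom * 100))
  opt <- stats::optimize(nb_profile, interval = c(lo, hi), maximum = TRUE,
                         y = y, sf = sf, grp_idx = grp_idx, tol = 1e-4)
  alpha <- max(exp(opt$maximum), 1e-8)
  theta <- vapply(grp_idx, function(g) nb_theta_mle(y[g], sf[g], alpha),
                  numeric(1))
  separation <- any(!is.finite(theta))
  if (separation) {
    fin <- theta[is.finite(theta)]
    anchor <- if (length(fin) > 0) max(fin) else 0
    theta[!is.finite(theta)] <- anchor - beta_cap
  }
  beta <- theta[2L] - theta[1L]
  capped <- abs(beta) > beta_cap
  if (capped) beta <- sign(beta) * beta_cap
  info <- vapply(seq_along(grp_idx), function(k) {
    mu <- sf[grp_idx[[k]]] * exp(theta[k])
    sum(mu / (1 + alpha * mu))
  }, numeric(1))
  se <- sqrt(sum(1 / pmax(info, 1e-12)))
  list(beta = beta, se = se, alpha = alpha,
       separation = separation || capped)
}

#' Two-group negative-binomial Wald test
#'
#' Per-feature NB generalized linear model with log link, offset
#' `log(size factor)` and a two-level group covariate. The gene-wise
#' dispersion (variance `mu + alpha * mu^2`) is estimated by maximizing the
#' Cox-Reid adjusted profile likelihood (a method-of-moments value brackets
#' the search; the estimate is floored at 1e-8). The Wald statistic is the group coefficient over its standard
#' error from the expected Fisher information, with a two-sided p-value from
#' the standard normal reference.
#'
#' Features with all-zero counts get `status = "zero"` and no test; features
#' below `min_total` summed counts get `status = "low_count"`. A group with
#' all-zero counts is perfect separation: the coefficient is capped at
#' (natural-log) 10 and flagged in the `separation` column, but the feature
#' is still tested.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param group character/factor of length `ncol(counts)` with exactly two
#'   levels.
#' @param size_factors positive vector per sample (see
#'   [estimate_size_factors()]).
#' @param reference group level used as denominator of the fold change
#'   (default: `"non_responder"` when present, else the first level).
#' @param min_total pre-filter: features whose counts sum below this are not
#'   tested (default 0, i.e. only all-zero features are excluded).
#' @return data.frame with one row per feature: `feature_id, baseMean,
#'   log2FoldChange, lfcSE, stat, pvalue, dispersion, separation, status`.
#'   `log2FoldChange > 0` means higher in the non-reference group.
#' @export
nb_wald_test <- function(counts, group, size_factors, reference = NULL,
                         min_total = 0) {
  counts <- as.matrix(counts)
  if (length(group) != ncol(counts))
    stop("group must have one label per sample column")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  group <- as.character(group)
  levs <- unique(group)
  if (length(levs) != 2L) stop("exactly two groups are required")
  if (is.null(reference))
    reference <- if ("non_responder" %in% levs) "non_responder" else levs[1L]
  if (!reference %in% levs) stop("reference level not present in group")
  other <- setdiff(levs, reference)
  if (min(table(group)) < 2L) stop("each group needs >= 2 samples")
  if (length(size_factors) != ncol(counts) || any(size_factors <= 0))
    stop("size_factors must be positive, one per sample")

  grp_idx <- list(which(group == reference), which(group == other))
  n_feat <- nrow(counts)
  out <- data.frame(
    feature_id = rownames(counts) %||% as.character(seq_len(n_feat)),
    baseMean = rowMeans(sweep(counts, 2L, size_factors, "/")),
    log2FoldChange = NA_real_, lfcSE = NA_real_, stat = NA_real_,
    pvalue = NA_real_, dispersion = NA_real_, separation = FALSE,
    status = "tested", stringsAsFactors = FALSE)
  totals <- rowSums(counts)
  out$status[totals <= min_total & totals > 0] <- "low_count"
  out$status[totals == 0] <- "zero"
  sf <- as.numeric(size_factors)
  for (i in which(out$status == "tested")) {
    fit <- fit_nb_feature(counts[i, ], sf, grp_idx)
    out$log2FoldChange[i] <- fit$beta / log(2)
    out$lfcSE[i] <- fit$se / log(2)
    out$stat[i] <- fit$beta / fit$se
    out$pvalue[i] <- 2 * stats::pnorm(-abs(fit$beta / fit$se))
    out$dispersion[i] <- fit$alpha
    out$separation[i] <- fit$separation
  }
  attr(out, "contrast") <- c(numerator = other, denominator = reference)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment and significance thresholds
#'
#' Adjusts p-values over tested features only (BH step-up), then splits
#' significant features into up- and down-regulated sets at
#' `padj < alpha` and `|log2FoldChange| > lfc`. With
#' `lfc_scale = "linear"` the fold-change threshold is interpreted on the
#' linear scale, i.e. `|log2FoldChange| > log2(lfc)`.
#'
#' @param results output of [nb_wald_test()].
#' @param alpha adjusted-p threshold in (0, 1); default 0.1.
#' @param lfc fold-change threshold; default 1.5 (on the log2 scale).
#' @param lfc_scale `"log2"` (default) or `"linear"`.
#' @return list with `results` (input plus a `padj` column), `up` and `down`
#'   (disjoint character vectors of feature ids).
#' @export
adjust_and_threshold <- function(results, alpha = 0.1, lfc = 1.5,
                                 lfc_scale = c("log2", "linear")) {
  lfc_scale <- match.arg(lfc_scale)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  thr <- if (lfc_scale == "log2") lfc else log2(lfc)
  results$padj <- rep(NA_real_, nrow(results))
  tested <- results$status == "tested"
  results$padj[tested] <- stats::p.adjust(results$pvalue[tested],
                                          method = "BH")
  sig <- tested & !is.na(results$padj) & results$padj < alpha
  up <- results$feature_id[sig & results$log2FoldChange > thr]
  down <- results$feature_id[sig & results$log2FoldChange < -thr]
  list(results = results, up = up, down = down)
}

#' One-call differential expression
#'
#' Convenience wrapper: [nb_wald_test()] followed by
#' [adjust_and_threshold()].
#'
#' @inheritParams nb_wald_test
#' @inheritParams adjust_and_threshold
#' @return as [adjust_and_threshold()], with the full result table in
#'   `$results` and DE ids in `$up` / `$down`.
#' @export
de_analysis <- function(counts, group, size_factors, reference = NULL,
                        alpha = 0.1, lfc = 1.5,
                        lfc_scale = c("log2", "linear"), min_total = 0) {
  res <- nb_wald_test(counts, group, size_factors, reference = reference,
                      min_total = min_total)
  adjust_and_threshold(res, alpha = alpha, lfc = lfc,
                       lfc_scale = match.arg(lfc_scale))
}
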