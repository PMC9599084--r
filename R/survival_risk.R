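#' Univariate Cox proportional-hazards fit for one feature
#'
#' Fits `Surv(time, event) ~ x` by maximizing the Cox partial likelihood
#' (Efron tie handling, Newton-Raphson to tolerance 1e-9, at most 50
#' iterations, via [survival::coxph()]). Monotone likelihood (perfect
#' separation of events by the covariate) inflates the estimate without
#' bound; coefficients beyond (natural-log) 10 are capped at +/-10 and
#' flagged. Zero-variance covariates cannot be fitted and return a zero
#' coefficient with the `untestable` flag.
#'
#' @param x numeric covariate per patient (normalized expression:
#'   `log2(size-factor-scaled count + 1)`, z-scored across patients).
#' @param time,event survival time (> 0) and 0/1 event indicator.
#' @param cap absolute coefficient bound for separation handling.
#' @return list: `coef`, `se`, `converged`, `separation`, `untestable`.
#' @export
fit_univariate_cox <- function(x, time, event, cap = 10) {
  if (sum(event) < 2L) stop("need >= 2 events for a Cox fit")
  if (length(unique(x)) < 2L || stats::sd(x) == 0)
    return(list(coef = 0, se = NA_real_, converged = TRUE,
                separation = FALSE, untestable = TRUE))
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(time, event) ~ x, ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 50L)))
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(fit$var)))[1L]
  separation <- !is.finite(beta) || abs(beta) > cap
  if (separation) beta <- sign(beta) * cap
  list(coef = beta, se = se,
       converged = fit$info["iter"] <= 50 || is.null(fit$info),
       separation = separation, untestable = FALSE)
}

#' Fit univariate Cox coefficients for a feature panel
#'
#' Runs [fit_univariate_cox()] for every row of a normalized expression
#' matrix. Warns when the panel has more features than patients (per-feature
#' fits on a pilot-sized cohort are unstable and the resulting coefficients
#' should be read as descriptive weights).
#'
#' @param expr normalized expression matrix, features x patients.
#' @param time,event survival endpoint per patient (column order).
#' @return data.frame `feature_id, coef, se, separation, untestable`.
#' @export
fit_signature_cox <- function(expr, time, event) {
  expr <- as.matrix(expr)
  if (nrow(expr) > ncol(expr))
    warning(sprintf(paste0("fitting %d features on %d patients: univariate ",
                           "Cox coefficients will be unstable"),
                    nrow(expr), ncol(expr)))
  fits <- lapply(seq_len(nrow(expr)), function(i)
    fit_univariate_cox(expr[i, ], time, event))
  data.frame(feature_id = rownames(expr),
             coef = vapply(fits, `[[`, numeric(1), "coef"),
             se = vapply(fits, `[[`, numeric(1), "se"),
             separation = vapply(fits, `[[`, logical(1), "separation"),
             untestable = vapply(fits, `[[`, logical(1), "untestable"),
             stringsAsFactors = FALSE)
}

#' ceRNA-signature risk score
#'
#' The per-patient risk score is the coefficient-weighted sum of the
#' signature's normalized expression values:
#' `RS(patient) = sum_i expression_i * coefficient_i` over the N signature
#' features.
#'
#' @param expr normalized expression matrix, signature features x patients.
#' @param coefficients named numeric vector of per-feature Cox coefficients
#'   (names must match `rownames(expr)`).
#' @return numeric vector of risk scores named by patient.
#' @export
compute_risk_score <- function(expr, coefficients) {
  expr <- as.matrix(expr)
  missing <- setdiff(names(coefficients), rownames(expr))
  if (length(missing) > 0)
    stop("expression missing for signature feature(s): ",
         paste(missing, collapse = ", "))
  ord <- rownames(expr)[rownames(expr) %in% names(coefficients)]
  drop(crossprod(expr[ord, , drop = FALSE], coefficients[ord]))
}

#' Stratify patients into high- and low-risk groups
#'
#' Scores strictly above the cutoff (default: the median score) are `high`;
#' scores at or below it are `low`, so with an odd patient count the median
#' patient falls in the low-risk group.
#'
#' @param scores numeric risk scores named by patient.
#' @param cutoff numeric cutoff, or `"median"` (default).
#' @return list: `group` (named character vector `"high"`/`"low"`) and
#'   `cutoff` (the numeric value used).
#' @export
stratify <- function(scores, cutoff = "median") {
  if (length(scores) < 2L) stop("need >= 2 patients to stratify")
  if (length(unique(scores)) == 1L)
    stop("all risk scores identical: no stratification possible")
  cut_val <- if (identical(cutoff, "median")) stats::median(scores)
  else as.numeric(cutoff)
  grp <- ifelse(scores > cut_val, "high", "low")
  names(grp) <- names(scores)
  list(group = grp, cutoff = cut_val)
}

#' Kaplan-Meier curves per risk group
#'
#' Product-limit survival estimate per group with Greenwood variance on the
#' log(-log S) scale (`conf.type = "log-log"`), median survival as the
#' earliest time with `S <= 0.5`, and its 95% confidence interval by
#' inversion; unreached bounds are `NA` (reported as "NR").
#'
#' @param time,event survival data per patient.
#' @param group group label per patient (e.g. from [stratify()]).
#' @return list: `fit` (the [survival::survfit()] object), `curves`
#'   (data.frame `group, time, n_risk, n_event, surv, lower, upper`) and
#'   `medians` (data.frame `group, n, events, median, lcl, ucl`).
#' @export
km_curve <- function(time, event, group) {
  group <- as.character(group)
  if (any(table(group) == 0L)) stop("groups must be nonempty")
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                           conf.type = "log-log")
  smry <- summary(fit)
  grp_lab <- if (is.null(smry$strata)) rep(unique(group), length(smry$time))
  else sub("^group=", "", as.character(smry$strata))
  curves <- data.frame(group = grp_lab, time = smry$time,
                       n_risk = smry$n.risk, n_event = smry$n.event,
                       surv = smry$surv, lower = smry$lower,
                       upper = smry$upper, stringsAsFactors = FALSE)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list(unique(group),
                                                       names(tab)))
  medians <- data.frame(group = sub("^group=", "", rownames(tab)),
                        n = tab[, "records"], events = tab[, "events"],
                        median = tab[, "median"], lcl = tab[, "0.95LCL"],
                        ucl = tab[, "0.95UCL"], stringsAsFactors = FALSE)
  rownames(medians) <- NULL
  list(fit = fit, curves = curves, medians = medians)
}

#' Two-group log-rank test
#'
#' Standard log-rank test: at each distinct event time, observed minus
#' expected events in one group with the hypergeometric variance; the
#' statistic is referred to chi-square with 1 degree of freedom.
#'
#' @param time,event survival data per patient.
#' @param group exactly two group labels per patient.
#' @return list: `statistic` (chi-square), `p`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  if (length(unique(group)) != 2L)
    stop("log-rank test requires exactly two nonempty groups")
  if (sum(event) < 1L) stop("need >= 1 event")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Build a ceRNA-signature risk model and evaluate survival separation
#'
#' End-to-end risk modelling: z-scored log2-normalized expression of the
#' signature features, per-feature univariate Cox coefficients on the
#' training endpoint, coefficient-weighted risk scores, a median (or custom)
#' cutoff split into high/low risk, and KM + log-rank evaluation of both
#' endpoints.
#'
#' @param counts raw count matrix (signature features x patients).
#' @param size_factors per-patient size factors.
#' @param meta data.frame with `sample_id, os_time, os_event, pfs_time,
#'   pfs_event` (patients matching `colnames(counts)`).
#' @param endpoint endpoint used to train the coefficients: `"os"`
#'   (default) or `"pfs"`.
#' @param cutoff passed to [stratify()].
#' @return object of class `risk_model`: list with `coefficients`, `scores`,
#'   `group`, `cutoff`, `normalized` (the z-scored matrix), and per-endpoint
#'   `km` / `logrank` results (`os`, `pfs`).
#' @export
build_risk_model <- function(counts, size_factors, meta, endpoint = c("os", "pfs"),
                             cutoff = "median") {
  endpoint <- match.arg(endpoint)
  counts <- as.matrix(counts)
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("meta must contain every patient in the count matrix")
  z <- zscore_rows(normalize_log2(counts, size_factors[colnames(counts)]))
  tr_time <- meta[[paste0(endpoint, "_time")]]
  tr_event <- meta[[paste0(endpoint, "_event")]]
  coefs <- fit_signature_cox(z, tr_time, tr_event)
  cvec <- stats::setNames(coefs$coef, coefs$feature_id)
  scores <- compute_risk_score(z, cvec)
  strat <- stratify(scores, cutoff = cutoff)
  eval_ep <- function(ep) {
    tt <- meta[[paste0(ep, "_time")]]; ev <- meta[[paste0(ep, "_event")]]
    list(km = km_curve(tt, ev, strat$group),
         logrank = logrank_test(tt, ev, strat$group))
  }
  structure(list(coefficients = coefs, scores = scores,
                 group = strat$group, cutoff = strat$cutoff,
                 normalized = z, endpoint = endpoint,
                 os = eval_ep("os"), pfs = eval_ep("pfs")),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model: %d-feature signature, %d patients (%d high / %d low risk)\n",
              nrow(x$coefficients), length(x$scores),
              sum(x$group == "high"), sum(x$group == "low")))
  cat(sprintf("  trained on %s; log-rank p: OS = %.3g, PFS = %.3g\n",
              toupper(x$endpoint), x$os$logrank$p, x$pfs$logrank$p))
  invisible(x)
}
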