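#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator. Defaults emulate the study design the pipeline targets: a small
#' immune-checkpoint-blockade cohort of 12 pre-treatment biopsies (8 responders
#' versus 4 non-responders), five circRNA callers with distinct coordinate
#' conventions and per-caller dropout, negative-binomial counts with a planted
#' two-group effect, miRNA interaction tables whose mRNA side carries support
#' out of 7 prediction tools, and survival times whose hazard depends on a
#' planted ceRNA signature.
#'
#' @param n_responders,n_nonresponders group sizes (counts >= 1).
#' @param n_circ_loci number of true circRNA loci.
#' @param n_callers number of circRNA callers (default 5).
#' @param caller_detection_prob probability that a given caller reports a
#'   given locus at all (caller dropout).
#' @param caller_offset_profile named list of length-2 integer vectors
#'   `c(start, end)`: the shift that converts each caller's reported
#'   coordinates to the canonical 0-based half-open convention
#'   (see [default_offset_profiles()]).
#' @param n_lnc,n_mrna,n_mirna feature counts for the lncRNA and mRNA count
#'   matrices and the miRNA id pool.
#' @param de_fraction fraction of features per matrix with a planted effect.
#' @param planted_log2fc absolute planted log2 fold change
#'   (responder vs non-responder; direction randomized per feature).
#' @param nb_dispersion NB dispersion alpha, variance = mu + alpha * mu^2.
#' @param mean_expression scale of per-feature base means (log-normal around
#'   this value for the lncRNA/mRNA matrices; BSJ counts use a tenth of it).
#' @param n_pred_tools number of miRNA-target prediction tools (default 7).
#' @param support_distribution probabilities over 1..n_pred_tools from which
#'   decoy mRNA-miRNA interactions draw their tool support.
#' @param baseline_hazard events per month for a patient with zero risk
#'   signal.
#' @param signature_hazard_beta log-hazard increase per unit of latent risk
#'   signal.
#' @param censor_rate expected fraction of censored observations.
#' @param seed master integer seed; every stage derives its own substream via
#'   [substream_seed()].
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_responders = 8L,
                       n_nonresponders = 4L,
                       n_circ_loci = 300L,
                       n_callers = 5L,
                       caller_detection_prob = 0.8,
                       caller_offset_profile = default_offset_profiles(n_callers),
                       n_lnc = 200L,
                       n_mrna = 500L,
                       n_mirna = 150L,
                       de_fraction = 0.1,
                       planted_log2fc = 2,
                       nb_dispersion = 0.1,
                       mean_expression = 100,
                       n_pred_tools = 7L,
                       support_distribution = c(0.35, 0.25, 0.15, 0.10,
                                                0.07, 0.05, 0.03),
                       baseline_hazard = 0.05,
                       signature_hazard_beta = 1,
                       censor_rate = 0.2,
                       seed = 1L) {
  cfg <- list(n_responders = n_responders, n_nonresponders = n_nonresponders,
              n_circ_loci = n_circ_loci, n_callers = n_callers,
              caller_detection_prob = caller_detection_prob,
              caller_offset_profile = caller_offset_profile,
              n_lnc = n_lnc, n_mrna = n_mrna, n_mirna = n_mirna,
              de_fraction = de_fraction, planted_log2fc = planted_log2fc,
              nb_dispersion = nb_dispersion,
              mean_expression = mean_expression,
              n_pred_tools = n_pred_tools,
              support_distribution = support_distribution,
              baseline_hazard = baseline_hazard,
              signature_hazard_beta = signature_hazard_beta,
              censor_rate = censor_rate, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` to validate.
#' @export
validate_sim_config <- function(config) {
  cfg_err <- function(field, why)
    stop(sprintf("invalid sim_config: field '%s' %s", field, why),
         call. = FALSE)
  counts <- c("n_responders", "n_nonresponders", "n_circ_loci", "n_callers",
              "n_lnc", "n_mrna", "n_mirna", "n_pred_tools")
  for (f in counts) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != floor(v))
      cfg_err(f, "must be an integer count >= 1")
  }
  for (f in c("caller_detection_prob", "censor_rate", "de_fraction")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      cfg_err(f, "must be a probability in [0, 1]")
  }
  if (!is.numeric(config$nb_dispersion) || config$nb_dispersion <= 0)
    cfg_err("nb_dispersion", "must be > 0")
  if (!is.numeric(config$mean_expression) || config$mean_expression <= 0)
    cfg_err("mean_expression", "must be > 0")
  if (!is.numeric(config$baseline_hazard) || config$baseline_hazard <= 0)
    cfg_err("baseline_hazard", "must be > 0")
  if (!is.numeric(config$planted_log2fc) || config$planted_log2fc < 0)
    cfg_err("planted_log2fc", "must be >= 0")
  p <- config$support_distribution
  if (!is.numeric(p) || length(p) != config$n_pred_tools || any(p < 0) ||
      sum(p) <= 0)
    cfg_err("support_distribution",
            sprintf("must be %d non-negative weights", config$n_pred_tools))
  prof <- config$caller_offset_profile
  if (!is.list(prof) || length(prof) != config$n_callers ||
      is.null(names(prof)) || anyDuplicated(names(prof)) ||
      !all(vapply(prof, function(x) is.numeric(x) && length(x) == 2L,
                  logical(1))))
    cfg_err("caller_offset_profile",
            "must be a named list of n_callers length-2 numeric shifts")
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      is.na(config$seed))
    cfg_err("seed", "must be a single integer")
  config
}

#' Shipped coordinate-convention shifts for common circRNA callers
#'
#' The shift `c(start, end)` added to a caller's reported coordinates yields
#' the canonical 0-based half-open interval. CIRCexplorer2 emits BED (already
#' 0-based half-open); CIRI, DCC, STARchip and CIRIquant report 1-based
#' fully-closed intervals, so their start shifts by -1.
#'
#' @param n_callers how many profiles to return (first `n_callers` of the 5).
#' @return named list of length-2 integer vectors.
#' @export
default_offset_profiles <- function(n_callers = 5L) {
  prof <- list(ciri          = c(-1L, 0L),
               circexplorer2 = c(0L, 0L),
               dcc           = c(-1L, 0L),
               starchip      = c(-1L, 0L),
               ciriquant     = c(-1L, 0L))
  if (n_callers > length(prof)) {
    extra <- paste0("caller", seq_len(n_callers - length(prof)) + length(prof))
    prof <- c(prof, stats::setNames(rep(list(c(0L, 0L)), length(extra)), extra))
  }
  prof[seq_len(n_callers)]
}

#' Simulate the patient cohort
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per sample: `sample_id`, `response`
#'   (`"responder"` / `"non_responder"`), and `total_linear_mapped_reads`
#'   (the library-size anchor used for size-factor estimation).
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_responders + config$n_nonresponders
  with_substream(config$seed, "cohort", {
    data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      response = rep(c("responder", "non_responder"),
                     c(config$n_responders, config$n_nonresponders)),
      total_linear_mapped_reads =
        round(stats::rlnorm(n, meanlog = log(2e7), sdlog = 0.25)),
      stringsAsFactors = FALSE)
  })
}

# Draw NB counts for a features-x-samples block.
# mu: matrix of means; alpha: dispersion (variance mu + alpha mu^2).
rnb_matrix <- function(mu, alpha) {
  m <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                             size = 1 / alpha),
              nrow = nrow(mu), dimnames = dimnames(mu))
  m
}

# Shared helper: per-feature base means, planted DE directions, group means.
plant_effects <- function(n_feat, prefix, cohort, config, mean_scale) {
  n_de <- round(config$de_fraction * n_feat)
  if (config$de_fraction > 0 && n_de < 1)
    warning(sprintf("de_fraction x %d features < 1; planting no %s effects",
                    n_feat, prefix))
  ids <- sprintf("%s_%04d", prefix, seq_len(n_feat))
  base_mean <- stats::rlnorm(n_feat, meanlog = log(mean_scale), sdlog = 0.5)
  lfc <- numeric(n_feat)
  de_idx <- integer(0)
  if (n_de >= 1) {
    de_idx <- sort(sample.int(n_feat, n_de))
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      config$planted_log2fc
  }
  sf <- cohort$total_linear_mapped_reads /
    exp(mean(log(cohort$total_linear_mapped_reads)))
  is_resp <- cohort$response == "responder"
  # responder mean = base * 2^(lfc/2), non-responder = base * 2^(-lfc/2)
  mu <- outer(base_mean, rep(1, nrow(cohort)))
  mu <- mu * 2^(outer(lfc / 2, ifelse(is_resp, 1, -1)))
  mu <- sweep(mu, 2L, sf, "*")
  dimnames(mu) <- list(ids, cohort$sample_id)
  list(ids = ids, base_mean = base_mean, log2fc = lfc, mu = mu,
       de_idx = de_idx)
}

#' Simulate per-caller circRNA calls and linear junction counts
#'
#' Generates a registry of true circRNA loci on canonical 0-based half-open
#' coordinates, draws per-sample BSJ counts (NB, with a planted two-group
#' effect on `de_fraction` of the loci) and FSJ counts, and emits one call
#' table per caller in that caller's own coordinate convention. Each caller
#' reports a locus at all with probability `caller_detection_prob`
#' (independent per locus and caller); a reporting caller re-quantifies the
#' per-sample BSJ count with Poisson noise and emits rows only where its
#' count is positive.
#'
#' @param config a [sim_config()].
#' @param cohort output of [simulate_cohort()].
#' @return list with elements
#'   `calls` (named list of per-caller data.frames: `chrom, start, end,
#'   strand, sample_id, bsj_reads, caller_id`, in caller coordinates),
#'   `fsj` (matrix loci x samples of forward-splice junction counts),
#'   `registry` (true locus table: `circ_id, chrom, start, end, strand,
#'   host_gene, base_mean, log2fc, is_de`), and
#'   `truth_de` (planted circRNA DE entries).
#' @export
simulate_circ_calls <- function(config, cohort) {
  config <- validate_sim_config(config)
  if (nrow(cohort) == 0L) stop("cohort must be nonempty")
  with_substream(config$seed, "circ_calls", {
    n <- config$n_circ_loci
    chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
    chrom <- sample(chroms, n, replace = TRUE,
                    prob = c(22:1, 10, 3) / sum(c(22:1, 10, 3)))
    start <- floor(stats::runif(n, 1e4, 1e8))
    width <- floor(stats::runif(n, 200, 2000))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    host_gene <- sprintf("GENE%04d", sample.int(max(1L, n %/% 3L), n,
                                                replace = TRUE))
    eff <- plant_effects(n, "circ", cohort, config,
                         mean_scale = config$mean_expression / 10)
    registry <- data.frame(
      circ_id = circ_key(chrom, start, start + width, strand),
      chrom = chrom, start = start, end = start + width, strand = strand,
      host_gene = host_gene, base_mean = eff$base_mean,
      log2fc = eff$log2fc,
      is_de = seq_len(n) %in% eff$de_idx,
      stringsAsFactors = FALSE)
    bsj_true <- rnb_matrix(eff$mu, config$nb_dispersion)
    rownames(bsj_true) <- registry$circ_id
    fsj_mu <- sweep(outer(stats::rlnorm(n, log(config$mean_expression / 2),
                                        0.5),
                          rep(1, nrow(cohort))),
                    2L, cohort$total_linear_mapped_reads /
                      exp(mean(log(cohort$total_linear_mapped_reads))), "*")
    fsj <- rnb_matrix(fsj_mu, config$nb_dispersion)
    dimnames(fsj) <- list(registry$circ_id, cohort$sample_id)

    callers <- names(config$caller_offset_profile)
    calls <- stats::setNames(vector("list", length(callers)), callers)
    for (cl in callers) {
      off <- config$caller_offset_profile[[cl]]
      detected <- stats::runif(n) < config$caller_detection_prob
      rows <- list()
      if (any(detected)) {
        idx <- which(detected)
        obs <- matrix(stats::rpois(length(idx) * nrow(cohort),
                                   lambda = as.vector(bsj_true[idx, ,
                                                               drop = FALSE])),
                      nrow = length(idx))
        nz <- which(obs > 0, arr.ind = TRUE)
        if (nrow(nz) > 0) {
          li <- idx[nz[, 1L]]
          rows <- data.frame(
            chrom = registry$chrom[li],
            # reported = canonical - shift, so that reported + shift = canonical
            start = registry$start[li] - off[1L],
            end = registry$end[li] - off[2L],
            strand = registry$strand[li],
            sample_id = cohort$sample_id[nz[, 2L]],
            bsj_reads = obs[nz],
            caller_id = cl,
            stringsAsFactors = FALSE)
        }
      }
      calls[[cl]] <- if (is.data.frame(rows)) rows else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   strand = character(), sample_id = character(),
                   bsj_reads = integer(), caller_id = character(),
                   stringsAsFactors = FALSE)
    }
    truth_de <- data.frame(feature_id = registry$circ_id[registry$is_de],
                           class = "circRNA",
                           log2fc = registry$log2fc[registry$is_de],
                           stringsAsFactors = FALSE)
    list(calls = calls, fsj = fsj, registry = registry, truth_de = truth_de,
         bsj_true = bsj_true)
  })
}

#' Simulate lncRNA and mRNA count matrices with planted effects
#'
#' Counts are NB(mean, dispersion) with per-sample means scaled by the
#' cohort's library-size factors; `round(de_fraction * n)` features per matrix
#' carry a planted log2 fold change of `planted_log2fc` with random sign.
#'
#' @inheritParams simulate_circ_calls
#' @return list with `lnc` and `mrna` count matrices (features x samples) and
#'   `truth_de` (data.frame `feature_id, class, log2fc` of planted features).
#' @export
simulate_expression <- function(config, cohort) {
  config <- validate_sim_config(config)
  if (length(unique(cohort$response)) < 2L)
    stop("cohort must contain both response groups")
  with_substream(config$seed, "expression", {
    lnc_eff <- plant_effects(config$n_lnc, "lnc", cohort, config,
                             config$mean_expression)
    mrna_eff <- plant_effects(config$n_mrna, "mrna", cohort, config,
                              config$mean_expression)
    lnc <- rnb_matrix(lnc_eff$mu, config$nb_dispersion)
    mrna <- rnb_matrix(mrna_eff$mu, config$nb_dispersion)
    truth <- rbind(
      data.frame(feature_id = lnc_eff$ids[lnc_eff$de_idx],
                 class = rep("lncRNA", length(lnc_eff$de_idx)),
                 log2fc = lnc_eff$log2fc[lnc_eff$de_idx]),
      data.frame(feature_id = mrna_eff$ids[mrna_eff$de_idx],
                 class = rep("mRNA", length(mrna_eff$de_idx)),
                 log2fc = mrna_eff$log2fc[mrna_eff$de_idx]))
    list(lnc = lnc, mrna = mrna, truth_de = truth)
  })
}

#' Simulate ceRNA-miRNA and mRNA-miRNA interaction tables
#'
#' Plants one (ceRNA, miRNA, mRNA) triple per differentially expressed ceRNA
#' (cycling over DE mRNAs), guaranteeing mRNA-side tool support >= 5 so every
#' planted triple survives the network's consensus filter. Decoy interactions
#' are added for both layers; decoy mRNA-miRNA support is drawn from
#' `support_distribution`.
#'
#' @param config a [sim_config()].
#' @param feature_ids list with character vectors `circ`, `lnc`, `mrna`
#'   (all feature ids; must be disjoint).
#' @param de_ids list with character vectors `cerna` (DE circRNA and lncRNA
#'   ids) and `mrna` (DE mRNA ids) used to plant recoverable triples, plus
#'   optional numeric vectors `cerna_sign` / `mrna_sign` (same order) giving
#'   each feature's planted direction: when present, every triple pairs a
#'   ceRNA with a same-direction mRNA, matching the positive ceRNA-mRNA
#'   correlation the sponge model predicts.
#' @return list with `cerna_mirna` (columns `source_id, mirna_id,
#'   source_class`), `mrna_mirna` (columns `source_id, mirna_id, support`),
#'   and `planted_triples` (`cerna_id, mirna_id, mrna_id`).
#' @export
simulate_interactions <- function(config, feature_ids, de_ids) {
  config <- validate_sim_config(config)
  all_ids <- c(feature_ids$circ, feature_ids$lnc, feature_ids$mrna)
  if (anyDuplicated(all_ids))
    stop("feature id sets must be disjoint")
  with_substream(config$seed, "interactions", {
    mirnas <- sprintf("miR-%04d", seq_len(config$n_mirna))
    n_tools <- config$n_pred_tools

    planted <- data.frame(cerna_id = character(), mirna_id = character(),
                          mrna_id = character(), stringsAsFactors = FALSE)
    if (length(de_ids$cerna) > 0 && length(de_ids$mrna) > 0) {
      nc <- length(de_ids$cerna)
      partner <- rep_len(de_ids$mrna, nc)
      if (!is.null(de_ids$cerna_sign) && !is.null(de_ids$mrna_sign)) {
        for (s in c(-1, 1)) {
          ci <- which(sign(de_ids$cerna_sign) == s)
          mi <- which(sign(de_ids$mrna_sign) == s)
          if (length(ci) > 0 && length(mi) > 0)
            partner[ci] <- rep_len(de_ids$mrna[mi], length(ci))
        }
      }
      planted <- data.frame(
        cerna_id = de_ids$cerna,
        mirna_id = sample(mirnas, nc, replace = nc > length(mirnas)),
        mrna_id = partner,
        stringsAsFactors = FALSE)
    }

    cerna_pool <- c(feature_ids$circ, feature_ids$lnc)
    n_decoy_c <- 2L * length(cerna_pool)
    decoy_c <- data.frame(
      source_id = sample(cerna_pool, n_decoy_c, replace = TRUE),
      mirna_id = sample(mirnas, n_decoy_c, replace = TRUE),
      stringsAsFactors = FALSE)
    cerna_mirna <- rbind(
      data.frame(source_id = planted$cerna_id, mirna_id = planted$mirna_id,
                 stringsAsFactors = FALSE),
      decoy_c)
    cerna_mirna <- cerna_mirna[!duplicated(cerna_mirna), , drop = FALSE]
    cerna_mirna$source_class <- ifelse(cerna_mirna$source_id %in%
                                         feature_ids$circ,
                                       "circRNA", "lncRNA")

    n_decoy_m <- 3L * length(feature_ids$mrna)
    decoy_m <- data.frame(
      source_id = sample(feature_ids$mrna, n_decoy_m, replace = TRUE),
      mirna_id = sample(mirnas, n_decoy_m, replace = TRUE),
      support = sample(seq_len(n_tools), n_decoy_m, replace = TRUE,
                       prob = config$support_distribution),
      stringsAsFactors = FALSE)
    planted_m <- data.frame(
      source_id = planted$mrna_id, mirna_id = planted$mirna_id,
      support = sample(5:n_tools, nrow(planted), replace = TRUE),
      stringsAsFactors = FALSE)
    mrna_mirna <- rbind(planted_m, decoy_m)
    # planted pairs win on collision so the support >= 5 guarantee holds
    mrna_mirna <- mrna_mirna[!duplicated(mrna_mirna[, c("source_id",
                                                        "mirna_id")]), ,
                             drop = FALSE]
    rownames(mrna_mirna) <- NULL
    list(cerna_mirna = cerna_mirna, mrna_mirna = mrna_mirna,
         planted_triples = planted)
  })
}

#' Simulate survival endpoints from a latent risk signal
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(signature_hazard_beta * signal)`. Censoring times
#' are drawn independently from an exponential whose rate is calibrated so
#' the expected censored fraction equals `censor_rate` at the average hazard
#' (non-informative censoring, so downstream Cox estimation is unbiased).
#' Progression-free survival uses twice the baseline hazard of overall
#' survival with the same signal.
#'
#' @param config a [sim_config()].
#' @param signal numeric vector of per-sample latent risk values (named by
#'   sample id if available).
#' @return data.frame `sample_id, os_time, os_event, pfs_time, pfs_event`;
#'   times are in months, events are 0/1.
#' @export
simulate_survival <- function(config, signal) {
  config <- validate_sim_config(config)
  if (config$baseline_hazard <= 0)
    stop("invalid sim_config: field 'baseline_hazard' must be > 0")
  n <- length(signal)
  ids <- if (!is.null(names(signal))) names(signal) else
    sprintf("S%02d", seq_len(n))
  with_substream(config$seed, "survival", {
    draw <- function(base) {
      haz <- base * exp(config$signature_hazard_beta * signal)
      t_event <- stats::rexp(n, rate = haz)
      if (config$censor_rate > 0) {
        cens_rate <- mean(haz) * config$censor_rate /
          (1 - min(config$censor_rate, 0.999))
        t_cens <- stats::rexp(n, rate = cens_rate)
      } else {
        t_cens <- rep(Inf, n)
      }
      list(time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
    }
    os <- draw(config$baseline_hazard)
    pfs <- draw(2 * config$baseline_hazard)
    data.frame(sample_id = ids, os_time = os$time, os_event = os$event,
               pfs_time = pfs$time, pfs_event = pfs$event,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Runs every generator stage and assembles the inputs the pipeline consumes
#' plus an exhaustive truth table: cohort metadata with survival endpoints,
#' per-caller circRNA call tables, FSJ counts, lncRNA/mRNA count matrices,
#' interaction tables, and the planted DE features, triples, locus registry
#' and latent risk signal. The latent signal is the coefficient-weighted
#' planted ceRNA signature: each planted DE ceRNA contributes its direction
#' (scaled by `1/sqrt(N)`) times its z-scored log2 normalized expression,
#' and the resulting per-sample signal is standardized so
#' `signature_hazard_beta` is the log-hazard increase per signature
#' standard deviation.
#'
#' @param config a [sim_config()].
#' @return list with `config, meta, calls, fsj, lnc, mrna, interactions,
#'   annotation` and `truth` (list: `de_features`, `planted_triples`,
#'   `registry`, `signal`, `signature_coefficients`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  cohort <- simulate_cohort(config)
  circ <- simulate_circ_calls(config, cohort)
  expr <- simulate_expression(config, cohort)
  de_features <- rbind(circ$truth_de, expr$truth_de)
  de_cerna <- de_features$feature_id[de_features$class != "mRNA"]
  de_mrna <- de_features$feature_id[de_features$class == "mRNA"]
  inter <- simulate_interactions(
    config,
    feature_ids = list(circ = circ$registry$circ_id,
                       lnc = rownames(expr$lnc),
                       mrna = rownames(expr$mrna)),
    de_ids = list(
      cerna = de_cerna,
      mrna = de_mrna,
      cerna_sign = de_features$log2fc[match(de_cerna,
                                            de_features$feature_id)],
      mrna_sign = de_features$log2fc[match(de_mrna,
                                           de_features$feature_id)]))

  sf <- estimate_size_factors(stats::setNames(
    cohort$total_linear_mapped_reads, cohort$sample_id))
  sig_expr <- rbind(circ$bsj_true[circ$registry$is_de, , drop = FALSE],
                    expr$lnc[rownames(expr$lnc) %in% de_cerna, ,
                             drop = FALSE])
  coefs <- stats::setNames(
    de_features$log2fc[match(rownames(sig_expr), de_features$feature_id)] /
      config$planted_log2fc / sqrt(max(1, nrow(sig_expr))),
    rownames(sig_expr))
  z <- zscore_rows(normalize_log2(sig_expr, sf[colnames(sig_expr)]))
  signal <- as.vector(crossprod(z, coefs))
  # standardized so signature_hazard_beta is log-hazard per signature SD
  if (stats::sd(signal) > 0)
    signal <- (signal - mean(signal)) / stats::sd(signal)
  names(signal) <- colnames(sig_expr)
  surv <- simulate_survival(config, signal)
  meta <- merge(cohort, surv, by = "sample_id", sort = TRUE)

  annotation <- circ$registry[, c("chrom", "start", "end", "strand",
                                  "host_gene")]
  annotation$external_id <- sprintf("hsa-%s_%04d", annotation$host_gene,
                                    seq_len(nrow(annotation)))
  list(config = config, meta = meta, calls = circ$calls, fsj = circ$fsj,
       lnc = expr$lnc, mrna = expr$mrna, interactions = inter,
       annotation = annotation,
       truth = list(de_features = de_features,
                    planted_triples = inter$planted_triples,
                    registry = circ$registry,
                    signal = signal,
                    signature_coefficients = coefs))
}

#' Write a simulated dataset to disk
#'
#' Materializes every input artifact the pipeline can consume: per-caller
#' call tables (one TSV combining BED-like columns with `sample_id`,
#' `bsj_reads`, `caller_id`), FSJ and expression count matrices, sample
#' metadata, interaction tables, the circRNA annotation, the truth tables
#' and the generating configuration (YAML).
#'
#' @param ds output of [simulate_dataset()].
#' @param outdir directory to write into (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(calls = p("circ_calls.tsv"), fsj = p("fsj_counts.tsv"),
             lnc = p("lnc_counts.tsv"), mrna = p("mrna_counts.tsv"),
             meta = p("sample_meta.tsv"),
             cerna_mirna = p("cerna_mirna.tsv"),
             mrna_mirna = p("mrna_mirna.tsv"),
             annotation = p("circ_annotation.tsv"),
             truth_de = p("truth_de_features.tsv"),
             truth_triples = p("truth_planted_triples.tsv"),
             config = p("sim_config.yaml"))
  write_tsv_table(do.call(rbind, c(ds$calls, list(make.row.names = FALSE))),
                  paths["calls"])
  write_matrix_tsv(ds$fsj, paths["fsj"])
  write_matrix_tsv(ds$lnc, paths["lnc"])
  write_matrix_tsv(ds$mrna, paths["mrna"])
  write_tsv_table(ds$meta, paths["meta"])
  write_tsv_table(ds$interactions$cerna_mirna, paths["cerna_mirna"])
  write_tsv_table(ds$interactions$mrna_mirna, paths["mrna_mirna"])
  write_tsv_table(ds$annotation, paths["annotation"])
  write_tsv_table(ds$truth$de_features, paths["truth_de"])
  write_tsv_table(ds$truth$planted_triples, paths["truth_triples"])
  cfg <- ds$config
  cfg$caller_offset_profile <- lapply(cfg$caller_offset_profile, as.integer)
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}
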