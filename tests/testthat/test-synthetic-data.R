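test_that("cohort generation honours group sizes and seeded determinism", {
  cfg <- sim_config(seed = 11L)
  cohort <- simulate_cohort(cfg)
  expect_equal(sum(cohort$response == "responder"), 8L)
  expect_equal(sum(cohort$response == "non_responder"), 4L)
  expect_identical(cohort, simulate_cohort(cfg))
  expect_false(identical(cohort, simulate_cohort(sim_config(seed = 12L))))
  expect_error(sim_config(n_responders = 0), "n_responders")
  expect_error(sim_config(caller_detection_prob = 1.2),
               "caller_detection_prob")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("caller dropout behaves at degenerate probabilities and matches a re-draw", {
  cohort <- simulate_cohort(sim_config(seed = 3L))
  all_in <- simulate_circ_calls(sim_config(caller_detection_prob = 1,
                                           n_circ_loci = 40L, seed = 3L),
                                cohort)
  for (tab in all_in$calls)
    expect_equal(length(unique(circ_key(tab$chrom, tab$start, tab$end,
                                        tab$strand))), 40L)
  none <- simulate_circ_calls(sim_config(caller_detection_prob = 0,
                                         n_circ_loci = 40L, seed = 3L),
                              cohort)
  expect_true(all(vapply(none$calls, nrow, integer(1)) == 0L))

  # per-caller presence counts fall inside an independent Binomial(500, 0.7)
  # re-draw envelope
  cfg <- sim_config(n_circ_loci = 500L, caller_detection_prob = 0.7,
                    seed = 17L)
  calls <- simulate_circ_calls(cfg, simulate_cohort(cfg))
  presence <- vapply(calls$calls, function(tab)
    length(unique(paste(tab$chrom, tab$start))), integer(1))
  set.seed(1)
  envelope <- range(rbinom(2000, 500, 0.7))
  expect_true(all(presence >= envelope[1] & presence <= envelope[2]))
})

test_that("expression generator plants the configured number of effects", {
  cfg <- sim_config(n_lnc = 50L, n_mrna = 1000L, de_fraction = 0.1,
                    seed = 5L)
  cohort <- simulate_cohort(cfg)
  expr <- simulate_expression(cfg, cohort)
  truth <- expr$truth_de
  expect_equal(sum(truth$class == "mRNA"), 100L)
  expect_equal(sum(truth$class == "lncRNA"), 5L)
  expect_identical(expr$lnc, simulate_expression(cfg, cohort)$lnc)
  w <- capture_warnings(
    simulate_expression(sim_config(n_lnc = 4L, n_mrna = 4L,
                                   de_fraction = 0.1, seed = 5L), cohort))
  expect_length(w, 2L)   # one per matrix
  expect_match(w, "planting no", all = TRUE)
})

test_that("a zero planted effect is statistically invisible", {
  # with planted_log2fc = 0 the 'planted' features must be indistinguishable
  # from null features: compare group-mean log-ratios between the two sets
  pvals <- vapply(1:30, function(s) {
    cfg <- sim_config(n_lnc = 2L, n_mrna = 200L, planted_log2fc = 0,
                      de_fraction = 0.25, seed = s)
    cohort <- simulate_cohort(cfg)
    expr <- suppressWarnings(simulate_expression(cfg, cohort))
    is_resp <- cohort$response == "responder"
    lr <- log2(rowMeans(expr$mrna[, is_resp]) + 1) -
      log2(rowMeans(expr$mrna[, !is_resp]) + 1)
    planted <- rownames(expr$mrna) %in% expr$truth_de$feature_id
    t.test(lr[planted], lr[!planted])$p.value
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.2)
})

test_that("interaction generator guarantees recoverable planted triples", {
  cfg <- sim_config(seed = 9L)
  ids <- list(circ = sprintf("c%02d", 1:20), lnc = sprintf("l%02d", 1:20),
              mrna = sprintf("m%02d", 1:40))
  de <- list(cerna = c("c01", "c02", "l01", "l02", "l03"),
             mrna = sprintf("m%02d", 1:10))
  inter <- simulate_interactions(cfg, ids, de)
  expect_equal(nrow(inter$planted_triples), 5L)
  sup <- merge(inter$planted_triples, inter$mrna_mirna,
               by.x = c("mrna_id", "mirna_id"),
               by.y = c("source_id", "mirna_id"))
  expect_equal(nrow(sup), 5L)
  expect_true(all(sup$support >= 5))
  expect_error(
    simulate_interactions(cfg, list(circ = "x", lnc = "x", mrna = "m"), de),
    "disjoint")

  # decoys concentrated at support 1 can never pass the 5-tool filter
  cfg1 <- sim_config(support_distribution = c(1, 0, 0, 0, 0, 0, 0),
                     seed = 9L)
  inter1 <- simulate_interactions(cfg1, ids, de)
  planted_key <- paste(inter1$planted_triples$mrna_id,
                       inter1$planted_triples$mirna_id)
  decoy <- !(paste(inter1$mrna_mirna$source_id,
                   inter1$mrna_mirna$mirna_id) %in% planted_key)
  expect_true(all(inter1$mrna_mirna$support[decoy] < 5))
})

test_that("survival generator respects censoring and hazard settings", {
  cfg0 <- sim_config(censor_rate = 0, seed = 21L)
  surv <- simulate_survival(cfg0, rnorm(50))
  expect_true(all(surv$os_event == 1L))
  expect_true(all(surv$os_time > 0))
  expect_error(
    simulate_survival(unclass_replace(cfg0, baseline_hazard = -1), rnorm(5)),
    "baseline_hazard")

  # beta = 0: times in high- vs low-signal halves come from one distribution
  ks_sig <- vapply(1:40, function(s) {
    cfg <- sim_config(signature_hazard_beta = 0, censor_rate = 0, seed = s)
    signal <- rnorm(60)
    tt <- simulate_survival(cfg, signal)$os_time
    hi <- signal > median(signal)
    suppressWarnings(ks.test(tt[hi], tt[!hi])$p.value)
  }, numeric(1))
  expect_lte(mean(ks_sig < 0.05), 0.15)
})

test_that("the full dataset is deterministic and its truth table exhaustive", {
  cfg <- sim_config(n_circ_loci = 60L, n_lnc = 40L, n_mrna = 80L,
                    seed = 31L)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$lnc, ds2$lnc)
  expect_identical(ds1$calls, ds2$calls)
  expect_identical(ds1$meta, ds2$meta)

  truth <- ds1$truth$de_features
  pools <- list(circRNA = ds1$truth$registry$circ_id,
                lncRNA = rownames(ds1$lnc), mRNA = rownames(ds1$mrna))
  for (cls in names(pools)) {
    ids <- truth$feature_id[truth$class == cls]
    expect_true(all(ids %in% pools[[cls]]))
    expect_false(any(ids %in% unlist(pools[names(pools) != cls])))
  }
  trip <- ds1$truth$planted_triples
  expect_true(all(trip$cerna_id %in% c(pools$circRNA, pools$lncRNA)))
  expect_true(all(trip$mrna_id %in% pools$mRNA))
  # one shared sample-id namespace
  expect_identical(sort(ds1$meta$sample_id), sort(colnames(ds1$lnc)))
  expect_identical(sort(ds1$meta$sample_id), sort(colnames(ds1$fsj)))
})
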