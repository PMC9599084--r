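mk_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]], sample_id = r[[5]],
               bsj_reads = as.integer(r[[6]]), caller_id = r[[7]],
               stringsAsFactors = FALSE)))
}

test_that("harmonization maps caller conventions onto one canonical key", {
  prof <- list(onebased = c(-1L, 0L), bedlike = c(0L, 0L))
  calls <- mk_calls(list("chr1", 101, 200, "+", "S01", 4, "onebased"),
                    list("chr1", 100, 200, "+", "S02", 2, "bedlike"))
  h <- harmonize_calls(calls, prof)
  expect_equal(h$start, c(100L, 100L))
  expect_equal(h$end, c(200L, 200L))
  expect_equal(unique(h$circ_id), "chr1:100-200:+")

  expect_error(harmonize_calls(calls, prof["bedlike"]), "onebased")
  expect_error(harmonize_calls(calls, prof["bedlike"]), "known profiles")

  # an interval that collapses after shifting is rejected and counted
  bad <- mk_calls(list("chr1", 200, 200, "+", "S01", 1, "bedlike"),
                  list("chr1", 100, 200, "+", "S01", 3, "bedlike"))
  expect_message(hb <- harmonize_calls(bad, prof), "rejected 1")
  expect_equal(nrow(hb), 1L)
  expect_equal(attr(hb, "rejected"), 1L)
})

test_that("harmonizing synthetic calls recovers the true locus registry", {
  cfg <- sim_config(n_circ_loci = 80L, seed = 13L)
  ds <- simulate_circ_calls(cfg, simulate_cohort(cfg))
  h <- harmonize_calls(ds$calls, cfg$caller_offset_profile)
  # brute-force offset reversal, caller by caller
  expected_keys <- unlist(lapply(names(ds$calls), function(cl) {
    tab <- ds$calls[[cl]]
    off <- cfg$caller_offset_profile[[cl]]
    circ_key(tab$chrom, tab$start + off[1], tab$end + off[2], tab$strand)
  }))
  expect_identical(h$circ_id, expected_keys)
  expect_true(all(h$circ_id %in% ds$registry$circ_id))
})

test_that("the call tensor sums duplicates and conserves reads", {
  prof <- list(a = c(0L, 0L), b = c(0L, 0L))
  one <- harmonize_calls(mk_calls(list("chr1", 10, 50, "+", "S01", 4, "a")),
                         prof)
  tens <- build_call_tensor(one)
  expect_equal(sum(tens > 0), 1L)
  expect_equal(tens["chr1:10-50:+", "S01", "a"], 4)

  dup <- harmonize_calls(mk_calls(list("chr1", 10, 50, "+", "S01", 2, "a"),
                                  list("chr1", 10, 50, "+", "S01", 3, "a")),
                         prof)
  expect_equal(build_call_tensor(dup)["chr1:10-50:+", "S01", "a"], 5)

  set.seed(42)
  cfg <- sim_config(n_circ_loci = 40L, seed = 8L)
  ds <- simulate_circ_calls(cfg, simulate_cohort(cfg))
  h <- harmonize_calls(ds$calls, cfg$caller_offset_profile)
  expect_equal(sum(build_call_tensor(h)), sum(h$bsj_reads))
})

test_that("consensus counts are medians over the reporting-caller set", {
  tens <- array(0, dim = c(1, 1, 3),
                dimnames = list("c1", "S01", c("a", "b", "c")))
  tens[1, 1, ] <- c(2, 4, 6)
  cm <- consensus_counts(tens)
  expect_equal(unname(cm$counts[1, 1]), 4)
  expect_equal(cm$support[["c1"]], c("a", "b", "c"))

  single <- array(0, dim = c(1, 1, 3),
                  dimnames = list("c1", "S01", c("a", "b", "c")))
  single[1, 1, 2] <- 4
  expect_equal(unname(consensus_counts(single)$counts[1, 1]), 4)

  set.seed(7)
  for (rep in 1:10) {
    tens <- random_call_tensor(n_circ = 30)
    cm <- consensus_counts(tens)
    for (i in sample(30, 5))
      expect_equal(unname(cm$counts[i, ]), brute_consensus_row(tens, i))
  }
})

test_that("high-confidence filter applies the reads/samples/callers criteria", {
  tens <- array(0, dim = c(3, 3, 4),
                dimnames = list(c("c1", "c2", "c3"),
                                c("S01", "S02", "S03"),
                                c("A", "B", "C", "D")))
  # c1: 3 callers, consensus >= 2 reads in 2 samples -> retained
  tens["c1", "S01", c("A", "B", "C")] <- 3
  tens["c1", "S02", c("A", "B", "C")] <- 2
  # c2: only 2 callers -> rejected
  tens["c2", , c("A", "B")] <- 5
  # c3: 3 callers but >= 2 consensus reads in only one sample -> rejected
  tens["c3", "S01", c("A", "B", "C")] <- 4
  tens["c3", "S02", "A"] <- 1
  expect_equal(high_confidence_filter(tens), "c1")
  expect_error(high_confidence_filter(tens, min_callers = 5), "exceeds")
  expect_error(high_confidence_filter(tens, min_reads = 0), ">= 1")

  set.seed(11)
  for (rep in 1:10) {
    tens <- random_call_tensor(n_circ = 60, density = 0.25)
    expect_identical(high_confidence_filter(tens), brute_filter(tens))
  }
})

test_that("the per-caller reads scope matches its own brute-force reading", {
  set.seed(12)
  for (rep in 1:5) {
    tens <- random_call_tensor(n_circ = 50, density = 0.3)
    per <- high_confidence_filter(tens, reads_scope = "per_caller")
    want <- character(0)
    for (i in seq_len(dim(tens)[1])) {
      n_good <- 0
      for (k in seq_len(dim(tens)[3]))
        if (sum(tens[i, , k] >= 2) >= 2) n_good <- n_good + 1
      if (n_good >= 3) want <- c(want, dimnames(tens)[[1]][i])
    }
    expect_identical(per, sort(want))
  }
})

test_that("the retained set is monotone and order-invariant", {
  set.seed(13)
  tens <- random_call_tensor(n_circ = 40, density = 0.25)
  base <- high_confidence_filter(tens)
  for (rep in 1:40) {
    t2 <- tens
    cell <- c(sample(dim(tens)[1], 1), sample(dim(tens)[2], 1),
              sample(dim(tens)[3], 1))
    t2[cell[1], cell[2], cell[3]] <- t2[cell[1], cell[2], cell[3]] +
      sample(1:3, 1)
    expect_true(all(base %in% high_confidence_filter(t2)))
  }
  # permuting samples and callers leaves the retained set unchanged
  perm <- tens[, sample(dim(tens)[2]), sample(dim(tens)[3])]
  expect_identical(high_confidence_filter(perm), base)
})

test_that("genome summaries partition reads by group and rank host genes", {
  counts <- matrix(c(10, 5, 2, 3), nrow = 2,
                   dimnames = list(c("chr5:10-90:+", "chr5:200-400:-"),
                                   c("S01", "S02")))
  cm <- structure(list(counts = counts,
                       support = list(`chr5:10-90:+` = "a",
                                      `chr5:200-400:-` = "a")),
                  class = "consensus_matrix")
  groups <- c(S01 = "responder", S02 = "non_responder")
  ann <- data.frame(circ_id = c("chr5:10-90:+", "chr5:200-400:-"),
                    host_gene = c("G1", "G1"), stringsAsFactors = FALSE)
  sm <- summarize_genome(cm, ann, groups)
  expect_equal(unique(sm$per_chromosome$chrom), "chr5")
  expect_equal(sum(sm$per_chromosome$total_reads), sum(counts))
  expect_equal(sm$host_gene_ranking$total_reads, sum(counts))

  sm0 <- summarize_genome(cm, ann[0, ], groups)
  expect_true(all(sm0$locus_table$host_gene == "novel"))
  expect_equal(nrow(sm0$host_gene_ranking), 0L)

  # generator truth: per-chromosome totals match the registry allocation
  cfg <- sim_config(n_circ_loci = 50L, caller_detection_prob = 1, seed = 19L)
  cohort <- simulate_cohort(cfg)
  ds <- simulate_circ_calls(cfg, cohort)
  tens <- build_call_tensor(harmonize_calls(ds$calls,
                                            cfg$caller_offset_profile))
  cmx <- consensus_counts(tens)
  ann2 <- ds$registry[, c("circ_id", "host_gene")]
  sm2 <- summarize_genome(cmx, ann2,
                          setNames(cohort$response, cohort$sample_id))
  chrom_truth <- tapply(rowSums(cmx$counts),
                        sub(":.*$", "", rownames(cmx$counts)), sum)
  agg <- tapply(sm2$per_chromosome$total_reads, sm2$per_chromosome$chrom, sum)
  expect_equal(agg[names(chrom_truth)], chrom_truth)
  expect_false("novel" %in% sm2$host_gene_ranking$host_gene)
})
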