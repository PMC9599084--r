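#' Harmonize multi-caller circRNA calls onto canonical coordinates
#'
#' circRNA callers disagree on coordinate conventions (0- vs 1-based, open vs
#' closed intervals), so the same back-splice junction is reported at
#' slightly different positions. Each caller's offset profile `c(start, end)`
#' is added to its reported coordinates to obtain the canonical 0-based
#' half-open interval; calls from different callers at the same biological
#' junction then share one locus key `chrom:start-end:strand`.
#'
#' Records whose interval collapses (`start >= end`) after shifting are
#' rejected and counted in the `rejected` attribute, with a message.
#'
#' @param calls a data.frame with columns `chrom, start, end, strand,
#'   sample_id, bsj_reads, caller_id`, or a named list of such per-caller
#'   data.frames (as produced by [simulate_circ_calls()]).
#' @param offset_profile named list mapping each `caller_id` to its
#'   `c(start, end)` shift; defaults to [default_offset_profiles()].
#' @return data.frame of calls on canonical coordinates with an added
#'   `circ_id` key column; attribute `rejected` holds the number of dropped
#'   records.
#' @export
harmonize_calls <- function(calls, offset_profile = default_offset_profiles()) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  need <- c("chrom", "start", "end", "strand", "sample_id", "bsj_reads",
            "caller_id")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(calls$caller_id), names(offset_profile))
  if (length(unknown) > 0)
    stop(sprintf("unknown caller id(s) %s; known profiles: %s",
                 paste(unknown, collapse = ", "),
                 paste(names(offset_profile), collapse = ", ")))
  if (nrow(calls) == 0L) {
    calls$circ_id <- character(0)
    attr(calls, "rejected") <- 0L
    return(calls)
  }
  shifts <- do.call(rbind, offset_profile[calls$caller_id])
  out <- calls
  out$start <- calls$start + shifts[, 1L]
  out$end <- calls$end + shifts[, 2L]
  bad <- out$start >= out$end
  if (any(bad))
    message(sprintf("harmonize_calls: rejected %d record(s) with start >= end after shifting",
                    sum(bad)))
  out <- out[!bad, , drop = FALSE]
  out$circ_id <- circ_key(out$chrom, out$start, out$end, out$strand)
  rownames(out) <- NULL
  attr(out, "rejected") <- sum(bad)
  out
}

#' Build the circRNA x sample x caller BSJ count tensor
#'
#' Missing (circ, sample, caller) cells are zero; duplicate records for one
#' cell are summed (split output lines from one caller are assumed to refer
#' to the same junction).
#'
#' @param harmonized output of [harmonize_calls()].
#' @param samples,callers optional character vectors fixing the sample /
#'   caller dimensions (defaults: those observed in the input, sorted).
#' @return 3-d numeric array with dimnames `(circ_id, sample_id, caller_id)`.
#' @export
build_call_tensor <- function(harmonized, samples = NULL, callers = NULL) {
  circs <- sort(unique(harmonized$circ_id))
  if (is.null(samples)) samples <- sort(unique(harmonized$sample_id))
  if (is.null(callers)) callers <- sort(unique(harmonized$caller_id))
  tens <- array(0, dim = c(length(circs), length(samples), length(callers)),
                dimnames = list(circ_id = circs, sample_id = samples,
                                caller_id = callers))
  if (nrow(harmonized) > 0) {
    idx <- cbind(match(harmonized$circ_id, circs),
                 match(harmonized$sample_id, samples),
                 match(harmonized$caller_id, callers))
    agg <- rowsum(harmonized$bsj_reads,
                  group = paste(idx[, 1L], idx[, 2L], idx[, 3L]))
    key <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
    tens[cbind(as.integer(key[, 1L]), as.integer(key[, 2L]),
               as.integer(key[, 3L]))] <- agg[, 1L]
  }
  tens
}

#' Merge per-caller counts into a consensus BSJ matrix
#'
#' For each circRNA, the set of callers that reported it anywhere (any
#' sample) defines its caller support; the consensus count for each
#' (circ, sample) cell is the median over that support set's counts
#' (zeros included for supporting callers that missed the sample), rounded
#' half to even. Cells of circRNAs with no report stay zero.
#'
#' @param tensor output of [build_call_tensor()].
#' @return object of class `consensus_matrix`: list with `counts` (matrix
#'   circ x sample) and `support` (named list of caller-id sets).
#' @export
consensus_counts <- function(tensor) {
  if (length(tensor) == 0L) stop("tensor is empty")
  reported <- apply(tensor > 0, c(1L, 3L), any)   # circ x caller
  counts <- matrix(0, nrow = dim(tensor)[1L], ncol = dim(tensor)[2L],
                   dimnames = dimnames(tensor)[1:2])
  support <- apply(reported, 1L, function(r) colnames(reported)[r],
                   simplify = FALSE)
  for (i in seq_len(nrow(counts))) {
    sup <- reported[i, ]
    if (!any(sup)) next
    counts[i, ] <- round(apply(tensor[i, , sup, drop = FALSE], 2L,
                               stats::median))
  }
  structure(list(counts = counts, support = support),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("consensus_matrix: %d circRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Multi-caller high-confidence circRNA filter
#'
#' A circRNA is retained iff (a) it was reported by at least `min_callers`
#' callers (anywhere, any sample), and (b) it shows at least `min_reads`
#' BSJ reads in at least `min_samples` samples. With
#' `reads_scope = "merged"` (default) condition (b) is evaluated on the
#' per-cell maximum over callers (any caller's evidence counts); with
#' `"per_caller"` it must hold within each of at least `min_callers`
#' individual callers.
#'
#' The retained set is monotone: adding a caller observation or incrementing
#' any count can only grow it. (Evaluating (b) on the median-merged
#' consensus counts would break this: a newly reporting low-count caller
#' drags the median down, so a circRNA could lose its high-confidence status
#' by being seen once more.)
#'
#' @param tensor output of [build_call_tensor()].
#' @param min_reads,min_samples,min_callers integer thresholds (>= 1);
#'   defaults 2 reads / 2 samples / 3 callers.
#' @param reads_scope `"merged"` or `"per_caller"` (see above).
#' @return sorted character vector of retained circ ids.
#' @export
high_confidence_filter <- function(tensor, min_reads = 2L, min_samples = 2L,
                                   min_callers = 3L,
                                   reads_scope = c("merged", "per_caller")) {
  reads_scope <- match.arg(reads_scope)
  if (min_reads < 1 || min_samples < 1 || min_callers < 1)
    stop("all thresholds must be >= 1")
  if (min_callers > dim(tensor)[3L])
    stop(sprintf("min_callers = %d exceeds the %d caller(s) present",
                 min_callers, dim(tensor)[3L]))
  reported <- apply(tensor > 0, c(1L, 3L), any)
  n_sup <- rowSums(reported)
  if (reads_scope == "merged") {
    cell_max <- apply(tensor, c(1L, 2L), max)
    ok_reads <- rowSums(cell_max >= min_reads) >= min_samples
  } else {
    per_caller_ok <- apply(tensor >= min_reads, c(1L, 3L), sum) >= min_samples
    ok_reads <- rowSums(per_caller_ok) >= min_callers
  }
  sort(dimnames(tensor)[[1L]][n_sup >= min_callers & ok_reads])
}

#' Read a circRNA annotation table
#'
#' Expects a TSV with header columns `chrom, start, end, strand, host_gene`
#' and optionally `external_id` (e.g. a circAtlas-style name). Coordinates
#' must be canonical 0-based half-open. Malformed lines raise a parse error
#' naming the line number.
#'
#' @param path TSV file path.
#' @return data.frame with a `circ_id` key column added.
#' @export
read_circ_annotation <- function(path) {
  ann <- read_tsv_table(path)
  need <- c("chrom", "start", "end", "strand", "host_gene")
  if (!all(need %in% names(ann)))
    stop("annotation file lacks column(s): ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  suppressWarnings({
    st <- as.numeric(ann$start); en <- as.numeric(ann$end)
  })
  bad <- which(is.na(st) | is.na(en) | st >= en |
                 !ann$strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop(sprintf("malformed annotation at line %d (1-based, after header)",
                 bad[1L]))
  ann$start <- st; ann$end <- en
  ann$circ_id <- circ_key(ann$chrom, ann$start, ann$end, ann$strand)
  ann
}

#' Genomic summaries of the consensus matrix
#'
#' Partitions consensus BSJ reads by chromosome and response group, and ranks
#' host genes by total consensus reads across their circRNAs. Loci absent
#' from the annotation are labeled `"novel"` and excluded from the gene
#' ranking.
#'
#' @param cm a [consensus_counts()] result.
#' @param annotation data.frame with `circ_id` and `host_gene` columns (see
#'   [read_circ_annotation()]); may have zero rows.
#' @param groups named character vector mapping sample id to response group.
#' @return list with `per_chromosome` (chrom x group read totals and circRNA
#'   counts), `host_gene_ranking` (host gene, total reads, n circRNAs;
#'   descending by reads) and `locus_table` (per-circ totals with host gene).
#' @export
summarize_genome <- function(cm, annotation, groups) {
  counts <- cm$counts
  if (!all(colnames(counts) %in% names(groups)))
    stop("groups must cover every sample in the consensus matrix")
  chrom <- sub(":.*$", "", rownames(counts))
  grp <- groups[colnames(counts)]
  per_group <- t(rowsum(t(counts), group = grp))  # circ x group
  per_chrom <- rowsum(per_group, group = chrom)
  per_chromosome <- data.frame(
    chrom = rep(rownames(per_chrom), ncol(per_chrom)),
    group = rep(colnames(per_chrom), each = nrow(per_chrom)),
    total_reads = as.vector(per_chrom),
    stringsAsFactors = FALSE)
  n_circ <- table(chrom)
  per_chromosome$n_circ <- as.integer(n_circ[per_chromosome$chrom])

  gene <- if (nrow(annotation) > 0)
    annotation$host_gene[match(rownames(counts), annotation$circ_id)]
  else rep(NA_character_, nrow(counts))
  gene[is.na(gene)] <- "novel"
  locus_table <- data.frame(circ_id = rownames(counts),
                            host_gene = gene,
                            total_reads = rowSums(counts),
                            stringsAsFactors = FALSE)
  known <- locus_table[locus_table$host_gene != "novel", , drop = FALSE]
  if (nrow(known) > 0) {
    ranking <- stats::aggregate(total_reads ~ host_gene, known, sum)
    ranking$n_circ <- as.integer(table(known$host_gene)[ranking$host_gene])
    ranking <- ranking[order(-ranking$total_reads), , drop = FALSE]
    rownames(ranking) <- NULL
  } else {
    ranking <- data.frame(host_gene = character(), total_reads = numeric(),
                          n_circ = integer(), stringsAsFactors = FALSE)
  }
  list(per_chromosome = per_chromosome, host_gene_ranking = ranking,
       locus_table = locus_table)
}
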