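#' Hierarchical clustering of samples for heatmap reporting
#'
#' Average-linkage agglomerative clustering of samples on the
#' `1 - Pearson correlation` distance of z-scored normalized expression,
#' the common default for expression heatmaps. Returns the leaf order and
#' merge heights so a heatmap can be drawn with any renderer.
#'
#' @param norm_expr normalized expression matrix (features x samples),
#'   z-scored per feature internally.
#' @param de_sets optional named list (per feature class) of `up` / `down`
#'   id vectors, summarised into per-class counts.
#' @return list: `hclust` (the sample dendrogram), `sample_order` (leaf
#'   order, left to right), `heights` (merge heights), `feature_order`
#'   (feature dendrogram leaf order when >= 2 features), `summary`
#'   (data.frame class, n_up, n_down; NULL without `de_sets`).
#' @export
cluster_and_report <- function(norm_expr, de_sets = NULL) {
  norm_expr <- as.matrix(norm_expr)
  if (ncol(norm_expr) < 2L) stop("need >= 2 samples to cluster")
  if (nrow(norm_expr) < 2L) stop("need >= 2 features to cluster")
  z <- zscore_rows(norm_expr)
  d <- stats::as.dist(1 - stats::cor(z))
  hc <- stats::hclust(d, method = "average")
  feat_order <- NULL
  keep <- apply(z, 1L, stats::sd) > 0
  if (sum(keep) >= 2L) {
    dz <- stats::as.dist(1 - stats::cor(t(z[keep, , drop = FALSE])))
    feat_order <- rownames(z)[keep][stats::hclust(dz, "average")$order]
  }
  summary <- NULL
  if (!is.null(de_sets))
    summary <- data.frame(
      class = names(de_sets),
      n_up = vapply(de_sets, function(s) length(s$up), integer(1)),
      n_down = vapply(de_sets, function(s) length(s$down), integer(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  list(hclust = hc, sample_order = colnames(norm_expr)[hc$order],
       heights = hc$height, feature_order = feat_order, summary = summary)
}

# Write retained circ keys as BED6.
write_retained_bed <- function(keys, path) {
  parts <- regmatches(keys, regexec("^(.*):(\\d+)-(\\d+):([+-])$", keys))
  df <- data.frame(chrom = vapply(parts, `[[`, "", 2L),
                   start = as.integer(vapply(parts, `[[`, "", 3L)),
                   end = as.integer(vapply(parts, `[[`, "", 4L)),
                   name = keys, score = 0L,
                   strand = vapply(parts, `[[`, "", 5L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$simulate)) {
    need <- c("calls", "fsj", "lnc", "mrna", "meta", "cerna_mirna",
              "mrna_mirna")
    paths <- config$inputs
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0)
      stop("pipeline config lacks input path(s): ",
           paste(miss, collapse = ", "))
    gone <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(gone) > 0)
      stop("input file(s) not found: ", paste(gone, collapse = ", "))
  }
  defaults <- list(
    consensus = list(min_reads = 2L, min_samples = 2L, min_callers = 3L,
                     reads_scope = "merged"),
    de = list(alpha = 0.1, lfc = 1.5, lfc_scale = "log2"),
    network = list(min_tools = 5L, keep = "positive", r_min = 0),
    risk = list(endpoint = "os", cutoff = "median"))
  for (st in names(defaults))
    config[[st]] <- utils::modifyList(defaults[[st]],
                                      config[[st]] %||% list())
  config
}

#' Run the full ceRNA analysis pipeline
#'
#' Executes consensus -> ratio -> differential expression (circRNA, lncRNA,
#' mRNA) -> ceRNA network -> survival risk from one configuration, writing
#' every artifact under `outdir` and recording it in a run manifest with an
#' md5 content hash. The configuration either names input files
#' (`inputs:` block) or requests synthetic data (`simulate:` block with
#' [sim_config()] arguments); all randomness flows from `config$seed`.
#'
#' A stage failure halts the run with the failing stage named; artifacts
#' written by earlier stages are retained.
#'
#' @param config a list (or path to a YAML file) with optional blocks
#'   `simulate` or `inputs`, stage parameter blocks `consensus`, `de`,
#'   `network`, `risk`, and a `seed`.
#' @param outdir output directory (created if needed).
#' @return list with the in-memory stage results (`consensus`, `ratios`,
#'   `de`, `network`, `risk`, `report`) and `manifest` (data.frame
#'   stage, artifact, md5, timestamp).
#' @export
run_pipeline <- function(config, outdir) {
  config <- validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(), artifact = character(),
                         md5 = character(), timestamp = character(),
                         stringsAsFactors = FALSE)
  note <- function(stage, path) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, artifact = path,
      md5 = unname(tools::md5sum(path)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- inputs -----------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    ds <- run_stage("simulate", simulate_dataset(do.call(sim_config, sim_args)))
    calls <- ds$calls; fsj <- ds$fsj; lnc <- ds$lnc; mrna <- ds$mrna
    meta <- ds$meta; inter <- ds$interactions; annotation <- ds$annotation
    annotation$circ_id <- circ_key(annotation$chrom, annotation$start,
                                   annotation$end, annotation$strand)
    p <- file.path(outdir, "simulated_truth.tsv")
    write_tsv_table(ds$truth$de_features, p); note("simulate", p)
    offset_profile <- ds$config$caller_offset_profile
  } else {
    inp <- config$inputs
    calls <- read_tsv_table(inp$calls)
    fsj <- read_matrix_tsv(inp$fsj)
    lnc <- read_matrix_tsv(inp$lnc)
    mrna <- read_matrix_tsv(inp$mrna)
    meta <- read_tsv_table(inp$meta)
    inter <- list(cerna_mirna = read_tsv_table(inp$cerna_mirna),
                  mrna_mirna = read_tsv_table(inp$mrna_mirna))
    annotation <- if (!is.null(inp$annotation))
      read_circ_annotation(inp$annotation)
    else data.frame(circ_id = character(), host_gene = character())
    offset_profile <- if (!is.null(config$offset_profile))
      lapply(config$offset_profile, as.integer)
    else default_offset_profiles()
  }
  groups <- stats::setNames(meta$response, meta$sample_id)
  sf <- estimate_size_factors(stats::setNames(
    meta$total_linear_mapped_reads, meta$sample_id))

  # -- consensus --------------------------------------------------------------
  cons <- run_stage("consensus", {
    harm <- harmonize_calls(calls, offset_profile)
    tens <- build_call_tensor(harm, samples = meta$sample_id)
    retained <- do.call(high_confidence_filter,
                        c(list(tensor = tens), config$consensus))
    cm <- consensus_counts(tens)
    cm$counts <- cm$counts[retained, , drop = FALSE]
    cm$support <- cm$support[retained]
    summaries <- summarize_genome(cm, annotation, groups)
    list(tensor = tens, retained = retained, cm = cm, summaries = summaries)
  })
  p <- file.path(outdir, "consensus_matrix.tsv")
  write_matrix_tsv(cons$cm$counts, p); note("consensus", p)
  p <- file.path(outdir, "retained_circ.bed")
  write_retained_bed(cons$retained, p); note("consensus", p)
  p <- file.path(outdir, "per_chromosome_summary.tsv")
  write_tsv_table(cons$summaries$per_chromosome, p); note("consensus", p)
  p <- file.path(outdir, "host_gene_ranking.tsv")
  write_tsv_table(cons$summaries$host_gene_ranking, p); note("consensus", p)

  # -- ratio ------------------------------------------------------------------
  ratios <- run_stage("ratio", {
    suppressMessages(ratio_table(cons$cm, fsj, by = "group",
                                 groups = groups))
  })
  p <- file.path(outdir, "circular_linear_ratio.tsv")
  write_tsv_table(ratios, p); note("ratio", p)

  # -- differential expression ------------------------------------------------
  de <- run_stage("de", {
    lapply(list(circ = cons$cm$counts, lnc = lnc, mrna = mrna),
           function(m) do.call(de_analysis,
                               c(list(counts = m, group = groups[colnames(m)],
                                      size_factors = sf[colnames(m)]),
                                 config$de)))
  })
  for (cls in names(de)) {
    p <- file.path(outdir, sprintf("de_%s.tsv", cls))
    write_tsv_table(de[[cls]]$results, p); note("de", p)
  }

  # -- ceRNA network ----------------------------------------------------------
  network <- run_stage("network", {
    de_cerna <- c(de$circ$up, de$circ$down, de$lnc$up, de$lnc$down)
    de_mrna <- c(de$mrna$up, de$mrna$down)
    filt <- consensus_mrna_mirna(inter$mrna_mirna,
                                 min_tools = config$network$min_tools)
    mirnas <- select_network_mirnas(inter$cerna_mirna, de_cerna)
    edges <- assemble_cerna_network(de_cerna, de_mrna, filt,
                                    inter$cerna_mirna, mirnas)
    cerna_expr <- rbind(normalize_log2(cons$cm$counts, sf[colnames(cons$cm$counts)]),
                        normalize_log2(lnc, sf[colnames(lnc)]))
    edges <- suppressMessages(correlate_edges(
      edges, cerna_expr, normalize_log2(mrna, sf[colnames(mrna)]),
      keep = config$network$keep, r_min = config$network$r_min))
    list(edges = edges, mirnas = mirnas, de_cerna = de_cerna,
         de_mrna = de_mrna)
  })
  p <- file.path(outdir, "cerna_edges.tsv")
  write_tsv_table(network$edges, p); note("network", p)
  if (nrow(network$edges) > 0) {
    p <- file.path(outdir, "cerna_network.graphml")
    cerna_network_graph(network$edges, p); note("network", p)
  }

  # -- survival risk ----------------------------------------------------------
  risk <- run_stage("risk", {
    sig_circ <- cons$cm$counts[rownames(cons$cm$counts) %in%
                                 c(de$circ$up, de$circ$down), , drop = FALSE]
    sig_lnc <- lnc[rownames(lnc) %in% c(de$lnc$up, de$lnc$down), ,
                   drop = FALSE]
    sig <- rbind(sig_circ, sig_lnc[, colnames(sig_circ), drop = FALSE])
    if (nrow(sig) < 1L) stop("empty DE ceRNA signature")
    suppressWarnings(build_risk_model(sig, sf, meta,
                                      endpoint = config$risk$endpoint,
                                      cutoff = config$risk$cutoff))
  })
  p <- file.path(outdir, "risk_coefficients.tsv")
  write_tsv_table(risk$coefficients, p); note("risk", p)
  p <- file.path(outdir, "risk_scores.tsv")
  write_tsv_table(data.frame(sample_id = names(risk$scores),
                             risk_score = unname(risk$scores),
                             group = unname(risk$group[names(risk$scores)])),
                  p); note("risk", p)
  p <- file.path(outdir, "km_curves.tsv")
  write_tsv_table(rbind(cbind(endpoint = "os", risk$os$km$curves),
                        cbind(endpoint = "pfs", risk$pfs$km$curves)),
                  p); note("risk", p)
  p <- file.path(outdir, "survival_summary.tsv")
  write_tsv_table(data.frame(
    endpoint = c("os", "pfs"),
    logrank_chisq = c(risk$os$logrank$statistic, risk$pfs$logrank$statistic),
    logrank_p = c(risk$os$logrank$p, risk$pfs$logrank$p)), p)
  note("risk", p)

  # -- report -----------------------------------------------------------------
  report <- run_stage("report", {
    sig_norm <- risk$normalized
    de_sets <- lapply(de, function(x) list(up = x$up, down = x$down))
    if (nrow(sig_norm) >= 2L) cluster_and_report(sig_norm, de_sets)
    else list(summary = data.frame(
      class = names(de_sets),
      n_up = vapply(de_sets, function(s) length(s$up), integer(1)),
      n_down = vapply(de_sets, function(s) length(s$down), integer(1))))
  })
  if (!is.null(report$summary)) {
    p <- file.path(outdir, "de_summary.tsv")
    write_tsv_table(report$summary, p); note("report", p)
  }
  p <- file.path(outdir, "manifest.tsv")
  write_tsv_table(manifest, p)

  list(consensus = cons, ratios = ratios, de = de, network = network,
       risk = risk, report = report, manifest = manifest, config = config)
}
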