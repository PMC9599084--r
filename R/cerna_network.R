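#' Prediction-tool consensus filter for mRNA-miRNA interactions
#'
#' miRNA-target predictions for mRNAs aggregate up to seven tools; to limit
#' false positives, only interactions supported by at least `min_tools`
#' distinct tools are kept as miRNA-mRNA pairs.
#'
#' @param records data.frame with columns `source_id` (mRNA), `mirna_id`
#'   and `support` (integer count of predicting tools).
#' @param min_tools support threshold (default 5).
#' @param n_tools number of configured tools (default 7).
#' @return the rows of `records` with `support >= min_tools`.
#' @export
consensus_mrna_mirna <- function(records, min_tools = 5L, n_tools = 7L) {
  if (!all(c("source_id", "mirna_id", "support") %in% names(records)))
    stop("records must have columns source_id, mirna_id, support")
  if (min_tools > n_tools)
    stop(sprintf("min_tools = %d exceeds the %d configured tools",
                 min_tools, n_tools))
  out <- records[records$support >= min_tools, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNAs interacting with differentially expressed ceRNAs
#'
#' The miRNA layer of the network is restricted to miRNAs that interact with
#' at least one differentially expressed circRNA or lncRNA.
#'
#' @param cerna_records data.frame with `source_id` (circRNA or lncRNA id)
#'   and `mirna_id`; may combine both classes.
#' @param de_cerna_ids character vector of DE ceRNA ids.
#' @return sorted character vector of miRNA ids.
#' @export
select_network_mirnas <- function(cerna_records, de_cerna_ids) {
  sort(unique(cerna_records$mirna_id[cerna_records$source_id %in%
                                       de_cerna_ids]))
}

#' Assemble the ceRNA-miRNA-mRNA network
#'
#' An edge (ceRNA, mRNA) exists iff some miRNA `m` (i) belongs to the
#' selected miRNA set, (ii) targets the DE ceRNA, and (iii) survived the
#' tool-consensus filter as a partner of the DE mRNA. `shared_mirnas` lists
#' every such `m`. ceRNAs with no miRNA interaction are absent from the
#' network.
#'
#' @param de_cerna_ids,de_mrna_ids DE feature ids from the expression
#'   analyses.
#' @param mrna_records tool-filtered mRNA-miRNA records (see
#'   [consensus_mrna_mirna()]).
#' @param cerna_records ceRNA-miRNA records (circRNA and lncRNA layers).
#' @param mirna_set miRNA ids from [select_network_mirnas()].
#' @return data.frame `cerna_id, mrna_id, shared_mirnas` (`;`-joined,
#'   sorted), `n_shared`; rows ordered by (cerna_id, mrna_id).
#' @export
assemble_cerna_network <- function(de_cerna_ids, de_mrna_ids, mrna_records,
                                   cerna_records, mirna_set) {
  c_rec <- cerna_records[cerna_records$source_id %in% de_cerna_ids &
                           cerna_records$mirna_id %in% mirna_set, ,
                         drop = FALSE]
  m_rec <- mrna_records[mrna_records$source_id %in% de_mrna_ids &
                          mrna_records$mirna_id %in% mirna_set, ,
                        drop = FALSE]
  empty <- data.frame(cerna_id = character(), mrna_id = character(),
                      shared_mirnas = character(), n_shared = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(c_rec) == 0L || nrow(m_rec) == 0L) return(empty)
  joined <- merge(unique(c_rec[, c("source_id", "mirna_id")]),
                  unique(m_rec[, c("source_id", "mirna_id")]),
                  by = "mirna_id", suffixes = c("_cerna", "_mrna"))
  if (nrow(joined) == 0L) return(empty)
  key <- paste(joined$source_id_cerna, joined$source_id_mrna, sep = "\r")
  shared <- tapply(joined$mirna_id, key,
                   function(m) paste(sort(unique(m)), collapse = ";"))
  parts <- do.call(rbind, strsplit(names(shared), "\r", fixed = TRUE))
  out <- data.frame(cerna_id = parts[, 1L], mrna_id = parts[, 2L],
                    shared_mirnas = unname(shared),
                    stringsAsFactors = FALSE)
  out$n_shared <- lengths(strsplit(out$shared_mirnas, ";", fixed = TRUE))
  out <- out[order(out$cerna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate network edges by expression correlation
#'
#' The ceRNA hypothesis predicts a *positive* correlation between a ceRNA
#' and the mRNAs whose repressing miRNAs it sponges. Each edge receives the
#' Pearson correlation (and its two-sided p-value) between the ceRNA's and
#' the mRNA's normalized expression across samples; with
#' `keep = "positive"` (default) edges with `r <= r_min` are removed.
#' Edges whose endpoints have zero expression variance cannot be
#' correlated and are dropped with a message.
#'
#' @param edges output of [assemble_cerna_network()].
#' @param cerna_expr,mrna_expr normalized expression matrices
#'   (`log2(size-factor-scaled count + 1)`, features x samples, identical
#'   sample order).
#' @param keep `"positive"` (drop edges with `r <= r_min`) or `"all"`.
#' @param r_min correlation threshold used when `keep = "positive"`.
#' @return `edges` with `pearson_r` and `pearson_p` columns appended.
#' @export
correlate_edges <- function(edges, cerna_expr, mrna_expr,
                            keep = c("positive", "all"), r_min = 0) {
  keep <- match.arg(keep)
  if (nrow(edges) == 0L) {
    edges$pearson_r <- numeric(0); edges$pearson_p <- numeric(0)
    return(edges)
  }
  if (!identical(colnames(cerna_expr), colnames(mrna_expr)))
    stop("expression matrices must share one sample order")
  if (ncol(cerna_expr) < 3L) stop("need >= 3 samples to correlate")
  miss_c <- setdiff(unique(edges$cerna_id), rownames(cerna_expr))
  miss_m <- setdiff(unique(edges$mrna_id), rownames(mrna_expr))
  if (length(miss_c) + length(miss_m) > 0)
    stop("expression missing for id(s): ",
         paste(c(miss_c, miss_m), collapse = ", "))
  r <- p <- rep(NA_real_, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    x <- cerna_expr[edges$cerna_id[i], ]
    y <- mrna_expr[edges$mrna_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- stats::cor.test(x, y, method = "pearson")
    r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  edges$pearson_r <- r
  edges$pearson_p <- p
  dropped <- is.na(r)
  if (any(dropped))
    message(sprintf("correlate_edges: dropped %d edge(s) with zero-variance expression",
                    sum(dropped)))
  edges <- edges[!dropped, , drop = FALSE]
  if (keep == "positive")
    edges <- edges[edges$pearson_r > r_min, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Export the ceRNA network
#'
#' Builds a bipartite igraph (ceRNA and mRNA nodes; shared miRNAs, counts
#' and correlations as edge attributes) and optionally writes it as GraphML
#' for network viewers.
#'
#' @param edges correlated edge table (see [correlate_edges()]).
#' @param path optional GraphML output path.
#' @return the igraph object, invisibly when `path` is given.
#' @export
cerna_network_graph <- function(edges, path = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("cerna_id", "mrna_id",
              intersect(c("shared_mirnas", "n_shared", "pearson_r",
                          "pearson_p"), names(edges)))],
    directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% edges$mrna_id
  igraph::V(g)$class <- ifelse(igraph::V(g)$type, "mRNA", "ceRNA")
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}
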