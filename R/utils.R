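#' Derive a reproducible substream seed from a master seed and a stage label
#'
#' Every stochastic stage of the package draws from its own substream so that
#' stages can be rerun independently and still reproduce byte-identical output.
#' The substream seed is a deterministic hash of the master seed and a short
#' stage label: `(seed * 48271 + h(label)) mod (2^31 - 1)`, where `h` is a
#' positional weighting of the label's UTF-8 code points.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the stage (e.g. `"cohort"`).
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L, nzchar(label))
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Evaluate `code` under a substream seed, restoring the caller's RNG state.
with_substream <- function(seed, label, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(substream_seed(seed, label))
  force(code)
}

#' Log2 normalized expression
#'
#' Divides counts by per-sample size factors and applies `log2(x + 1)`, the
#' transform used for correlation validation and for the risk-score
#' normalization.
#'
#' @param counts numeric matrix, features x samples.
#' @param size_factors positive numeric vector, one per sample (column).
#' @return matrix of the same shape.
#' @export
normalize_log2 <- function(counts, size_factors) {
  counts <- as.matrix(counts)
  if (length(size_factors) != ncol(counts))
    stop("size_factors must have one entry per sample column")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2L, size_factors, "/") + 1)
}

# Z-score rows of a matrix; rows with zero variance become all-zero.
zscore_rows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

# Stable string key for a circRNA locus on canonical coordinates.
circ_key <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "-", end, ":", strand)
}

# TSV helpers -----------------------------------------------------------------

#' Read / write tab-separated tables
#'
#' Thin wrappers over [utils::read.delim()] / [utils::write.table()] with the
#' conventions used by every artifact in this package: tab separator, header
#' row, no quoting, no row names (matrices are written with the feature id as
#' the first column, named `feature_id`).
#'
#' @param path file path.
#' @param x data.frame or matrix to write.
#' @return `read_tsv_table`: a data.frame. Writers return `path`, invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tsv_table
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname read_tsv_table
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
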