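#' Circular-to-linear transcript ratio
#'
#' For a locus with `bsj` back-splice junction reads (circular transcript)
#' and `fsj` forward-splice junction reads (linear transcript), the ratio is
#' `2 * bsj / (2 * bsj + fsj)`: each circular molecule contributes two
#' junction-spanning ends, so BSJ reads are doubled before comparing with
#' linear junction reads. The ratio lies in \[0, 1\] and equals 1 exactly
#' when the locus is transcribed only circularly (`fsj = 0`, `bsj > 0`).
#' When both counts are zero the ratio is undefined and `NA` is returned.
#'
#' @param bsj,fsj non-negative counts (vectorized, recycled).
#' @return numeric vector of ratios in \[0, 1\], `NA` where `bsj = fsj = 0`.
#' @export
circular_linear_ratio <- function(bsj, fsj) {
  if (any(bsj < 0, na.rm = TRUE) || any(fsj < 0, na.rm = TRUE))
    stop("bsj and fsj must be non-negative")
  denom <- 2 * bsj + fsj
  ifelse(denom == 0, NA_real_, 2 * bsj / denom)
}

#' Per-circRNA circular-to-linear ratio table
#'
#' Aggregates BSJ and FSJ reads over the requested scope *before* applying
#' the ratio formula (the ratio of pooled counts, not the mean of per-sample
#' ratios; set `by = "sample"` for per-sample values).
#'
#' @param cm a [consensus_counts()] result (or a plain BSJ count matrix).
#' @param fsj matrix of forward-splice junction counts, circ x sample.
#' @param by pooling scope: `"cohort"` (all samples), `"group"` (per
#'   response group; requires `groups`), or `"sample"`.
#' @param groups named character vector sample id -> group (for
#'   `by = "group"`).
#' @param circ_ids optional subset of circ ids (default: rows shared by both
#'   inputs; ids missing from either input are recorded in the `missing`
#'   attribute).
#' @return data.frame `circ_id, scope, bsj, fsj, ratio`; undefined ratios
#'   are `NA`. Attribute `missing` lists requested ids absent from an input.
#' @export
ratio_table <- function(cm, fsj, by = c("cohort", "group", "sample"),
                        groups = NULL, circ_ids = NULL) {
  by <- match.arg(by)
  bsj <- if (inherits(cm, "consensus_matrix")) cm$counts else as.matrix(cm)
  fsj <- as.matrix(fsj)
  if (is.null(circ_ids))
    circ_ids <- intersect(rownames(bsj), rownames(fsj))
  missing <- setdiff(circ_ids, intersect(rownames(bsj), rownames(fsj)))
  if (length(missing) > 0)
    message(sprintf("ratio_table: %d circ id(s) missing from an input",
                    length(missing)))
  circ_ids <- setdiff(circ_ids, missing)
  samples <- intersect(colnames(bsj), colnames(fsj))
  if (length(samples) == 0L) stop("scope contains zero samples")
  bsj <- bsj[circ_ids, samples, drop = FALSE]
  fsj <- fsj[circ_ids, samples, drop = FALSE]

  scope_of <- switch(by,
    cohort = rep("cohort", length(samples)),
    sample = samples,
    group = {
      if (is.null(groups)) stop("by = 'group' requires groups")
      unname(groups[samples])
    })
  b <- t(rowsum(t(bsj), group = scope_of))
  f <- t(rowsum(t(fsj), group = scope_of))
  out <- data.frame(
    circ_id = rep(circ_ids, ncol(b)),
    scope = rep(colnames(b), each = length(circ_ids)),
    bsj = as.vector(b), fsj = as.vector(f),
    stringsAsFactors = FALSE)
  out$ratio <- circular_linear_ratio(out$bsj, out$fsj)
  n_undef <- sum(is.na(out$ratio))
  if (n_undef > 0)
    message(sprintf("ratio_table: %d undefined ratio(s) (bsj = fsj = 0)",
                    n_undef))
  attr(out, "missing") <- missing
  out
}
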