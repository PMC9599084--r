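# Shared fixture generators and independent brute-force oracles.
# Oracles are deliberately naive (triple loops, enumeration) and never share
# code with the implementation they check.

# Random harmonized-call fixture as a circ x sample x caller tensor.
random_call_tensor <- function(n_circ = 50, n_samples = 12, n_callers = 5,
                               density = 0.3, max_reads = 6) {
  tens <- array(0, dim = c(n_circ, n_samples, n_callers),
                dimnames = list(circ_id = sprintf("c%03d", seq_len(n_circ)),
                                sample_id = sprintf("S%02d", seq_len(n_samples)),
                                caller_id = paste0("caller", seq_len(n_callers))))
  nz <- runif(length(tens)) < density
  tens[nz] <- sample.int(max_reads, sum(nz), replace = TRUE)
  tens
}

# Brute-force high-confidence filter: explicit loops over circ/sample/caller.
brute_filter <- function(tens, min_reads = 2, min_samples = 2,
                         min_callers = 3) {
  keep <- character(0)
  for (i in seq_len(dim(tens)[1])) {
    callers <- 0
    for (k in seq_len(dim(tens)[3])) {
      seen <- FALSE
      for (j in seq_len(dim(tens)[2])) if (tens[i, j, k] > 0) seen <- TRUE
      if (seen) callers <- callers + 1
    }
    if (callers < min_callers) next
    n_ok <- 0
    for (j in seq_len(dim(tens)[2])) {
      best <- 0
      for (k in seq_len(dim(tens)[3]))
        if (tens[i, j, k] > best) best <- tens[i, j, k]
      if (best >= min_reads) n_ok <- n_ok + 1
    }
    if (n_ok >= min_samples) keep <- c(keep, dimnames(tens)[[1]][i])
  }
  sort(keep)
}

# Brute-force consensus row: median over callers that reported circ i
# anywhere, rounded half to even.
brute_consensus_row <- function(tens, i) {
  sup <- c()
  for (k in seq_len(dim(tens)[3]))
    if (any(tens[i, , k] > 0)) sup <- c(sup, k)
  out <- numeric(dim(tens)[2])
  if (length(sup) == 0) return(out)
  for (j in seq_len(dim(tens)[2]))
    out[j] <- round(median(tens[i, j, sup]))
  out
}

# Brute-force Benjamini-Hochberg step-up: returns adjusted p-values.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    adj[o[k]] <- running
  }
  adj
}

# Brute-force ceRNA network: triple loop over (ceRNA record, mRNA record,
# miRNA identity).
brute_network <- function(de_cerna, de_mrna, mrna_rec, cerna_rec, mirnas) {
  edges <- list()
  for (a in seq_len(nrow(cerna_rec))) {
    if (!(cerna_rec$source_id[a] %in% de_cerna)) next
    if (!(cerna_rec$mirna_id[a] %in% mirnas)) next
    for (b in seq_len(nrow(mrna_rec))) {
      if (!(mrna_rec$source_id[b] %in% de_mrna)) next
      if (!(mrna_rec$mirna_id[b] %in% mirnas)) next
      if (cerna_rec$mirna_id[a] != mrna_rec$mirna_id[b]) next
      key <- paste(cerna_rec$source_id[a], mrna_rec$source_id[b])
      edges[[key]] <- sort(unique(c(edges[[key]], cerna_rec$mirna_id[a])))
    }
  }
  if (length(edges) == 0)
    return(data.frame(cerna_id = character(), mrna_id = character(),
                      shared_mirnas = character()))
  parts <- do.call(rbind, strsplit(names(edges), " ", fixed = TRUE))
  out <- data.frame(cerna_id = parts[, 1], mrna_id = parts[, 2],
                    shared_mirnas = vapply(edges, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cerna_id, out$mrna_id), ]
  rownames(out) <- NULL
  out
}

# Cox partial likelihood for a single covariate, no ties (Breslow = Efron
# when event times are distinct); used by the grid-search oracle.
cox_partial_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Brute-force two-group log-rank: observed minus expected over event times
# with the hypergeometric variance.
brute_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(statistic = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Naive average-linkage agglomeration on a distance matrix: returns the
# sorted merge heights.
brute_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- mean(d[clusters[[a]], clusters[[b]]])
      if (h < best[1]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# Tamper with a validated config (to exercise validation paths downstream).
unclass_replace <- function(cfg, ...) {
  mods <- list(...)
  for (n in names(mods)) cfg[[n]] <- mods[[n]]
  cfg
}
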