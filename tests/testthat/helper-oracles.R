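# Independent brute-force oracles. These deliberately re-derive the scoring
# statistics with explicit position-by-position loops, sharing no code with
# the package engines they check.

# ssGSEA: integrated weighted KS statistic for one sample and one set.
oracle_ssgsea_es <- function(expr_col, gene_ids, set_members, tau = 0.25) {
  N <- length(expr_col)
  r <- rank(expr_col, ties.method = "average")
  ord <- order(-r, seq_len(N))       # decreasing rank, gene-index tie-break
  in_set <- gene_ids %in% set_members
  m <- sum(in_set)
  denom_in <- 0
  for (i in seq_len(N)) if (in_set[ord[i]]) denom_in <- denom_in + r[ord[i]]^tau
  es <- 0; cin <- 0; cout <- 0
  for (i in seq_len(N)) {
    g <- ord[i]
    if (in_set[g]) cin <- cin + r[[g]]^tau / denom_in
    else cout <- cout + 1 / (N - m)
    es <- es + (cin - cout)
  }
  unname(es)
}

# GSVA: Gaussian kernel-CDF, symmetrized rank statistic, weighted KS walk.
oracle_gsva_es <- function(expr, set_members, gsva_tau = 1,
                           max_diff = TRUE) {
  N <- nrow(expr); n <- ncol(expr)
  z <- matrix(NA_real_, N, n)
  for (i in seq_len(N)) {
    h <- max(stats::sd(expr[i, ]) / 4, 1e-8)
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + stats::pnorm((expr[i, j] - expr[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  in_set <- rownames(expr) %in% set_members
  m <- sum(in_set)
  es <- numeric(n)
  for (j in seq_len(n)) {
    rnk <- rank(z[, j], ties.method = "average")
    s <- abs(rnk - (N + 1) / 2)^gsva_tau
    ord <- order(-z[, j], seq_len(N))
    denom <- sum(s[in_set])
    cin <- 0; cout <- 0; mx <- 0; mn <- 0
    for (i in seq_len(N)) {
      g <- ord[i]
      if (in_set[g]) cin <- cin + s[g] / denom
      else cout <- cout + 1 / (N - m)
      dev <- cin - cout
      if (dev > mx) mx <- dev
      if (dev < mn) mn <- dev
    }
    es[j] <- if (max_diff) mx + mn else if (mx >= -mn) mx else mn
  }
  es
}

# Mean silhouette width from first principles (pairwise distances).
oracle_mean_silhouette <- function(points, labels) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), 0))
    widths[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(widths)
}

# Random toy expression cohort (no structure).
random_toy <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Random gene-set collection over the toy universe.
random_sets <- function(gene_ids, n_sets, seed, min_m = 2L) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(gene_ids, sample(min_m:(length(gene_ids) - 1L), 1L)))
  gene_set_collection(stats::setNames(sets, sprintf("S%02d", seq_len(n_sets))))
}
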