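#' Enrichment scoring parameters
#'
#' @param method `"ssgsea"` (rank-weighted integrated statistic, the default
#'   used for subtyping) or `"gsva"` (kernel-CDF Kolmogorov-Smirnov variant,
#'   used for the replication-stress score).
#' @param tau ssGSEA rank-weight exponent (>= 0, default 0.25).
#' @param normalize Divide all enrichment scores by the global
#'   (max - min) over the whole score matrix, storing the extremes for later
#'   reuse at prediction time. Default `TRUE`.
#' @param gsva_max_diff GSVA: if `TRUE` (default) the enrichment score is the
#'   sum of the maximum positive and maximum negative deviations of the
#'   random walk; otherwise the maximum-magnitude deviation with its sign.
#' @param gsva_tau GSVA weight exponent (default 1).
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(method = c("ssgsea", "gsva"), tau = 0.25,
                              normalize = TRUE, gsva_max_diff = TRUE,
                              gsva_tau = 1) {
  method <- match.arg(method)
  stopifnot(tau >= 0, gsva_tau >= 0)
  structure(list(method = method, tau = tau, normalize = normalize,
                 gsva_max_diff = gsva_max_diff, gsva_tau = gsva_tau),
            class = "enrichment_params")
}

#' Construct a score matrix object
#'
#' Thin wrapper around a sets x samples numeric matrix that carries the
#' scoring parameters and the global min/max used for range normalization
#' (needed to score new cohorts on the training scale).
#'
#' @param scores Sets x samples numeric matrix (dimnames required).
#' @param params An `enrichment_params`.
#' @param norm_min,norm_max Global extremes of the unnormalized scores, or
#'   `NA` when `params$normalize` is `FALSE`.
#' @return A `score_matrix`.
#' @export
score_matrix <- function(scores, params, norm_min = NA_real_,
                         norm_max = NA_real_) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  structure(list(scores = scores, params = params,
                 norm_min = norm_min, norm_max = norm_max),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d sets x %d samples (%s%s)\n",
              nrow(x$scores), ncol(x$scores), x$params$method,
              if (isTRUE(x$params$normalize)) ", range-normalized" else ""))
  invisible(x)
}

#' Per-sample rank transform
#'
#' Ranks each column 1..N with N assigned to the highest expression; ties
#' receive average ranks. ssGSEA depends on expression only through these
#' ranks, so any strictly monotone per-sample transform of the input leaves
#' the scores unchanged.
#'
#' @param x Genes x samples numeric matrix.
#' @return Matrix of the same shape holding per-column ranks.
#' @export
rank_transform <- function(x) {
  x <- validate_expression(x, allow_dup_genes = TRUE)
  apply(x, 2L, rank, ties.method = "average")
}

# Membership indicator matrix (genes x sets), with overlap checks.
set_indicator <- function(gene_ids, c) {
  ind <- vapply(unclass(c), function(m) gene_ids %in% m,
                logical(length(gene_ids)))
  ind <- matrix(ind, nrow = length(gene_ids),
                dimnames = list(NULL, names(c)))
  m <- colSums(ind)
  if (any(m == 0L))
    stop("gene set(s) with no overlap in the expression matrix: ",
         paste(names(c)[m == 0L], collapse = ", "))
  if (any(m == length(gene_ids)))
    stop("gene set(s) covering the entire universe (out-of-set step ",
         "undefined): ", paste(names(c)[m == length(gene_ids)], collapse = ", "))
  ind
}

#' ssGSEA single-sample enrichment scores
#'
#' For each sample, genes are ordered by decreasing rank (ties broken by
#' ascending gene index). Walking down the ordered list, an in-set fraction
#' accumulates `rank^tau` mass (normalized by the total over set members)
#' while the out-of-set fraction steps `1/(N - |S|)`. The enrichment score
#' is the sum of (in - out) over all N positions: the integrated statistic,
#' not the maximum deviation. With `normalize = TRUE` all scores are divided
#' by the global `max - min` of the matrix and the extremes are stored.
#'
#' @param x Genes x samples expression matrix (no NAs; log-scale or
#'   normalized continuous values).
#' @param c A `gene_set_collection`; every set must share >= 1 gene with `x`
#'   and must not cover the whole universe.
#' @param p An `enrichment_params` with `method = "ssgsea"`.
#' @return A `score_matrix` (sets x samples).
#' @export
ssgsea_scores <- function(x, c, p = enrichment_params("ssgsea")) {
  stopifnot(inherits(p, "enrichment_params"), p$method == "ssgsea")
  x <- validate_expression(x, allow_dup_genes = TRUE)
  es <- ssgsea_es(x, c, tau = p$tau)
  if (isTRUE(p$normalize)) {
    nmin <- min(es); nmax <- max(es)
    if (nmax - nmin <= 0)
      stop("degenerate score range; cannot range-normalize")
    es <- es / (nmax - nmin)
    return(score_matrix(es, p, norm_min = nmin, norm_max = nmax))
  }
  score_matrix(es, p)
}

# Unnormalized ssGSEA enrichment scores, vectorized across sets per sample.
ssgsea_es <- function(x, c, tau = 0.25) {
  n_genes <- nrow(x)
  ind <- set_indicator(rownames(x), c)
  m <- colSums(ind)
  R <- apply(x, 2L, rank, ties.method = "average")
  es <- matrix(NA_real_, length(c), ncol(x),
               dimnames = list(names(c), colnames(x)))
  out_step <- 1 / (n_genes - m)             # per set
  for (j in seq_len(ncol(x))) {
    ord <- order(-R[, j], seq_len(n_genes)) # decreasing rank, index tie-break
    w <- R[ord, j]^tau
    io <- ind[ord, , drop = FALSE]
    win <- w * io                           # genes x sets
    cin <- apply(win, 2L, cumsum)
    cin <- sweep(cin, 2L, colSums(win), "/")
    cout <- apply((!io) * rep(out_step, each = n_genes), 2L, cumsum)
    es[, j] <- colSums(cin - cout)
  }
  es
}

#' GSVA kernel-CDF enrichment scores
#'
#' Per gene, a Gaussian-kernel cumulative density is estimated across
#' samples (bandwidth = per-gene SD / 4, floored at 1e-8 for zero-variance
#' genes). The resulting gene-level statistics are ranked within each sample
#' and symmetrized about the middle rank; a weighted Kolmogorov-Smirnov
#' random walk down the decreasing-statistic ordering yields the enrichment
#' score: max positive + max negative deviation when `gsva_max_diff`, else
#' the largest-magnitude deviation with its sign.
#'
#' @inheritParams ssgsea_scores
#' @param p An `enrichment_params` with `method = "gsva"`. Range
#'   normalization is not applied to GSVA scores (they are already bounded).
#' @return A `score_matrix` (sets x samples).
#' @export
gsva_scores <- function(x, c, p = enrichment_params("gsva")) {
  stopifnot(inherits(p, "enrichment_params"), p$method == "gsva")
  x <- validate_expression(x, allow_dup_genes = TRUE)
  if (ncol(x) < 4L)
    stop("GSVA requires >= 4 samples for the kernel density estimate")
  n_genes <- nrow(x); n_samp <- ncol(x)
  ind <- set_indicator(rownames(x), c)
  m <- colSums(ind)

  # kernel CDF per gene across samples
  bw <- pmax(apply(x, 1L, stats::sd) / 4, 1e-8)
  z <- matrix(NA_real_, n_genes, n_samp)
  for (i in seq_len(n_genes)) {
    xi <- x[i, ]
    z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / bw[i]))
  }

  es <- matrix(NA_real_, length(c), n_samp,
               dimnames = list(names(c), colnames(x)))
  mid <- (n_genes + 1) / 2
  for (j in seq_len(n_samp)) {
    r <- rank(z[, j], ties.method = "average")
    s <- abs(r - mid)^p$gsva_tau
    ord <- order(-z[, j], seq_len(n_genes))
    so <- s[ord]
    io <- ind[ord, , drop = FALSE]
    win <- so * io
    cin <- apply(win, 2L, cumsum)
    cin <- sweep(cin, 2L, colSums(win), "/")
    cout <- apply((!io) * rep(1 / (n_genes - m), each = n_genes), 2L, cumsum)
    dev <- cin - cout
    for (k in seq_along(c)) {
      mx <- max(dev[, k], 0); mn <- min(dev[, k], 0)
      es[k, j] <- if (isTRUE(p$gsva_max_diff)) mx + mn
                  else if (mx >= -mn) mx else mn
    }
  }
  score_matrix(es, p)
}

#' Score new samples on a stored training range
#'
#' Computes unnormalized ssGSEA scores for new samples and divides them by
#' the training extremes (`norm_max - norm_min`) captured during class
#' discovery, so that new cohorts land on the same scale as the training
#' score matrix. Values outside the training range are permitted.
#'
#' @inheritParams ssgsea_scores
#' @param norm_min,norm_max Stored global extremes from the training phase.
#' @return A `score_matrix` with the stored extremes attached.
#' @export
score_with_stored_range <- function(x, c, p = enrichment_params("ssgsea"),
                                    norm_min, norm_max) {
  if (!is.finite(norm_min) || !is.finite(norm_max) || norm_max <= norm_min)
    stop("degenerate stored range: norm_max must exceed norm_min")
  es <- ssgsea_es(x, c, tau = p$tau) / (norm_max - norm_min)
  p$normalize <- TRUE
  score_matrix(es, p, norm_min = norm_min, norm_max = norm_max)
}

#' Write/read a score matrix as TSV + JSON sidecar
#'
#' @param s A `score_matrix`. @param path TSV output path; parameters and
#'   stored extremes go to `<path>.json`.
#' @export
write_scores <- function(s, path) {
  df <- data.frame(set_name = rownames(s$scores), s$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(params = unclass(s$params), norm_min = s$norm_min,
         norm_max = s$norm_max),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- do.call(enrichment_params, meta$params[c("method", "tau", "normalize",
                                                "gsva_max_diff", "gsva_tau")])
  score_matrix(m, p,
               norm_min = if (is.null(meta$norm_min)) NA_real_ else meta$norm_min,
               norm_max = if (is.null(meta$norm_max)) NA_real_ else meta$norm_max)
}
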