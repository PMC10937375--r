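#' Configuration for unsupervised class discovery
#'
#' @param k_grid Candidate cluster counts (all >= 2; default 2..8).
#' @param perplexity t-SNE perplexity. `NULL` (default) uses 30 clipped to
#'   the admissible bound `(n - 1) / 3`; an explicit value violating the
#'   bound is an error.
#' @param seed Integer seed; mandatory for reproducibility and recorded in
#'   the result.
#' @param n_bootstrap Bootstrap resamples for cluster-stability assessment
#'   (default 100).
#' @param stability_floor Mean cluster-wise Jaccard below which a k is
#'   considered unstable (default 0.75, the conventional "stable" floor).
#' @param scale_embedding Standardize each embedding dimension to mean 0,
#'   variance 1 before clustering (default `TRUE`).
#' @param max_iter t-SNE iterations (default 1000).
#' @param nstart k-means restarts (default 25).
#' @param boot_nstart k-means restarts inside the bootstrap loop (default
#'   10; kept lower than `nstart` purely for runtime).
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(k_grid = 2:8, perplexity = NULL, seed = 1L,
                             n_bootstrap = 100L, stability_floor = 0.75,
                             scale_embedding = TRUE, max_iter = 1000L,
                             nstart = 25L, boot_nstart = 10L) {
  stopifnot(min(k_grid) >= 2L, stability_floor > 0, stability_floor < 1)
  structure(list(k_grid = as.integer(k_grid), perplexity = perplexity,
                 seed = as.integer(seed), n_bootstrap = as.integer(n_bootstrap),
                 stability_floor = stability_floor,
                 scale_embedding = scale_embedding,
                 max_iter = as.integer(max_iter), nstart = as.integer(nstart),
                 boot_nstart = as.integer(boot_nstart)),
            class = "discovery_config")
}

#' Embed a score matrix in two dimensions (t-SNE)
#'
#' Runs t-SNE on samples (rows = samples, features = gene-set scores) and
#' optionally standardizes the two output dimensions, which are then used
#' for k-means clustering. Deterministic for a fixed seed.
#'
#' @param s A `score_matrix` (sets x samples) or a plain sets x samples
#'   matrix.
#' @param cfg A `discovery_config`.
#' @return Samples x 2 coordinate matrix (rownames = sample ids).
#' @export
embed_scores <- function(s, cfg = discovery_config()) {
  m <- if (inherits(s, "score_matrix")) s$scores else s
  n <- ncol(m)
  if (n < 10L) stop("embedding requires >= 10 samples, got ", n)
  bound <- (n - 1) / 3
  perp <- cfg$perplexity
  if (is.null(perp)) {
    perp <- min(30, floor(bound) - 1e-9)
  } else if (perp >= bound) {
    stop(sprintf("perplexity must be < (n - 1)/3 = %.2f", bound))
  }
  set.seed(cfg$seed)
  fit <- Rtsne::Rtsne(t(m), dims = 2L, perplexity = perp,
                      max_iter = cfg$max_iter, check_duplicates = FALSE,
                      pca = TRUE, verbose = FALSE)
  emb <- fit$Y
  if (isTRUE(cfg$scale_embedding)) emb <- scale(emb)
  rownames(emb) <- colnames(m)
  colnames(emb) <- c("Dim1", "Dim2")
  emb[, , drop = FALSE]
}

#' k-means clustering with canonicalized labels
#'
#' Multiple random restarts keep the solution with the lowest within-cluster
#' sum of squares; labels are renumbered so cluster 1 is the largest.
#'
#' @param embedding Samples x d numeric matrix.
#' @param k Number of clusters (k = 1 is admitted for diagnostics).
#' @param seed Integer seed.
#' @param nstart Restarts (default 25).
#' @return Integer labels in 1..k with attribute `tot_withinss`.
#' @export
kmeans_cluster <- function(embedding, k, seed = 1L, nstart = 25L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k > n) stop("k exceeds the number of samples")
  if (k == 1L) {
    labs <- rep(1L, n)
    attr(labs, "tot_withinss") <- sum(scale(embedding, scale = FALSE)^2)
    return(labs)
  }
  if (nrow(unique(embedding)) < k)
    stop("fewer distinct points than clusters requested")
  set.seed(seed)
  fit <- NULL
  for (attempt in 1:5) {
    fit <- tryCatch(
      stats::kmeans(embedding, centers = k, nstart = nstart, iter.max = 100L),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("k-means failed after 5 restart rounds")
  labs <- canonicalize_labels(fit$cluster)
  attr(labs, "tot_withinss") <- fit$tot.withinss
  labs
}

# Mean cluster-wise bootstrap Jaccard stability for a given k.
bootstrap_jaccard <- function(embedding, k, seed, B = 100L, nstart = 10L) {
  n <- nrow(embedding)
  base <- kmeans_cluster(embedding, k, seed = seed, nstart = nstart)
  orig <- split(seq_len(n), base)
  set.seed(seed + 7L)
  jacc <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- embedding[idx, , drop = FALSE]
    labs_b <- tryCatch(
      kmeans_cluster(sub, k, seed = seed + b, nstart = nstart),
      error = function(e) NULL)
    if (is.null(labs_b)) next
    present <- unique(idx)
    boot_cl <- lapply(split(idx, labs_b), unique)
    for (cl in seq_len(k)) {
      a <- intersect(orig[[cl]], present)
      if (length(a) == 0L) next
      jacc[b, cl] <- max(vapply(boot_cl, function(bset)
        length(intersect(a, bset)) / length(union(a, bset)), 0))
    }
  }
  mean(jacc, na.rm = TRUE)
}

#' Select the number of clusters
#'
#' For every k in the grid computes the mean silhouette width, the
#' within-cluster sum of squares (elbow curve), and the mean cluster-wise
#' bootstrap Jaccard stability. The chosen k maximizes silhouette among k
#' whose stability reaches `stability_floor`; if none qualifies, the overall
#' silhouette argmax is returned with `low_stability = TRUE`.
#'
#' @param embedding Samples x d matrix (typically the scaled 2-D embedding).
#' @param cfg A `discovery_config`.
#' @return List: `chosen_k`, `silhouette_by_k`, `wss_by_k`,
#'   `jaccard_stability_by_k`, `low_stability`.
#' @export
select_k <- function(embedding, cfg = discovery_config()) {
  ks <- cfg$k_grid
  if (max(ks) > nrow(embedding)) stop("k_grid exceeds the number of samples")
  d <- stats::dist(embedding)
  sil <- wss <- stab <- stats::setNames(rep(NA_real_, length(ks)),
                                        as.character(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    labs <- kmeans_cluster(embedding, k, seed = cfg$seed, nstart = cfg$nstart)
    wss[i] <- attr(labs, "tot_withinss")
    sil[i] <- mean(cluster::silhouette(as.integer(labs), d)[, "sil_width"])
    stab[i] <- bootstrap_jaccard(embedding, k, seed = cfg$seed,
                                 B = cfg$n_bootstrap,
                                 nstart = cfg$boot_nstart)
  }
  stable <- which(stab >= cfg$stability_floor)
  if (length(stable)) {
    chosen <- ks[stable[which.max(sil[stable])]]
    low <- FALSE
  } else {
    chosen <- ks[which.max(sil)]
    low <- TRUE
    warning("no k reached the stability floor; falling back to the ",
            "silhouette argmax")
  }
  list(chosen_k = as.integer(chosen), silhouette_by_k = sil, wss_by_k = wss,
       jaccard_stability_by_k = stab, low_stability = low)
}

#' End-to-end pathway-level class discovery
#'
#' Filters the gene-set collection against the expression universe
#' (min_size 10), computes range-normalized ssGSEA scores, embeds samples in
#' two dimensions, selects k by silhouette/elbow/bootstrap stability, and
#' clusters at the chosen k. Clustering operates on the scaled 2-D embedding;
#' set `cluster_on_scores = TRUE` to cluster the full score matrix instead
#' (sensitivity analysis, non-default).
#'
#' @param x Genes x samples expression matrix.
#' @param c A `gene_set_collection`.
#' @param cfg A `discovery_config`.
#' @param min_size Minimum surviving set size (default 10).
#' @param tau ssGSEA weight exponent (default 0.25).
#' @param cluster_on_scores Cluster the score matrix rather than the
#'   embedding.
#' @return A `discovery_result` list: `embedding`, `labels`, `chosen_k`,
#'   per-k diagnostics, `scores` (the training `score_matrix`), `seed`,
#'   `low_stability`.
#' @export
discover <- function(x, c, cfg = discovery_config(), min_size = 10L,
                     tau = 0.25, cluster_on_scores = FALSE) {
  csets <- filter_sets(c, x, min_size = min_size)
  sc <- ssgsea_scores(x, csets, enrichment_params("ssgsea", tau = tau,
                                                  normalize = TRUE))
  emb <- embed_scores(sc, cfg)
  space <- if (cluster_on_scores) t(sc$scores) else emb
  sel <- select_k(space, cfg)
  labels <- kmeans_cluster(space, sel$chosen_k, seed = cfg$seed,
                           nstart = cfg$nstart)
  structure(list(embedding = emb, labels = as.integer(labels),
                 chosen_k = sel$chosen_k,
                 silhouette_by_k = sel$silhouette_by_k,
                 wss_by_k = sel$wss_by_k,
                 jaccard_stability_by_k = sel$jaccard_stability_by_k,
                 low_stability = sel$low_stability,
                 scores = sc, seed = cfg$seed),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("discovery_result: %d samples, chosen k = %d (%s)\n",
              nrow(x$embedding), x$chosen_k,
              if (x$low_stability) "LOW stability" else "stable"))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Serialize / load a discovery result (JSON + TSV embedding)
#'
#' @param r A `discovery_result`. @param path Basename; writes
#'   `<path>.json` and `<path>.embedding.tsv`.
#' @export
write_discovery <- function(r, path) {
  jsonlite::write_json(
    list(labels = r$labels, chosen_k = r$chosen_k,
         silhouette_by_k = as.list(r$silhouette_by_k),
         wss_by_k = as.list(r$wss_by_k),
         jaccard_stability_by_k = as.list(r$jaccard_stability_by_k),
         low_stability = r$low_stability, seed = r$seed,
         sample_ids = rownames(r$embedding)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(sample_id = rownames(r$embedding), r$embedding),
    paste0(path, ".embedding.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
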