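make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
}

test_that("embedding is deterministic, standardized, and bound-checked", {
  set.seed(20)
  m <- matrix(rnorm(15 * 40), 15, 40,
              dimnames = list(sprintf("S%02d", 1:15), sprintf("s%02d", 1:40)))
  cfg <- discovery_config(seed = 4)
  e1 <- embed_scores(m, cfg)
  e2 <- embed_scores(m, cfg)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(40L, 2L))
  expect_equal(apply(e1, 2, var), c(Dim1 = 1, Dim2 = 1), tolerance = 1e-9)
  expect_equal(colMeans(e1), c(Dim1 = 0, Dim2 = 0), tolerance = 1e-9)

  expect_error(embed_scores(m, discovery_config(seed = 1, perplexity = 20)),
               "perplexity")
  expect_error(embed_scores(m[, 1:8], cfg), ">= 10 samples")
})

test_that("embedding separates well-separated score blobs", {
  set.seed(21)
  m <- cbind(matrix(rnorm(10 * 20, 0), 10, 20),
             matrix(rnorm(10 * 20, 10), 10, 20))
  dimnames(m) <- list(sprintf("S%02d", 1:10), sprintf("s%02d", 1:40))
  e <- embed_scores(m, discovery_config(seed = 5))
  grp <- rep(1:2, each = 20)
  centd <- sqrt(sum((colMeans(e[grp == 1, ]) - colMeans(e[grp == 2, ]))^2))
  within95 <- max(vapply(1:2, function(g) {
    pts <- e[grp == g, ]
    stats::quantile(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2)), 0.95)
  }, 0))
  expect_gt(centd, within95)
})

test_that("k-means recovers planted blobs and canonicalizes labels", {
  emb <- make_blobs(c(30), matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE),
                    seed = 6)
  truth <- rep(1:3, each = 30)
  labs <- kmeans_cluster(emb, 3, seed = 2)
  expect_gte(adjusted_rand_index(labs, truth), 0.99)
  expect_setequal(unique(labs), 1:3)
  # largest cluster is labeled 1
  unb <- make_blobs(10, matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE), seed = 7)
  unb <- rbind(unb, make_blobs(25, matrix(c(0, 10), 1, 2), seed = 8))
  l2 <- kmeans_cluster(unb, 3, seed = 3)
  expect_identical(which.max(tabulate(l2)), 1L)

  expect_identical(unique(kmeans_cluster(emb, 1, seed = 1)), 1L)
  dup <- matrix(1, 10, 2)
  expect_error(kmeans_cluster(dup, 2, seed = 1), "distinct")
})

test_that("silhouette inside select_k matches a brute-force implementation", {
  emb <- make_blobs(10, matrix(c(0, 0, 6, 0), 2, 2, byrow = TRUE), seed = 9)
  cfg <- discovery_config(k_grid = 2:3, seed = 3, n_bootstrap = 10)
  sel <- select_k(emb, cfg)
  for (k in 2:3) {
    labs <- kmeans_cluster(emb, k, seed = cfg$seed, nstart = cfg$nstart)
    expect_equal(sel$silhouette_by_k[[as.character(k)]],
                 oracle_mean_silhouette(emb, as.integer(labs)),
                 tolerance = 1e-12)
  }
})

test_that("select_k picks the planted k and flags unstable structure", {
  emb3 <- make_blobs(25, matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE),
                     seed = 10)
  sel3 <- select_k(emb3, discovery_config(k_grid = 2:5, seed = 2,
                                          n_bootstrap = 40))
  expect_identical(sel3$chosen_k, 3L)
  expect_false(sel3$low_stability)

  emb2 <- make_blobs(30, matrix(c(0, 0, 10, 0), 2, 2, byrow = TRUE),
                     seed = 11)
  sel2 <- select_k(emb2, discovery_config(k_grid = 2:4, seed = 2,
                                          n_bootstrap = 40))
  expect_gt(sel2$silhouette_by_k[["2"]], sel2$silhouette_by_k[["3"]])

  # null data: k >= 3 lacks bootstrap stability
  set.seed(42)
  null_emb <- matrix(rnorm(200), 100, 2)
  seln <- select_k(null_emb, discovery_config(k_grid = 2:5, seed = 2,
                                              n_bootstrap = 40))
  expect_true(all(seln$jaccard_stability_by_k[c("3", "4", "5")] < 0.75))

  # unreachable floor on null data exercises the fallback-with-warning path
  expect_warning(
    self <- select_k(null_emb, discovery_config(k_grid = 2:4, seed = 2,
                                                n_bootstrap = 10,
                                                stability_floor = 0.99)),
    "stability")
  expect_true(self$low_stability)
  expect_identical(self$chosen_k,
                   as.integer(names(which.max(self$silhouette_by_k))))
})

test_that("discover runs end-to-end, deterministically, on generated cohorts", {
  sim <- simulate_cohort(n_samples = 60, n_genes = 600, n_sets = 15,
                         set_size = 20, seed = 14)
  cfg <- discovery_config(k_grid = 2:4, seed = 14, n_bootstrap = 25)
  res <- discover(sim$expr, sim$sets, cfg)
  expect_identical(res$chosen_k, 3L)
  expect_gte(adjusted_rand_index(res$labels, sim$truth$labels), 0.9)
  expect_identical(sort(names(res$silhouette_by_k)), c("2", "3", "4"))

  res2 <- discover(sim$expr, sim$sets, cfg)
  expect_equal(res, res2)

  tiny <- simulate_cohort(n_samples = 8, n_genes = 300, n_sets = 6,
                          set_size = 15, seed = 1)
  expect_error(discover(tiny$expr, tiny$sets, cfg), ">= 10 samples")
})

test_that("discovery results serialize to JSON + TSV", {
  sim <- simulate_cohort(n_samples = 40, n_genes = 400, n_sets = 10,
                         set_size = 20, seed = 15)
  res <- discover(sim$expr, sim$sets,
                  discovery_config(k_grid = 2:3, seed = 15, n_bootstrap = 10))
  base <- withr::local_tempfile()
  write_discovery(res, base)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_identical(meta$chosen_k, res$chosen_k)
  expect_identical(meta$labels, res$labels)
  emb <- utils::read.table(paste0(base, ".embedding.tsv"), header = TRUE)
  expect_identical(nrow(emb), nrow(res$embedding))
})
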