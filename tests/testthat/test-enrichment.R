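toy5 <- matrix(c(5, 4, 3, 2, 1), ncol = 1,
               dimnames = list(paste0("g", 1:5), "s1"))
unnorm <- enrichment_params("ssgsea", normalize = FALSE)

test_that("rank transform is column-wise with average ties", {
  x <- matrix(c(5, 4, 3, 2, 1,
                7, 7, 1, 2, 3), ncol = 2,
              dimnames = list(paste0("g", 1:5), c("a", "b")))
  r <- rank_transform(x)
  expect_equal(unname(r[, "a"]), c(5, 4, 3, 2, 1))
  expect_equal(unname(r[, "b"]), c(4.5, 4.5, 1, 2, 3))
  # strictly monotone transforms leave ranks unchanged
  expect_equal(rank_transform(exp(x)), r)
})

test_that("ssGSEA matches the frozen position-loop oracle values", {
  cc <- gene_set_collection(list(top = c("g1", "g2"), bottom = c("g4", "g5")))
  es <- ssgsea_scores(toy5, cc, unnorm)$scores
  # values computed with the independent position-by-position oracle
  expect_equal(unname(es["top", 1]), 2.513942856221443, tolerance = 1e-13)
  expect_equal(unname(es["bottom", 1]), -2.456786383137055, tolerance = 1e-13)
  expect_gt(es["top", 1], 0)
  expect_lt(es["bottom", 1], 0)
})

test_that("ssGSEA is deterministic and rank-invariant per sample", {
  x <- cbind(toy5, s2 = toy5[, 1], s3 = 10 * toy5[, 1])
  colnames(x) <- c("s1", "s2", "s3")
  cc <- gene_set_collection(list(S = c("g1", "g3")))
  es <- ssgsea_scores(x, cc, unnorm)$scores
  expect_equal(es[, "s1"], es[, "s2"], ignore_attr = TRUE)
  expect_equal(es[, "s1"], es[, "s3"], ignore_attr = TRUE)
})

test_that("range normalization spans exactly 1 and stores the extremes", {
  set.seed(3)
  x <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:6)))
  cc <- gene_set_collection(list(A = rownames(x)[1:8], B = rownames(x)[9:20],
                                 C = rownames(x)[21:25]))
  s <- ssgsea_scores(x, cc, enrichment_params("ssgsea", normalize = TRUE))
  expect_equal(max(s$scores) - min(s$scores), 1, tolerance = 1e-12)
  raw <- ssgsea_scores(x, cc, unnorm)$scores
  expect_equal(s$norm_min, min(raw))
  expect_equal(s$norm_max, max(raw))
  expect_equal(s$scores, raw / (s$norm_max - s$norm_min))
})

test_that("degenerate sets are rejected with the set named", {
  cc <- gene_set_collection(list(ghost = c("zz1", "zz2")))
  expect_error(ssgsea_scores(toy5, cc, unnorm), "ghost")
  call <- gene_set_collection(list(all = paste0("g", 1:5)))
  expect_error(ssgsea_scores(toy5, call, unnorm), "all")
})

test_that("ssGSEA equals the oracle on random toys, including complement swaps", {
  for (s in 1:20) {
    x <- random_toy(sample(6:10, 1), sample(2:4, 1), seed = s)
    members <- sample(rownames(x), sample(2:(nrow(x) - 2), 1))
    comp <- setdiff(rownames(x), members)
    cc <- gene_set_collection(list(S = members, Sc = comp))
    es <- ssgsea_scores(x, cc, unnorm)$scores
    for (j in seq_len(ncol(x))) {
      expect_equal(es["S", j],
                   oracle_ssgsea_es(x[, j], rownames(x), members),
                   tolerance = 1e-12)
      expect_equal(es["Sc", j],
                   oracle_ssgsea_es(x[, j], rownames(x), comp),
                   tolerance = 1e-12)
    }
  }
})

test_that("GSVA sign, exchangeability and bandwidth floor behave", {
  set.seed(11)
  x <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  x[1:3, 4] <- x[1:3, 4] + 10          # set genes top-expressed in s4
  cc <- gene_set_collection(list(S = paste0("g", 1:3)))
  es <- gsva_scores(x, cc)$scores
  expect_gt(es[1, "s4"], 0)

  # permuting sample order leaves each sample's score unchanged
  perm <- c(3, 1, 6, 2, 5, 4)
  es_p <- gsva_scores(x[, perm], cc)$scores
  expect_equal(es_p[1, colnames(x)], es[1, ], ignore_attr = TRUE)

  # zero-variance gene: bandwidth floored, no error
  x0 <- x; x0[5, ] <- 2
  expect_silent(gsva_scores(x0, cc))
  expect_error(gsva_scores(x[, 1:3], cc), ">= 4 samples")
})

test_that("GSVA equals the straight-line kernel-CDF oracle on toys", {
  for (s in 1:8) {
    x <- random_toy(8, sample(6:10, 1), seed = 100 + s)
    cc <- gene_set_collection(list(S1 = rownames(x)[1:3],
                                   S2 = rownames(x)[c(2, 5, 7, 8)]))
    es <- gsva_scores(x, cc)$scores
    expect_equal(unname(es["S1", ]), oracle_gsva_es(x, cc$S1),
                 tolerance = 1e-9)
    expect_equal(unname(es["S2", ]), oracle_gsva_es(x, cc$S2),
                 tolerance = 1e-9)
    # non-maxdiff variant agrees with the oracle too
    pmd <- enrichment_params("gsva", gsva_max_diff = FALSE)
    expect_equal(unname(gsva_scores(x, cc, pmd)$scores["S1", ]),
                 oracle_gsva_es(x, cc$S1, max_diff = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("stored-range scoring reproduces training scores and extrapolates", {
  set.seed(7)
  x <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:8)))
  cc <- gene_set_collection(list(A = rownames(x)[1:6], B = rownames(x)[7:15]))
  train <- ssgsea_scores(x, cc, enrichment_params("ssgsea"))
  again <- score_with_stored_range(x, cc, train$params,
                                   train$norm_min, train$norm_max)
  expect_equal(again$scores, train$scores, tolerance = 1e-12)

  shifted <- x + 5           # rank-invariant: same scaled scores
  s2 <- score_with_stored_range(shifted, cc, train$params,
                                train$norm_min, train$norm_max)
  expect_equal(s2$scores, train$scores, tolerance = 1e-12)

  expect_error(score_with_stored_range(x, cc, train$params, 1, 1),
               "degenerate")
})

test_that("score matrices round-trip through TSV + JSON sidecar", {
  set.seed(8)
  x <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:5)))
  cc <- gene_set_collection(list(A = rownames(x)[1:5], B = rownames(x)[6:12]))
  s <- ssgsea_scores(x, cc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(s, path)
  s2 <- read_scores(path)
  expect_equal(s2$scores, s$scores, tolerance = 1e-12)
  expect_equal(s2$norm_min, s$norm_min)
  expect_identical(s2$params$method, "ssgsea")
})
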