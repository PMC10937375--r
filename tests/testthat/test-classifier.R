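# Small train/test cohorts shared across blocks (module-level fixtures).
sim_train <- simulate_cohort(n_samples = 90, n_genes = 600, n_sets = 15,
                             set_size = 20, seed = 41)
sim_test <- simulate_cohort(n_samples = 45, n_genes = 600, n_sets = 15,
                            set_size = 20, seed = 42)
small_cfg <- classifier_config(seed = 41, cost_grid = c(0.5, 2),
                               gamma_factors = 1)
model <- train_classifier(sim_train$expr, sim_train$truth$labels,
                          sim_train$sets, small_cfg)

test_that("stratified splitting reproduces exact proportions", {
  labs <- rep(c("1", "2", "3"), c(45, 62, 58))      # 165 samples
  sp <- split_train_test(labs, 125 / 165, seed = 2)
  expect_length(sp$train, 125L)
  expect_length(sp$test, 40L)
  # class proportions preserved within rounding
  tr_tab <- table(labs[sp$train])
  expect_true(all(abs(tr_tab / 125 - table(labs) / 165) < 0.02))

  expect_warning(sp1 <- split_train_test(labs, 1, seed = 1), "empty test")
  expect_length(sp1$test, 0L)

  spA <- split_train_test(labs, 0.7, seed = 1)
  spB <- split_train_test(labs, 0.7, seed = 2)
  expect_length(spA$train, length(spB$train))
  expect_false(identical(spA$train, spB$train))

  expect_error(split_train_test(c("a", "a", "b"), 0.5, seed = 1), "< 2")
})

test_that("LOOCV tuning separates a separable toy and returns single points", {
  set.seed(43)
  X <- rbind(matrix(rnorm(24, 0), 12, 2), matrix(rnorm(24, 5), 12, 2),
             matrix(rnorm(24, 10), 12, 2))
  y <- rep(c("A", "B", "C"), each = 12)
  tu <- tune_svm_loocv(X, y)
  expect_equal(tu$accuracy, 1)

  one <- tune_svm_loocv(X, y, cost_grid = 2, gamma_grid = 0.5)
  expect_equal(one$cost, 2)
  expect_equal(one$gamma, 0.5)

  # permuted labels: LOOCV accuracy collapses to chance (3-permutation mean)
  gap <- mean(vapply(1:3, function(r) {
    yp <- sample(y)
    tp <- tune_svm_loocv(X, yp, cost_grid = 1, gamma_grid = 0.5)
    tp$accuracy - max(table(yp)) / length(yp)
  }, 0))
  expect_lt(abs(gap), 0.1)

  expect_error(tune_svm_loocv(matrix(1, 12, 2), rep(c("A", "B"), 6), 1, 1),
               "constant")
})

test_that("one-vs-one probabilities live on the simplex and recover classes", {
  set.seed(44)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2),
             matrix(rnorm(40, 12), 20, 2))
  y <- rep(c("A", "B", "C"), each = 20)
  fit <- svm_ovo_train(X, y, cost = 1, gamma = 0.5)
  P <- svm_ovo_prob(fit, X)
  expect_equal(rowSums(P), rep(1, 60), tolerance = 1e-9)
  expect_true(all(P >= 0))
  expect_gte(mean(colnames(P)[max.col(P)] == y), 0.95)
})

test_that("training enforces the three-class contract and is deterministic", {
  expect_error(
    train_classifier(sim_train$expr,
                     ifelse(sim_train$truth$labels == "3", "1",
                            sim_train$truth$labels),
                     sim_train$sets, small_cfg),
    "3-class|PDS")

  m2 <- train_classifier(sim_train$expr, sim_train$truth$labels,
                         sim_train$sets, small_cfg)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_classifier(model, f1)
  write_classifier(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("held-out prediction is accurate with simplex probabilities", {
  calls <- predict(model, sim_test$expr)
  expect_gte(mean(calls$call == paste0("PDS", sim_test$truth$labels)), 0.95)
  P <- as.matrix(calls[, c("p_PDS1", "p_PDS2", "p_PDS3")])
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
  expect_true(all(P >= 0))
  expect_identical(calls$sample_id, colnames(sim_test$expr))
})

test_that("thresholding is monotone: raising it only creates mixed calls", {
  c06 <- predict(model, sim_test$expr, threshold = 0.6)
  c08 <- predict(model, sim_test$expr, threshold = 0.8)
  # every 0.8 call is either mixed or identical to the 0.6 call
  expect_true(all(c08$call == "mixed" | c08$call == c06$call))
  expect_gte(mixed_fraction(c08), mixed_fraction(c06))
  expect_error(predict(model, sim_test$expr, threshold = 0.2), "threshold")
})

test_that("explicit probability vectors threshold as specified", {
  probs <- rbind(s1 = c(0.70, 0.20, 0.10),
                 s2 = c(0.55, 0.30, 0.15),
                 s3 = c(0.25, 0.30, 0.45))
  colnames(probs) <- c("PDS1", "PDS2", "PDS3")
  calls <- pdskit:::calls_from_probs(probs, 0.6, colnames(probs))
  expect_identical(calls$call, c("PDS1", "mixed", "mixed"))
  expect_equal(mixed_fraction(calls), 2 / 3)
  all_conf <- pdskit:::calls_from_probs(
    matrix(c(0.9, 0.05, 0.05), 1, dimnames = list("s", colnames(probs))),
    0.6, colnames(probs))
  expect_equal(mixed_fraction(all_conf), 0)
  expect_error(mixed_fraction(calls[0, ]), "no calls")
})

test_that("prediction guards gene overlap", {
  x <- sim_test$expr
  used <- unique(unlist(model$gmt, use.names = FALSE))
  # drop 30% of each set's genes -> warning, but every set keeps members
  drop_genes <- unlist(lapply(unclass(model$gmt), function(m)
    m[seq_len(round(0.3 * length(m)))]), use.names = FALSE)
  x_part <- x[setdiff(rownames(x), drop_genes), ]
  expect_warning(predict(model, x_part), "model genes")

  x_none <- x[setdiff(rownames(x), used), ]
  expect_error(predict(model, x_none), "overlap")
})

test_that("the persisted model predicts identically after reload", {
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(model, path)
  m2 <- read_classifier(path)
  expect_equal(predict(m2, sim_test$expr), predict(model, sim_test$expr),
               tolerance = 1e-12)
  expect_error(read_classifier(withr::local_tempfile(fileext = ".json",
                                                     lines = "{}")),
               "archive")
})

test_that("training-cohort prediction reproduces training scores before the SVM", {
  sc <- ssgsea_scores(sim_train$expr,
                      filter_sets(sim_train$sets, sim_train$expr, 10),
                      model$enrichment_params)
  S_train <- sc$scores[model$selected_sets, ]
  S_pred <- score_with_stored_range(sim_train$expr, model$gmt,
                                    model$enrichment_params,
                                    model$norm_min, model$norm_max)$scores
  S_pred <- combat_reference(S_pred[model$selected_sets, ],
                             model$batch_model)
  expect_equal(S_pred, S_train, tolerance = 1e-12)
})
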