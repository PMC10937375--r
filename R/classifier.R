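#' Stratified train/test split
#'
#' Per-class quotas are apportioned by largest remainder so the overall
#' train size equals `round(train_fraction * n)` while preserving class
#' proportions; deterministic for a fixed seed.
#'
#' @param labels Per-sample class labels (named vector or plain; every class
#'   needs >= 2 members).
#' @param train_fraction Fraction of samples for training.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_fraction, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("class(es) with < 2 members: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  stopifnot(train_fraction > 0, train_fraction <= 1)
  n <- length(labels)
  target <- round(train_fraction * n)
  quota <- as.numeric(tab) * train_fraction
  base <- floor(quota)
  rem <- target - sum(base)
  if (rem > 0) {
    extra <- order(-(quota - base), seq_along(base))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  names(base) <- names(tab)
  set.seed(seed)
  train_idx <- unlist(lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    sample(idx, min(base[[cl]], length(idx)))
  }), use.names = FALSE)
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) == 0L) warning("empty test set (train_fraction = 1)")
  list(train = train_idx, test = test_idx)
}

#' Configuration for classifier training
#'
#' @param min_size Minimum gene-set size after universe filtering (default
#'   10). @param tau ssGSEA weight exponent (default 0.25).
#' @param correlation_cutoff Feature-pruning cutoff (default 0.9).
#' @param cost_grid,gamma_factors SVM tuning grid; widths are the median
#'   heuristic times `gamma_factors`.
#' @param threshold Default probability call threshold (in (1/3, 1];
#'   default 0.6).
#' @param seed Integer seed.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(min_size = 10L, tau = 0.25,
                              correlation_cutoff = 0.9,
                              cost_grid = c(0.25, 0.5, 1, 2, 4, 8),
                              gamma_factors = c(0.1, 1, 10),
                              threshold = 0.6, seed = 1L) {
  stopifnot(threshold > 1 / 3, threshold <= 1)
  structure(list(min_size = as.integer(min_size), tau = tau,
                 correlation_cutoff = correlation_cutoff,
                 cost_grid = cost_grid, gamma_factors = gamma_factors,
                 threshold = threshold, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train the pathway-derived subtype classifier
#'
#' End-to-end training: universe filtering and range-normalized ssGSEA
#' scoring (the global extremes are stored for prediction-time scaling),
#' subtype-specific feature selection with correlation pruning,
#' reference-batch statistics for ComBat alignment of future cohorts, and a
#' LOOCV-tuned one-vs-one RBF-SVM with per-pair sigmoid calibration. The
#' classifier is three-class by contract (PDS1/PDS2/PDS3); cluster labels
#' 1..3 are mapped onto those names.
#'
#' @param x Genes x samples training expression matrix.
#' @param labels Training labels: integers 1..3 or characters
#'   `"PDS1".."PDS3"`.
#' @param c A `gene_set_collection`.
#' @param cfg A `classifier_config`.
#' @return A `pds_classifier` model carrying everything needed for
#'   standalone prediction.
#' @export
train_classifier <- function(x, labels, c, cfg = classifier_config()) {
  labels <- as.character(labels)
  if (all(grepl("^[0-9]+$", labels))) labels <- paste0("PDS", labels)
  classes <- c("PDS1", "PDS2", "PDS3")
  if (!setequal(unique(labels), classes))
    stop("classifier is 3-class by contract; labels must cover exactly ",
         "PDS1, PDS2, PDS3")
  stopifnot(length(labels) == ncol(x))
  csets <- filter_sets(c, x, min_size = cfg$min_size)
  p <- enrichment_params("ssgsea", tau = cfg$tau, normalize = TRUE)
  sc <- ssgsea_scores(x, csets, p)
  feats <- select_features(sc, labels, cutoff = cfg$correlation_cutoff)
  selected <- feats$set_name
  if (length(selected) < 2L) stop("feature selection left < 2 gene sets")
  S <- sc$scores[selected, , drop = FALSE]
  batch_model <- fit_reference_batch(S)
  X <- t(S)
  set.seed(cfg$seed)
  tuned <- tune_svm_loocv(X, labels, cost_grid = cfg$cost_grid,
                          gamma_grid = median_gamma(X) * cfg$gamma_factors)
  svm <- svm_ovo_train(X, labels, cost = tuned$cost, gamma = tuned$gamma,
                       classes = classes)
  structure(list(
    selected_sets = selected,
    feature_subtypes = stats::setNames(feats$subtype, feats$set_name),
    gmt = subset_collection(csets, selected),
    enrichment_params = p,
    norm_min = sc$norm_min, norm_max = sc$norm_max,
    batch_model = batch_model,
    svm = svm, tuning = tuned[c("cost", "gamma", "accuracy")],
    classes = classes, default_threshold = cfg$threshold,
    seed = cfg$seed), class = "pds_classifier")
}

#' @export
print.pds_classifier <- function(x, ...) {
  cat(sprintf(paste0("pds_classifier: %d gene sets, RBF-SVM ",
                     "(cost = %g, gamma = %.4g), threshold %.2f\n"),
              length(x$selected_sets), x$svm$cost, x$svm$gamma,
              x$default_threshold))
  invisible(x)
}

#' Predict pathway-derived subtype calls
#'
#' Pipeline: ssGSEA on the model's gene sets, scaling by the stored training
#' extremes, reference-batch ComBat against the training scores, calibrated
#' SVM probabilities, and thresholded calls. A sample is labeled with the
#' argmax class when its maximum probability reaches the threshold and
#' `"mixed"` otherwise, so raising the threshold can only convert class
#' labels to mixed, never the reverse.
#'
#' @param object A `pds_classifier`.
#' @param x Genes x samples expression matrix. A warning is issued when
#'   fewer than 80% of the genes used by the model's sets are present; zero
#'   overlap is an error.
#' @param threshold Call threshold in (1/3, 1] (default: the model's).
#' @param combat Apply reference-batch alignment (default `TRUE`).
#' @param ... Unused.
#' @return Data frame of subtype calls: `sample_id`, `p_PDS1`, `p_PDS2`,
#'   `p_PDS3`, `call`, `threshold`.
#' @export
predict.pds_classifier <- function(object, x,
                                   threshold = object$default_threshold,
                                   combat = TRUE, ...) {
  stopifnot(threshold > 1 / 3, threshold <= 1)
  model_genes <- unique(unlist(object$gmt, use.names = FALSE))
  overlap <- mean(model_genes %in% rownames(x))
  if (overlap == 0) stop("no overlap between model genes and expression matrix")
  if (overlap < 0.8)
    warning(sprintf("only %.0f%% of model genes present in the matrix",
                    100 * overlap))
  sc <- score_with_stored_range(x, object$gmt, object$enrichment_params,
                                norm_min = object$norm_min,
                                norm_max = object$norm_max)
  S <- sc$scores[object$selected_sets, , drop = FALSE]
  if (isTRUE(combat)) S <- combat_reference(S, object$batch_model)
  probs <- svm_ovo_prob(object$svm, t(S))
  calls_from_probs(probs, threshold, classes = object$classes)
}

# Thresholded calls from a samples x classes probability matrix.
calls_from_probs <- function(probs, threshold, classes) {
  probs <- probs[, classes, drop = FALSE]
  top <- max.col(probs, ties.method = "first")
  pmax_ <- probs[cbind(seq_len(nrow(probs)), top)]
  call <- ifelse(pmax_ >= threshold, classes[top], "mixed")
  out <- data.frame(sample_id = rownames(probs), probs, call = call,
                    threshold = threshold, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  names(out)[2:4] <- paste0("p_", classes)
  out
}

#' Fraction of mixed calls
#'
#' @param calls Data frame from [predict.pds_classifier()] (non-empty).
#' @return Fraction of samples labeled `"mixed"`; non-decreasing in the
#'   threshold used to produce the calls.
#' @export
mixed_fraction <- function(calls) {
  if (nrow(calls) == 0L) stop("no calls")
  mean(calls$call == "mixed")
}

#' Persist / load a classifier model (single JSON archive)
#'
#' The archive embeds the gene sets, scaling extremes, reference-batch
#' statistics and all SVM parameters, so prediction needs no external
#' files. Numbers are serialized at full precision; training twice with the
#' same seed yields a byte-identical file.
#'
#' @param model A `pds_classifier`. @param path Output JSON path.
#' @export
write_classifier <- function(model, path) {
  fits <- lapply(model$svm$fits, function(ft) list(
    pos = ft$pos, neg = ft$neg, X_sv = as.data.frame(ft$X_sv),
    sv_ids = rownames(ft$X_sv), coef = ft$coef, bias = ft$bias,
    platt = as.list(ft$platt)))
  obj <- list(
    format = "pds_classifier/1",
    selected_sets = model$selected_sets,
    feature_subtypes = as.list(model$feature_subtypes),
    gmt = lapply(unclass(model$gmt), as.list),
    enrichment_params = unclass(model$enrichment_params),
    norm_min = model$norm_min, norm_max = model$norm_max,
    batch_model = list(sets = model$batch_model$sets,
                       ref_mean = model$batch_model$ref_mean,
                       ref_var = model$batch_model$ref_var,
                       ref_sample_ids = model$batch_model$ref_sample_ids,
                       n_ref = model$batch_model$n_ref),
    svm = list(classes = model$svm$classes, gamma = model$svm$gamma,
               cost = model$svm$cost, fits = fits),
    tuning = model$tuning,
    classes = model$classes, default_threshold = model$default_threshold,
    seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "pds_classifier/1"))
    stop("not a pds_classifier archive: ", path)
  fits <- lapply(seq_len(nrow(o$svm$fits)), function(i) {
    ft <- o$svm$fits[i, ]
    Xsv <- as.matrix(ft$X_sv[[1L]])
    rownames(Xsv) <- ft$sv_ids[[1L]]
    list(pos = ft$pos, neg = ft$neg, X_sv = Xsv,
         coef = unlist(ft$coef), bias = ft$bias,
         platt = c(A = ft$platt$A, B = ft$platt$B))
  })
  svm <- structure(list(classes = o$svm$classes, gamma = o$svm$gamma,
                        cost = o$svm$cost, fits = fits), class = "svm_ovo")
  ep <- do.call(enrichment_params,
                o$enrichment_params[c("method", "tau", "normalize",
                                      "gsva_max_diff", "gsva_tau")])
  structure(list(
    selected_sets = o$selected_sets,
    feature_subtypes = unlist(o$feature_subtypes),
    gmt = gene_set_collection(lapply(o$gmt, unlist)),
    enrichment_params = ep,
    norm_min = o$norm_min, norm_max = o$norm_max,
    batch_model = structure(list(
      sets = o$batch_model$sets,
      ref_mean = stats::setNames(o$batch_model$ref_mean, o$batch_model$sets),
      ref_var = stats::setNames(o$batch_model$ref_var, o$batch_model$sets),
      ref_sample_ids = o$batch_model$ref_sample_ids,
      n_ref = o$batch_model$n_ref), class = "batch_model"),
    svm = svm, tuning = o$tuning, classes = o$classes,
    default_threshold = o$default_threshold, seed = o$seed),
    class = "pds_classifier")
}

#' Write subtype calls as TSV
#' @param calls Call data frame. @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
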