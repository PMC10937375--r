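#' Subtype-specific gene-set selection
#'
#' A gene set is assigned to the subtype in which its mean score is (a)
#' strictly the maximum across subtypes and (b) above the grand mean over
#' all samples. Sets satisfying neither condition for any subtype are
#' dropped, so the selected sets form a partition across subtypes.
#'
#' @param s A `score_matrix` or plain sets x samples matrix.
#' @param labels Per-sample subtype labels (length = n samples; >= 2
#'   subtypes, each with >= 2 samples).
#' @return Data frame with columns `set_name`, `subtype`, ordered as in the
#'   input score matrix.
#' @export
subtype_specific_sets <- function(s, labels) {
  m <- if (inherits(s, "score_matrix")) s$scores else s
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m))
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >= 2 subtypes")
  if (any(tab < 2L))
    stop("subtype(s) with < 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  groups <- sort(names(tab))
  gm <- vapply(groups, function(g)
    rowMeans(m[, labels == g, drop = FALSE]), numeric(nrow(m)))
  gm <- matrix(gm, nrow = nrow(m), dimnames = list(rownames(m), groups))
  grand <- rowMeans(m)
  best <- max.col(gm, ties.method = "first")
  top <- gm[cbind(seq_len(nrow(gm)), best)]
  strict <- vapply(seq_len(nrow(gm)), function(i)
    sum(gm[i, ] == top[i]) == 1L, logical(1L))
  keep <- strict & (top > grand)
  data.frame(set_name = rownames(m)[keep],
             subtype = groups[best[keep]],
             stringsAsFactors = FALSE)
}

#' Greedy correlation pruning of selected gene sets
#'
#' While any pair of surviving sets has absolute across-sample Pearson
#' correlation above `cutoff`, the member of the most-correlated pair with
#' the larger mean absolute correlation to all remaining sets is removed
#' (ties broken by set name, removing the lexicographically later one), so
#' the result is independent of input order. Constant-score sets have
#' undefined correlation; they are treated as correlation 0 and retained.
#'
#' @param s A `score_matrix` or plain sets x samples matrix.
#' @param selected Character vector of set names to prune (>= 2).
#' @param cutoff Absolute-correlation threshold in (0, 1] (default 0.9).
#' @return Character vector of surviving set names (input order).
#' @export
prune_correlated <- function(s, selected, cutoff = 0.9) {
  stopifnot(cutoff > 0, cutoff <= 1)
  m <- if (inherits(s, "score_matrix")) s$scores else s
  if (length(selected) < 2L) stop("need >= 2 selected sets")
  missing_ <- setdiff(selected, rownames(m))
  if (length(missing_)) stop("unknown sets: ", paste(missing_, collapse = ", "))
  sub <- m[selected, , drop = FALSE]
  cc <- suppressWarnings(abs(stats::cor(t(sub))))
  cc[!is.finite(cc)] <- 0          # constant sets: correlation treated as 0
  diag(cc) <- 0
  alive <- rownames(cc)
  while (length(alive) > 1L) {
    cm <- cc[alive, alive, drop = FALSE]
    mx <- max(cm)
    if (mx <= cutoff) break
    hits <- which(cm == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    pair_names <- t(apply(hits, 1L, function(h)
      sort(c(alive[h[1L]], alive[h[2L]]))))
    ordp <- order(pair_names[, 1L], pair_names[, 2L])
    pair <- pair_names[ordp[1L], ]
    mac <- rowMeans(cm[pair, , drop = FALSE])
    drop_ <- if (mac[1L] > mac[2L]) pair[1L]
             else if (mac[2L] > mac[1L]) pair[2L]
             else max(pair)         # name tie-break: later name removed
    alive <- setdiff(alive, drop_)
  }
  selected[selected %in% alive]
}

#' Run both selection stages and write the feature table
#'
#' @param s A `score_matrix` (training scores). @param labels Subtype labels.
#' @param cutoff Correlation cutoff (default 0.9).
#' @return Data frame (`set_name`, `subtype`) restricted to pruned
#'   survivors.
#' @export
select_features <- function(s, labels, cutoff = 0.9) {
  assigned <- subtype_specific_sets(s, labels)
  if (nrow(assigned) < 2L) stop("fewer than 2 subtype-specific sets")
  kept <- prune_correlated(s, assigned$set_name, cutoff = cutoff)
  assigned[assigned$set_name %in% kept, , drop = FALSE]
}

#' @rdname select_features
#' @param features Data frame from [select_features()]. @param path TSV path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
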