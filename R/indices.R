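#' Stem maturation index (SMI)
#'
#' Per sample (or cell), the difference between the polycomb-target (PRC)
#' and MYC-target ssGSEA scores, min-max rescaled onto [-1, 1] across the
#' supplied samples: the dataset maximum difference maps to 1
#' (differentiated-like) and the minimum to -1 (stem-like). The rescale is
#' cohort-relative, so SMI values are not comparable across independently
#' scored cohorts. A degenerate cohort in which all differences are equal
#' yields SMI 0 everywhere.
#'
#' @param x Genes x samples (or cells) expression matrix.
#' @param myc_set,prc_set Character vectors of member genes; both must
#'   overlap the matrix.
#' @param tau ssGSEA weight exponent (default 0.25).
#' @return Data frame: `sample_id`, `myc`, `prc`, `d` (prc - myc), `smi`.
#' @export
smi <- function(x, myc_set, prc_set, tau = 0.25) {
  c2 <- gene_set_collection(list(MYC_targets = myc_set,
                                 PRC_targets = prc_set))
  sc <- ssgsea_scores(x, c2, enrichment_params("ssgsea", tau = tau,
                                               normalize = FALSE))
  myc <- sc$scores["MYC_targets", ]
  prc <- sc$scores["PRC_targets", ]
  d <- prc - myc
  s <- if (diff(range(d)) == 0) rep(0, length(d)) else rescale_range(d, -1, 1)
  data.frame(sample_id = colnames(x), myc = myc, prc = prc, d = d, smi = s,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcriptomic proliferative index
#'
#' Per-sample aggregate (median by default) of the expression of a
#' proliferation-associated signature (PCNA-metagene tradition); only
#' signature genes present in the matrix contribute.
#'
#' @param x Genes x samples expression matrix.
#' @param signature Character vector of signature genes.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return Named numeric vector (per sample).
#' @export
proliferative_index <- function(x, signature,
                                aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  present <- intersect(signature, rownames(x))
  if (length(present) == 0L)
    stop("no signature gene present in the expression matrix")
  sub <- x[present, , drop = FALSE]
  if (aggregate == "median") apply(sub, 2L, stats::median) else colMeans(sub)
}

#' Replication-stress score
#'
#' Bulk mode: the per-sample sum of GSVA scores across a collection of
#' cell-cycle / DNA-repair signatures (left unscaled). Single-cell mode:
#' the per-cell sum of ssGSEA scores, min-max rescaled onto [-1, 1] across
#' cells.
#'
#' @param x Genes x samples (or cells) expression matrix.
#' @param signatures A `gene_set_collection` of replication-stress-related
#'   sets. Sets without any overlap are dropped with a warning naming them.
#' @param mode `"bulk"` or `"single_cell"`.
#' @param tau ssGSEA weight exponent (single-cell mode; default 0.25).
#' @return Named numeric vector (per sample/cell).
#' @export
replication_stress <- function(x, signatures, mode = c("bulk", "single_cell"),
                               tau = 0.25) {
  mode <- match.arg(mode)
  overlap <- vapply(unclass(signatures),
                    function(m) sum(m %in% rownames(x)), 0L)
  if (any(overlap == 0L)) {
    warning("dropping sets with no overlap: ",
            paste(names(signatures)[overlap == 0L], collapse = ", "))
    signatures <- subset_collection(signatures,
                                    names(signatures)[overlap > 0L])
    if (length(signatures) == 0L) stop("no signature set overlaps the matrix")
  }
  if (mode == "bulk") {
    sc <- gsva_scores(x, signatures, enrichment_params("gsva"))
    colSums(sc$scores)
  } else {
    sc <- ssgsea_scores(x, signatures,
                        enrichment_params("ssgsea", tau = tau,
                                          normalize = FALSE))
    total <- colSums(sc$scores)
    stats::setNames(rescale_range(total, -1, 1), names(total))
  }
}

#' Stem-signature (CBC / RSC) scores
#'
#' Raw (unnormalized) ssGSEA scores for the crypt-base columnar (LGR5+) and
#' regenerative (ANXA1+) stem-cell signatures, for scatter / landscape use.
#'
#' @param x Genes x samples expression matrix.
#' @param cbc_set,rsc_set Member gene vectors.
#' @param tau ssGSEA weight exponent (default 0.25).
#' @return Data frame: `sample_id`, `cbc`, `rsc`.
#' @export
stem_scores <- function(x, cbc_set, rsc_set, tau = 0.25) {
  c2 <- gene_set_collection(list(CBC = cbc_set, RSC = rsc_set))
  sc <- ssgsea_scores(x, c2, enrichment_params("ssgsea", tau = tau,
                                               normalize = FALSE))
  data.frame(sample_id = colnames(x), cbc = sc$scores["CBC", ],
             rsc = sc$scores["RSC", ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Tertile-based high/low labeling of two scores
#'
#' Each score is binned into empirical tertiles (low/mid/high). A sample is
#' `<A>-high` when score A falls in the top tertile and score B in the
#' bottom tertile, symmetrically for `<B>-high`; everything else is
#' `"neither"`. The three labels are mutually exclusive and exhaustive.
#'
#' @param scores_a,scores_b Aligned numeric score vectors (>= 3 values).
#' @param names_ Length-2 character vector naming the scores (default
#'   `c("A", "B")`).
#' @return Character vector of labels.
#' @export
tertile_high_labels <- function(scores_a, scores_b, names_ = c("A", "B")) {
  stopifnot(length(scores_a) == length(scores_b), length(names_) == 2L)
  if (length(scores_a) < 3L) stop("tertiles undefined for < 3 samples")
  bin <- function(x) {
    q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE)
    ifelse(x <= q[1L], "low", ifelse(x > q[2L], "high", "mid"))
  }
  ba <- bin(scores_a); bb <- bin(scores_b)
  ifelse(ba == "high" & bb == "low", paste0(names_[1L], "-high"),
         ifelse(bb == "high" & ba == "low", paste0(names_[2L], "-high"),
                "neither"))
}
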