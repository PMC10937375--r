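#' Read a gene-by-sample expression matrix
#'
#' Loads a numeric genes x samples matrix from delimited text or a
#' MatrixMarket triplet with row/column name sidecar files. Values are
#' expected to be log-scale or otherwise normalized continuous expression;
#' the loader never transforms them. Missing values are an error: the
#' downstream scoring is rank-based and ranks are ill-defined on NA.
#'
#' Duplicate gene identifiers are preserved on load so that microarray
#' probe-level matrices can be collapsed afterwards with
#' [collapse_features()]. Duplicate sample identifiers are an error.
#'
#' @param path Path to a TSV/CSV file (first column gene ids, header sample
#'   ids) or, for `dialect = "mtx-triplet"`, the MatrixMarket `.mtx` file.
#' @param dialect One of `"tsv"`, `"csv"`, `"mtx-triplet"`.
#' @param row_names,col_names For `mtx-triplet` only: paths to one-id-per-line
#'   text files with gene and sample ids. Default `<path>.rownames` /
#'   `<path>.colnames`.
#' @return A numeric matrix (genes x samples) with rownames and colnames.
#' @export
read_expression <- function(path, dialect = c("tsv", "csv", "mtx-triplet"),
                            row_names = NULL, col_names = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "mtx-triplet") {
    if (is.null(row_names)) row_names <- paste0(path, ".rownames")
    if (is.null(col_names)) col_names <- paste0(path, ".colnames")
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar id files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
    return(validate_expression(m, allow_dup_genes = TRUE))
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]     # before [.data.frame make.unique's them
  vals <- as.matrix(df[, -1L, drop = FALSE])
  colnames(vals) <- sample_ids
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  validate_expression(num, allow_dup_genes = TRUE)
}

#' Validate an expression matrix
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param allow_dup_genes Permit duplicate gene ids (pre-collapse matrices).
#' @return `x`, invisibly checked.
#' @export
validate_expression <- function(x, allow_dup_genes = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (!allow_dup_genes && anyDuplicated(rownames(x))) stop("duplicate gene ids")
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  x
}

#' Write an expression matrix as TSV
#'
#' @param x Numeric genes x samples matrix.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to one row per gene
#'
#' For each gene, the probe whose across-sample mean is highest is retained
#' (the standard microarray collapse rule). Probes absent from `id_map` are
#' dropped.
#'
#' @param x Numeric probes x samples matrix (probe rownames).
#' @param id_map Named character vector: `names(id_map)` are probe ids,
#'   values are gene ids.
#' @return Genes x samples matrix with unique gene rownames.
#' @export
collapse_features <- function(x, id_map) {
  x <- validate_expression(x, allow_dup_genes = TRUE)
  if (length(id_map) == 0L) stop("empty probe-to-gene mapping")
  keep <- rownames(x) %in% names(id_map)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0L) stop("no probes matched the mapping")
  genes <- unname(id_map[rownames(x)])
  means <- rowMeans(x)
  ord <- order(genes, -means)      # within gene, highest mean first
  first <- !duplicated(genes[ord])
  sel <- sort(ord[first])          # winners, in original row order
  out <- x[sel, , drop = FALSE]
  rownames(out) <- genes[sel]
  out
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Matching against expression matrices is exact-string;
#' no case folding is applied.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: named list of character member vectors
#'   with a `description` attribute (named character) and a `provenance`
#'   attribute (free text).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields")
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop("duplicate gene-set name: ", names_[duplicated(names_)][1L])
  descs <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(stats::setNames(members, names_),
                      description = stats::setNames(descs, names_),
                      provenance = path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique members per set).
#' @param description Optional named character vector of descriptions.
#' @param provenance Free-text source tag.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, description = NULL, provenance = "") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    if (anyDuplicated(m)) m <- unique(m)
    m
  })
  if (is.null(description))
    description <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, description = description, provenance = provenance,
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, member sizes %d-%d\n",
              length(x), if (length(x)) min(lengths(x)) else 0L,
              if (length(x)) max(lengths(x)) else 0L))
  invisible(x)
}

#' Subset a gene-set collection by name
#' @param x Collection. @param names_ Set names to keep (order respected).
#' @return Restricted collection.
#' @export
subset_collection <- function(x, names_) {
  missing_ <- setdiff(names_, names(x))
  if (length(missing_)) stop("unknown set names: ", paste(missing_, collapse = ", "))
  gene_set_collection(unclass(x)[names_],
                      description = attr(x, "description")[names_],
                      provenance = attr(x, "provenance"))
}

#' Write a gene-set collection to GMT
#'
#' Round-trips with [read_gmt()]: names, descriptions, member order and
#' counts are preserved byte-for-byte for ASCII identifiers.
#'
#' @param x A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(x)), names(x))
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, desc[[nm]], x[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets against an expression universe
#'
#' Intersects each set with the genes of `x` and removes sets with fewer
#' than `min_size` surviving members (default 10, the minimum-size rule used
#' when scoring curated pathway collections).
#'
#' @param c A `gene_set_collection`.
#' @param x Expression matrix whose rownames define the universe.
#' @param min_size Minimum surviving members per set (>= 1).
#' @param verbose Report the survivor count.
#' @return Filtered collection (members restricted to the universe).
#' @export
filter_sets <- function(c, x, min_size = 10L, verbose = FALSE) {
  stopifnot(min_size >= 1L)
  universe <- rownames(x)
  kept <- lapply(unclass(c), function(m) m[m %in% universe])
  ok <- lengths(kept) >= min_size
  if (!any(ok))
    stop("no gene set has >= ", min_size, " members in the expression ",
         "universe; check identifier conventions (exact-string matching)")
  if (verbose)
    message(sum(ok), " of ", length(c), " sets survive min_size = ", min_size)
  gene_set_collection(kept[ok],
                      description = attr(c, "description")[names(kept)[ok]],
                      provenance = attr(c, "provenance"))
}

#' Optional low-variance gene pre-filter
#'
#' Removes the fraction `var_cutoff` of genes with the lowest across-sample
#' variance. Off by default in every pipeline; exposed for RNA-seq matrices
#' where low-variance tags carry no ranking information.
#'
#' @param x Expression matrix. @param var_cutoff Fraction of genes to drop.
#' @return Filtered matrix.
#' @export
filter_low_variance <- function(x, var_cutoff = 0.25) {
  stopifnot(var_cutoff >= 0, var_cutoff < 1)
  if (var_cutoff == 0) return(x)
  v <- apply(x, 1L, stats::var)
  x[v > stats::quantile(v, var_cutoff), , drop = FALSE]
}
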