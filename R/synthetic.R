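# Synthetic expression cohorts with known ground truth. The generator
# emulates the structure the subtyping pipeline assumes: K latent subtypes
# activating disjoint blocks of gene sets, additive Gaussian noise on a
# log-like scale, optional batch location shifts, and a fraction of "mixed"
# samples blending two subtype profiles 50/50. Gene sets and their subtype
# assignments are a deterministic function of the size parameters, so two
# cohorts drawn with different seeds share the same set structure and can
# serve as train/test pairs.

#' Simulate an expression cohort with planted subtypes
#'
#' Background expression is Normal(0, `noise_sd`) per gene. Half of the gene
#' sets are informative, assigned round-robin to subtypes 1..k; member genes
#' of a subtype's sets are shifted by `effect_size * noise_sd` in samples of
#' that subtype. Mixed samples receive half the shift from each of two
#' subtypes. Optional batches add a location shift to every gene.
#'
#' @param n_samples,n_genes Cohort dimensions (defaults 150 x 1200).
#' @param n_sets Number of gene sets (default 30, sizes `set_size`,
#'   disjoint members; `n_sets * set_size <= n_genes` required).
#' @param k Number of subtypes (default 3).
#' @param effect_size Activation shift in units of `noise_sd` (default 2).
#' @param mixed_fraction Fraction of samples blending two subtypes
#'   (default 0).
#' @param batch_shifts Optional numeric vector of per-batch location shifts;
#'   samples are assigned to batches round-robin.
#' @param noise_sd Gaussian noise SD (default 1).
#' @param set_size Genes per set (default 30, about the median size of
#'   curated pathway collections after a min-size-10 universe filter).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return List: `expr` (genes x samples), `sets`
#'   (`gene_set_collection`), `truth` (labels with `"mixed"`, mixed flags
#'   and blend pairs, per-set subtype assignment, batch assignments,
#'   parameters, seed).
#' @export
simulate_cohort <- function(n_samples = 150L, n_genes = 1200L, n_sets = 30L,
                            k = 3L, effect_size = 2, mixed_fraction = 0,
                            batch_shifts = NULL, noise_sd = 1,
                            set_size = 30L, seed = 1L) {
  stopifnot(k >= 2L, effect_size >= 0, mixed_fraction >= 0,
            mixed_fraction < 1)
  if (n_sets * set_size > n_genes)
    stop("infeasible: n_sets * set_size exceeds n_genes")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  set_names <- sprintf("SET%02d", seq_len(n_sets))
  members <- lapply(seq_len(n_sets), function(i)
    gene_ids[((i - 1L) * set_size + 1L):(i * set_size)])
  names(members) <- set_names
  # deterministic structure: first half informative, round-robin subtype
  n_inf <- ceiling(n_sets / 2)
  set_subtype <- c(rep_len(seq_len(k), n_inf), rep(0L, n_sets - n_inf))
  names(set_subtype) <- set_names

  set.seed(seed)
  n_mixed <- round(mixed_fraction * n_samples)
  pure_labels <- rep_len(seq_len(k), n_samples - n_mixed)
  labels <- c(sample(pure_labels), rep(NA_integer_, n_mixed))
  mixed_flags <- c(rep(FALSE, n_samples - n_mixed), rep(TRUE, n_mixed))
  ord <- sample.int(n_samples)
  labels <- labels[ord]; mixed_flags <- mixed_flags[ord]
  blend <- matrix(NA_integer_, n_samples, 2L)
  for (j in which(mixed_flags)) blend[j, ] <- sample.int(k, 2L)

  expr <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                 n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
  shift <- effect_size * noise_sd
  gene_of_subtype <- lapply(seq_len(k), function(g)
    unlist(members[set_subtype == g], use.names = FALSE))
  for (j in seq_len(n_samples)) {
    if (mixed_flags[j]) {
      expr[gene_of_subtype[[blend[j, 1L]]], j] <-
        expr[gene_of_subtype[[blend[j, 1L]]], j] + shift / 2
      expr[gene_of_subtype[[blend[j, 2L]]], j] <-
        expr[gene_of_subtype[[blend[j, 2L]]], j] + shift / 2
    } else {
      expr[gene_of_subtype[[labels[j]]], j] <-
        expr[gene_of_subtype[[labels[j]]], j] + shift
    }
  }
  batch <- NULL
  if (!is.null(batch_shifts)) {
    batch <- rep_len(seq_along(batch_shifts), n_samples)
    expr <- expr + rep(batch_shifts[batch], each = n_genes)
  }
  truth_labels <- ifelse(mixed_flags, "mixed", as.character(labels))
  list(expr = expr,
       sets = gene_set_collection(members, provenance = "simulate_cohort"),
       truth = list(labels = truth_labels, subtype = labels,
                    mixed_flags = mixed_flags, blend = blend,
                    set_subtype = set_subtype, effect_size = effect_size,
                    noise_sd = noise_sd, batch = batch,
                    batch_shifts = batch_shifts, seed = as.integer(seed)))
}

#' Simulate a stem-to-differentiated expression axis
#'
#' Each cell carries a latent differentiation coordinate t ~ Uniform(0, 1).
#' MYC-target genes scale with (1 - t) (stem-like end) and PRC-target genes
#' with t (differentiated end), with per-gene amplitudes spread over
#' [1.5, 2.5]; background genes keep fixed baselines drawn uniformly over
#' the same dynamic range so gene orderings shift smoothly along the axis.
#' Gaussian noise is added everywhere.
#'
#' @param n_cells Number of cells (default 200).
#' @param myc_set,prc_set Disjoint character vectors of gene ids.
#' @param noise_sd Noise SD (default 0.5).
#' @param n_background Background genes (default 400).
#' @param seed Integer seed.
#' @return List: `expr` (genes x cells), `t` (latent coordinate per cell).
#' @export
simulate_differentiation_axis <- function(n_cells = 200L, myc_set, prc_set,
                                          noise_sd = 0.5,
                                          n_background = 400L, seed = 1L) {
  if (length(intersect(myc_set, prc_set)))
    stop("myc_set and prc_set must be disjoint")
  set.seed(seed)
  t_ <- stats::runif(n_cells)
  bg_ids <- sprintf("bg%04d", seq_len(n_background))
  gene_ids <- c(myc_set, prc_set, bg_ids)
  amp <- function(n) seq(1.5, 2.5, length.out = n)
  a_myc <- amp(length(myc_set)); a_prc <- amp(length(prc_set))
  baseline <- stats::runif(n_background, 0, 2.5)
  expr <- rbind(outer(a_myc, 1 - t_),
                outer(a_prc, t_),
                matrix(baseline, n_background, n_cells))
  expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd),
                        nrow(expr), n_cells)
  dimnames(expr) <- list(gene_ids, sprintf("c%04d", seq_len(n_cells)))
  list(expr = expr, t = t_)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `<base>.expr.tsv`, `<base>.gmt`, `<base>.labels.tsv` and
#' `<base>.truth.json` (the truth round-trips through this serialization).
#'
#' @param sim Output of [simulate_cohort()]. @param base Output basename.
#' @export
write_cohort <- function(sim, base) {
  write_expression(sim$expr, paste0(base, ".expr.tsv"))
  write_gmt(sim$sets, paste0(base, ".gmt"))
  utils::write.table(
    data.frame(sample_id = colnames(sim$expr), label = sim$truth$labels),
    paste0(base, ".labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(sim$truth, paste0(base, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(base)
}
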