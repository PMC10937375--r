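#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to
#' label permutation), ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Relabel cluster ids so cluster 1 is the largest (ties by first occurrence).
canonicalize_labels <- function(labels) {
  sizes <- table(labels)
  first_at <- vapply(names(sizes), function(l) match(l, as.character(labels)),
                     0L)
  ord <- names(sizes)[order(-as.integer(sizes), first_at)]
  as.integer(factor(as.character(labels), levels = ord))
}

# Min-max rescale onto [lo, hi]; degenerate range maps to the midpoint.
rescale_range <- function(x, lo = -1, hi = 1) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep((lo + hi) / 2, length(x)))
  lo + (hi - lo) * (x - rng[1L]) / diff(rng)
}
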