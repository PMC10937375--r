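#' Fit reference-batch statistics
#'
#' Captures the per-set mean and (biased, /n) variance of the reference
#' score matrix, plus the reference sample ids. These sufficient statistics
#' define the standardization used by [combat_reference()]: the reference
#' batch itself is never adjusted.
#'
#' @param ref A `score_matrix` or plain sets x samples matrix of reference
#'   (training) scores.
#' @param var_floor Variance floor applied per set (default 1e-8).
#' @return A list of class `batch_model`: `sets`, `ref_mean`, `ref_var`,
#'   `ref_sample_ids`, `n_ref`.
#' @export
fit_reference_batch <- function(ref, var_floor = 1e-8) {
  m <- if (inherits(ref, "score_matrix")) ref$scores else ref
  mu <- rowMeans(m)
  v <- rowMeans((m - mu)^2)       # /n, matching the standardization step
  structure(list(sets = rownames(m), ref_mean = mu,
                 ref_var = pmax(v, var_floor),
                 ref_sample_ids = colnames(m), n_ref = ncol(m)),
            class = "batch_model")
}

# Parametric empirical-Bayes priors for the scale parameters (method of
# moments for the inverse-gamma).
eb_aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
eb_bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

# Iterative solution for the empirical-Bayes batch-effect posteriors.
eb_solve <- function(Z, g_hat, d_hat, g_bar, t2, a, b, tol = 1e-4) {
  n <- ncol(Z)
  g_old <- g_hat; d_old <- d_hat
  repeat {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((Z - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new; d_old <- d_new
    if (change < tol) break
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' Reference-batch ComBat adjustment
#'
#' Two-batch empirical-Bayes location/scale correction in which the
#' reference (training) batch defines the standardization: target scores are
#' standardized by the reference mean/variance, the target batch effects are
#' estimated per set and shrunk toward parametric priors (normal for
#' location, inverse-gamma for scale), and the adjusted values are mapped
#' back onto the reference scale. Target samples whose ids appear among the
#' reference sample ids are returned unchanged.
#'
#' @param target A `score_matrix` or plain sets x samples matrix; its sets
#'   must exactly match the model's sets.
#' @param model A `batch_model` from [fit_reference_batch()].
#' @param shrink Apply empirical-Bayes shrinkage (default `TRUE`). With
#'   `FALSE` the raw batch estimates are used (the no-shrinkage limit, which
#'   removes a pure location shift exactly).
#' @return Adjusted matrix (or `score_matrix`, matching the input type).
#' @export
combat_reference <- function(target, model, shrink = TRUE) {
  stopifnot(inherits(model, "batch_model"))
  is_sm <- inherits(target, "score_matrix")
  m <- if (is_sm) target$scores else target
  if (!identical(rownames(m), model$sets)) {
    if (!setequal(rownames(m), model$sets))
      stop("target sets do not match the batch model's sets")
    m <- m[model$sets, , drop = FALSE]
  }
  is_ref <- colnames(m) %in% model$ref_sample_ids
  adj <- m
  if (any(!is_ref)) {
    tgt <- m[, !is_ref, drop = FALSE]
    n_t <- ncol(tgt)
    sd_ref <- sqrt(model$ref_var)
    Z <- (tgt - model$ref_mean) / sd_ref
    g_hat <- rowMeans(Z)
    if (n_t >= 2L) {
      d_hat <- apply(Z, 1L, stats::var)       # /(n-1), as in the EB scheme
      d_hat <- pmax(d_hat, 1e-8)
    } else {
      d_hat <- rep(1, nrow(Z))                # single sample: location-only
    }
    if (shrink && nrow(Z) >= 2L && n_t >= 2L) {
      g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
      a <- eb_aprior(d_hat); b <- eb_bprior(d_hat)
      if (is.finite(t2) && t2 > 0 && is.finite(a) && is.finite(b)) {
        post <- eb_solve(Z, g_hat, d_hat, g_bar, t2, a, b)
        g_star <- post$gamma_star; d_star <- post$delta_star
      } else {
        g_star <- g_hat; d_star <- d_hat
      }
    } else {
      g_star <- g_hat
      d_star <- if (n_t >= 2L) d_hat else rep(1, nrow(Z))
    }
    adj[, !is_ref] <- ((Z - g_star) / sqrt(d_star)) * sd_ref + model$ref_mean
  }
  if (is_sm) { target$scores <- adj; target } else adj
}
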