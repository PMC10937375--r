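# Support-vector machine with a radial-basis-function kernel, trained by
# solving the dual quadratic program directly (quadprog). One-vs-one
# multiclass with per-pair sigmoid (Platt) calibration and pairwise coupling
# of class probabilities.

#' RBF kernel matrix
#' @param X1,X2 Row-wise sample matrices. @param gamma Kernel width.
#' @return `nrow(X1)` x `nrow(X2)` kernel matrix.
#' @export
rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

# Median heuristic for the kernel width: 1 / median squared distance.
median_gamma <- function(X) {
  d2 <- as.vector(stats::dist(X))^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) return(1)
  1 / stats::median(d2)
}

# Binary soft-margin SVM dual, y in {-1, +1}. Returns alpha, bias.
svm_binary_fit <- function(K, y, cost) {
  n <- length(y)
  D <- (y %o% y) * K
  diag(D) <- diag(D) + 1e-8            # PD safeguard for the QP solver
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1L)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-8 * cost
  f0 <- as.vector(K %*% (alpha * y))   # decision values without bias
  free <- sv & alpha < cost * (1 - 1e-6)
  bias <- if (any(free)) mean(y[free] - f0[free])
          else mean(y[sv] - f0[sv])
  list(alpha = alpha, bias = bias, sv = sv)
}

# Platt sigmoid fit: P(y = +1 | f) = 1 / (1 + exp(A f + B)), with
# prior-corrected targets; Newton iterations with backtracking (Lin et al.).
platt_fit <- function(f, y) {
  prior1 <- sum(y > 0); prior0 <- sum(y < 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t_ <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t_ * z + log1p(exp(-z)), (t_ - 1) * z + log1p(exp(z))))
  }
  fv <- fval(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t_ - p
    d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      An <- A + step * dA; Bn <- B + step * dB
      fn <- fval(An, Bn)
      if (fn < fv + 1e-4 * step * (g1 * dA + g2 * dB) || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB
    fv <- fval(A, B)
  }
  c(A = A, B = B)
}

platt_prob <- function(f, ab) {
  z <- ab[["A"]] * f + ab[["B"]]
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Train a one-vs-one RBF-SVM with calibrated probabilities
#'
#' @param X Samples x features matrix. @param y Class labels (>= 2 classes).
#' @param cost Soft-margin cost. @param gamma Kernel width.
#' @param classes Optional explicit class ordering.
#' @param calib_folds Folds for the cross-validated decision values used to
#'   fit the Platt sigmoids (default 5; sigmoids fitted on training
#'   decision values overfit badly when the classes are separable). Fold
#'   assignment is deterministic (round-robin within class).
#' @return An `svm_ovo` model (support vectors, dual coefficients, biases,
#'   per-pair Platt parameters).
#' @export
svm_ovo_train <- function(X, y, cost, gamma, classes = NULL,
                          calib_folds = 5L, calibrate = TRUE) {
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  stopifnot(length(classes) >= 2L, all(y %in% classes))
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    idx <- which(y %in% pr)
    yy <- ifelse(y[idx] == pr[1L], 1, -1)
    Xp <- X[idx, , drop = FALSE]
    K <- rbf_kernel(Xp, Xp, gamma)
    fit <- svm_binary_fit(K, yy, cost)
    platt <- NULL
    if (calibrate) {
      # sigmoid calibration on cross-validated decision values
      np <- length(yy)
      nf <- max(2L, min(calib_folds, min(table(yy))))
      fold <- integer(np)
      for (cl in c(-1, 1)) {
        w <- which(yy == cl)
        fold[w] <- rep_len(seq_len(nf), length(w))
      }
      f_cv <- numeric(np)
      for (fd in seq_len(nf)) {
        tr <- fold != fd
        sub <- tryCatch(svm_binary_fit(K[tr, tr, drop = FALSE], yy[tr], cost),
                        error = function(e) NULL)
        if (is.null(sub)) { f_cv[!tr] <- 0; next }
        f_cv[!tr] <- as.vector(K[!tr, tr, drop = FALSE] %*%
                                 (sub$alpha * yy[tr])) + sub$bias
      }
      platt <- platt_fit(f_cv, yy)
    }
    keep <- fit$sv
    list(pos = pr[1L], neg = pr[2L],
         X_sv = Xp[keep, , drop = FALSE],
         coef = (fit$alpha * yy)[keep], bias = fit$bias,
         platt = platt)
  })
  structure(list(classes = classes, gamma = gamma, cost = cost,
                 fits = fits), class = "svm_ovo")
}

# Pairwise decision values for new samples: matrix n x n_pairs.
svm_ovo_decision <- function(model, X) {
  vapply(model$fits, function(ft) {
    as.vector(rbf_kernel(X, ft$X_sv, model$gamma) %*% ft$coef) + ft$bias
  }, numeric(nrow(X)))
}

# Couple pairwise probabilities into class probabilities (Wu & Lin, second
# method): solve the KKT linear system, then clip and renormalize.
couple_probs <- function(r_mat, classes, pair_idx) {
  k <- length(classes)
  Q <- matrix(0, k, k)
  for (p in seq_len(nrow(pair_idx))) {
    i <- pair_idx[p, 1L]; j <- pair_idx[p, 2L]
    rij <- r_mat[p]                     # P(class i | i or j)
    rji <- 1 - rij
    Q[i, i] <- Q[i, i] + rji^2
    Q[j, j] <- Q[j, j] + rij^2
    Q[i, j] <- Q[i, j] - rij * rji
    Q[j, i] <- Q[j, i] - rij * rji
  }
  A <- rbind(cbind(Q, rep(1, k)), c(rep(1, k), 0))
  rhs <- c(rep(0, k), 1)
  p <- tryCatch(solve(A, rhs)[seq_len(k)],
                error = function(e) rep(1 / k, k))
  p <- pmax(p, 0)
  p / sum(p)
}

#' Predict calibrated class probabilities from a one-vs-one SVM
#'
#' @param model An `svm_ovo`. @param X Samples x features matrix.
#' @return Samples x classes probability matrix (rows on the simplex).
#' @export
svm_ovo_prob <- function(model, X) {
  dec <- svm_ovo_decision(model, X)
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = nrow(X))
  k <- length(model$classes)
  pair_idx <- t(vapply(model$fits, function(ft)
    c(match(ft$pos, model$classes), match(ft$neg, model$classes)),
    integer(2L)))
  r <- vapply(seq_along(model$fits), function(p)
    platt_prob(dec[, p], model$fits[[p]]$platt), numeric(nrow(X)))
  if (is.null(dim(r))) r <- matrix(r, nrow = nrow(X))
  probs <- t(vapply(seq_len(nrow(X)), function(i)
    couple_probs(r[i, ], model$classes, pair_idx), numeric(k)))
  colnames(probs) <- model$classes
  rownames(probs) <- rownames(X)
  probs
}

# Majority-vote class prediction from pairwise decisions (used in tuning).
svm_ovo_vote <- function(model, X) {
  dec <- svm_ovo_decision(model, X)
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = nrow(X))
  k <- length(model$classes)
  votes <- matrix(0L, nrow(X), k)
  for (p in seq_along(model$fits)) {
    i <- match(model$fits[[p]]$pos, model$classes)
    j <- match(model$fits[[p]]$neg, model$classes)
    win <- ifelse(dec[, p] >= 0, i, j)
    votes[cbind(seq_len(nrow(X)), win)] <- votes[cbind(seq_len(nrow(X)), win)] + 1L
  }
  model$classes[max.col(votes, ties.method = "first")]
}

#' Tune RBF-SVM hyperparameters by leave-one-out cross-validation
#'
#' Evaluates every (cost, gamma) grid point by LOOCV accuracy on the
#' training samples (one-vs-one majority vote) and returns the argmax; ties
#' prefer the smaller cost, then the smaller width.
#'
#' @param X Samples x features matrix. @param y Labels (>= 2 per class).
#' @param cost_grid Costs to try (default 0.25 to 8 by powers of two).
#' @param gamma_grid Kernel widths; default median-heuristic times
#'   `c(0.1, 1, 10)`.
#' @return List: `cost`, `gamma`, `accuracy`, `grid` (all LOOCV accuracies).
#' @export
tune_svm_loocv <- function(X, y, cost_grid = c(0.25, 0.5, 1, 2, 4, 8),
                           gamma_grid = NULL) {
  y <- as.character(y)
  if (any(table(y) < 2L)) stop("every class needs >= 2 samples for LOOCV")
  if (all(apply(X, 2L, stats::var) == 0)) stop("all features are constant")
  if (is.null(gamma_grid)) gamma_grid <- median_gamma(X) * c(0.1, 1, 10)
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  n <- nrow(X)
  classes <- sort(unique(y))
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  # the kernel depends only on gamma: precompute once per width, and only
  # refit the pairs that actually contain the held-out sample
  grid$accuracy <- NA_real_
  for (gam in unique(grid$gamma)) {
    K <- rbf_kernel(X, X, gam)
    pair_idx <- lapply(pairs, function(pr) which(y %in% pr))
    for (g in which(grid$gamma == gam)) {
      cost <- grid$cost[g]
      full <- lapply(seq_along(pairs), function(p) {
        idx <- pair_idx[[p]]
        yy <- ifelse(y[idx] == pairs[[p]][1L], 1, -1)
        fit <- svm_binary_fit(K[idx, idx, drop = FALSE], yy, cost)
        list(idx = idx, yy = yy, fit = fit)
      })
      votes <- matrix(0L, n, length(classes))
      for (p in seq_along(pairs)) {
        idx <- full[[p]]$idx; yy <- full[[p]]$yy
        ci <- match(pairs[[p]][1L], classes)
        cj <- match(pairs[[p]][2L], classes)
        for (i in seq_len(n)) {
          if (i %in% idx) {
            pos <- match(i, idx)
            sub <- svm_binary_fit(K[idx[-pos], idx[-pos], drop = FALSE],
                                  yy[-pos], cost)
            f <- sum(K[i, idx[-pos]] * (sub$alpha * yy[-pos])) + sub$bias
          } else {
            f <- sum(K[i, idx] * (full[[p]]$fit$alpha * yy)) +
              full[[p]]$fit$bias
          }
          win <- if (f >= 0) ci else cj
          votes[i, win] <- votes[i, win] + 1L
        }
      }
      pred <- classes[max.col(votes, ties.method = "first")]
      grid$accuracy[g] <- mean(pred == y)
    }
  }
  best <- order(-grid$accuracy, grid$cost, grid$gamma)[1L]
  list(cost = grid$cost[best], gamma = grid$gamma[best],
       accuracy = grid$accuracy[best], grid = grid)
}
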