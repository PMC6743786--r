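# Soft-margin kernel SVM via sequential minimal optimization (SMO).
# Implemented in-package because the environment provides no SVM library.
# Dual problem: min_a 1/2 a' Q a - e' a, 0 <= a <= C, y' a = 0,
# with Q_ij = y_i y_j K(x_i, x_j); maximal-violating-pair working set
# selection and incremental gradient updates.

.kernel_matrix <- function(X, X2 = NULL, kernel = c("linear", "rbf"), sigma = 1) {
  kernel <- match.arg(kernel)
  if (is.null(X2)) X2 <- X
  if (kernel == "linear") return(tcrossprod(X, X2))
  d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

# y in {-1, +1}; returns signed dual coefficients (alpha_i y_i) and bias
.smo_train <- function(K, y, C, tol = 1e-3) {
  n <- length(y)
  a <- numeric(n)
  G <- rep(-1, n)                       # gradient of the dual objective
  max_iter <- max(300L * n, 10000L)
  for (it in seq_len(max_iter)) {
    yG <- -y * G
    up <- (y > 0 & a < C - 1e-12) | (y < 0 & a > 1e-12)
    lo <- (y < 0 & a < C - 1e-12) | (y > 0 & a > 1e-12)
    if (!any(up) || !any(lo)) break
    iu <- which(up); il <- which(lo)
    i <- iu[which.max(yG[iu])]
    j <- il[which.min(yG[il])]
    if (yG[i] - yG[j] < tol) break
    s <- y[i] * y[j]
    # pair curvature: the label signs cancel, same form for both cases
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 1e-12) quad <- 1e-12
    ai_old <- a[i]; aj_old <- a[j]
    if (s < 0) {                        # opposite labels
      delta <- (-G[i] - G[j]) / quad
      ai <- ai_old + delta; aj <- aj_old + delta
      diff <- ai_old - aj_old
      if (diff > 0) { L_i <- diff; H_i <- C } else { L_i <- 0; H_i <- C + diff }
      ai <- min(max(ai, L_i), H_i); aj <- ai - diff
    } else {                            # same labels
      delta <- (G[i] - G[j]) / quad
      ssum <- ai_old + aj_old
      ai <- ai_old - delta
      L_i <- max(0, ssum - C); H_i <- min(C, ssum)
      ai <- min(max(ai, L_i), H_i); aj <- ssum - ai
    }
    a[i] <- ai; a[j] <- aj
    # Q columns: Q[, i] = y * y_i * K[, i]
    G <- G + (y * y[i] * K[, i]) * (ai - ai_old) +
             (y * y[j] * K[, j]) * (aj - aj_old)
  }
  fsv <- which(a > 1e-8 & a < C - 1e-8)
  f_no_b <- as.numeric(K %*% (a * y))
  b <- if (length(fsv)) mean(y[fsv] - f_no_b[fsv]) else {
    sv <- which(a > 1e-8)
    if (length(sv)) mean(y[sv] - f_no_b[sv]) else 0
  }
  list(coefs = a * y, b = b)
}

# binary SVM fit on raw data; labels must have exactly two levels, mapped to
# (-1, +1) in the order given
.svm_binary_fit <- function(X, y01, kernel, sigma, C) {
  K <- .kernel_matrix(X, kernel = kernel, sigma = sigma)
  sol <- .smo_train(K, y01, C)
  keep <- abs(sol$coefs) > 1e-10
  list(X_sv = X[keep, , drop = FALSE], coefs = sol$coefs[keep], b = sol$b,
       kernel = kernel, sigma = sigma, C = C)
}

.svm_binary_decision <- function(fit, X) {
  if (!nrow(fit$X_sv)) return(rep(fit$b, nrow(X)))
  Kx <- .kernel_matrix(X, fit$X_sv, kernel = fit$kernel, sigma = fit$sigma)
  as.numeric(Kx %*% fit$coefs) + fit$b
}

# median pairwise Euclidean distance (subsampled), the reference scale for
# the rbf kernel width grid
.median_pairwise_dist <- function(X, max_n = 300L, seed = 1L) {
  n <- nrow(X)
  if (n > max_n) {
    set.seed(seed)
    X <- X[sample.int(n, max_n), , drop = FALSE]
  }
  d <- stats::dist(X)
  md <- stats::median(d[d > 0])
  if (!is.finite(md) || md <= 0) 1 else md
}
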