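#' Decoder specification
#'
#' Describes a model-free decoding method and its hyperparameter grids.
#' Cross-validation defaults: 5-fold on the training split; \code{C} grid
#' \{0.1, 1, 10, 100\}; rbf width grid = median pairwise distance times
#' \{0.25, 0.5, 1, 2, 4\}; Gaussian-decoder ridge \eqn{\lambda} grid
#' log-spaced \eqn{10^{-4}..10^{1}} relative to the mean diagonal variance.
#'
#' @param method one of \code{"svm-linear"}, \code{"svm-rbf"},
#'   \code{"gaussian-decoder"}, \code{"mlp"}.
#' @param C_grid soft-margin constants to cross-validate (SVMs).
#' @param sigma_mult rbf width multipliers of the median pairwise distance.
#' @param lambda_grid relative ridge grid (Gaussian decoder).
#' @param hidden hidden layer sizes (MLP).
#' @param dropout,epochs,batch MLP training budget.
#' @param cv_folds folds for hyperparameter cross-validation.
#' @return object of class \code{decoder_spec}.
#' @export
decoder_spec <- function(method = c("svm-linear", "svm-rbf", "gaussian-decoder", "mlp"),
                         C_grid = c(0.1, 1, 10, 100),
                         sigma_mult = c(0.25, 0.5, 1, 2, 4),
                         lambda_grid = 10^seq(-4, 1, length.out = 6),
                         hidden = c(300L, 200L), dropout = 0.2,
                         epochs = 200L, batch = 128L, cv_folds = 5L) {
  method <- match.arg(method)
  stopifnot(all(C_grid > 0), all(sigma_mult > 0), all(lambda_grid > 0),
            cv_folds >= 2L)
  structure(list(method = method, C_grid = C_grid, sigma_mult = sigma_mult,
                 lambda_grid = lambda_grid, hidden = as.integer(hidden),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch = as.integer(batch), cv_folds = as.integer(cv_folds)),
            class = "decoder_spec")
}

# stratified fold assignment
.strat_folds <- function(y, k, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  f
}

#' Fit a model-free decoder on labeled training data
#'
#' Trains the decoding function \eqn{F_\omega} of the requested method.
#' SVMs: soft-margin with linear or rbf kernel; \code{C} (and the rbf width)
#' are selected by internal cross-validation on the training data only; more
#' than two classes are handled by a dendrogram-SVM (binary SVMs on a
#' hierarchy obtained by average-linkage clustering of the class means).
#' Gaussian decoder: per-class mean and covariance with diagonal (ridge)
#' regularization \eqn{\Sigma + \lambda I}; \eqn{\lambda} maximizes held-out
#' validation log-likelihood. MLP: fully connected network (default 300-200
#' hidden ELU units), He initialization, Adam with batch normalization and
#' dropout, early stopping on a validation split.
#'
#' @param train a [labeled_dataset()] with at least two classes.
#' @param spec a [decoder_spec()].
#' @param prior prior over labels used by the Gaussian decoder's posterior
#'   (defaults to training frequencies).
#' @param seed seed for cross-validation splits and initialization.
#' @return an object of class \code{decoder} (subclass per method) with a
#'   \code{predict} method mapping a matrix of trajectories to labels.
#' @export
fit_decoder <- function(train, spec, prior = NULL, seed = 1L) {
  X <- train$X; y <- train$labels
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes")
  fit <- switch(spec$method,
    "svm-linear" = .fit_svm_decoder(X, y, classes, "linear", spec, seed),
    "svm-rbf" = .fit_svm_decoder(X, y, classes, "rbf", spec, seed),
    "gaussian-decoder" = .fit_gaussian_decoder(X, y, classes, spec, prior, seed),
    "mlp" = .mlp_train(X, y, hidden = spec$hidden, dropout = spec$dropout,
                       batch = spec$batch, epochs = spec$epochs, seed = seed))
  structure(list(method = spec$method, fit = fit, classes = classes),
            class = c(paste0(gsub("-", "_", spec$method), "_decoder"), "decoder"))
}

#' @export
predict.decoder <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) newdata$X else as.matrix(newdata)
  switch(object$method,
    "svm-linear" = , "svm-rbf" = .predict_svm_decoder(object$fit, X),
    "gaussian-decoder" = .predict_gaussian_decoder(object$fit, X),
    "mlp" = .mlp_predict(object$fit, X))
}

#' @export
print.decoder <- function(x, ...) {
  cat("Trained decoder:", x$method, "| classes:",
      paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# ---- SVM decoder (binary + dendrogram multiclass) --------------------------

.fit_svm_decoder <- function(X, y, classes, kernel, spec, seed) {
  sigma_grid <- if (kernel == "rbf")
    .median_pairwise_dist(X, seed = seed) * spec$sigma_mult else NA_real_
  if (length(classes) == 2L) {
    node <- .svm_cv_fit(X, y, classes, kernel, spec, sigma_grid, seed)
    list(kind = "binary", node = node, classes = classes)
  } else {
    # dendrogram-SVM: average-linkage tree over class-mean distances,
    # a binary SVM at every internal node separating left from right leaves
    mu <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                   numeric(ncol(X))))
    hc <- stats::hclust(stats::dist(mu), method = "average")
    nodes <- list()
    groups <- list()      # node id -> list(left labels, right labels)
    leafset <- function(i) if (i < 0) classes[-i] else groups[[i]]$all
    for (nd in seq_len(nrow(hc$merge))) {
      l <- hc$merge[nd, 1L]; r <- hc$merge[nd, 2L]
      left <- leafset(l); right <- leafset(r)
      sel <- y %in% c(left, right)
      yy <- ifelse(y[sel] %in% left, classes[1L], classes[2L]) # temp 2-level
      node <- .svm_cv_fit(X[sel, , drop = FALSE], yy,
                          classes[1:2], kernel, spec, sigma_grid, seed + nd)
      nodes[[nd]] <- node
      groups[[nd]] <- list(left = left, right = right, all = c(left, right),
                           child_l = l, child_r = r)
    }
    list(kind = "dsvm", nodes = nodes, groups = groups, classes = classes)
  }
}

# cross-validated binary SVM: picks (C, sigma) by k-fold accuracy on train
.svm_cv_fit <- function(X, y, classes, kernel, spec, sigma_grid, seed) {
  y01 <- ifelse(y == classes[1L], -1, 1)
  grid <- if (kernel == "rbf")
    expand.grid(C = spec$C_grid, sigma = sigma_grid)
  else expand.grid(C = spec$C_grid, sigma = NA_real_)
  if (nrow(grid) > 1L) {
    folds <- .strat_folds(y, spec$cv_folds, seed)
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      ok <- 0L; tot <- 0L
      for (f in seq_len(spec$cv_folds)) {
        tr <- folds != f
        fit <- .svm_binary_fit(X[tr, , drop = FALSE], y01[tr], kernel,
                               grid$sigma[g], grid$C[g])
        pr <- sign(.svm_binary_decision(fit, X[!tr, , drop = FALSE]))
        pr[pr == 0] <- -1
        ok <- ok + sum(pr == y01[!tr]); tot <- tot + sum(!tr)
      }
      acc[g] <- ok / tot
    }
    best <- grid[which.max(acc), ]
  } else best <- grid[1L, ]
  fit <- .svm_binary_fit(X, y01, kernel, best$sigma, best$C)
  fit$classes <- classes
  fit
}

.predict_svm_decoder <- function(fit, X) {
  if (fit$kind == "binary") {
    dv <- .svm_binary_decision(fit$node, X)
    ifelse(dv < 0, fit$classes[1L], fit$classes[2L])
  } else {
    out <- character(nrow(X))
    root <- length(fit$nodes)
    descend <- function(rows, nd) {
      if (!length(rows)) return()
      g <- fit$groups[[nd]]
      dv <- .svm_binary_decision(fit$nodes[[nd]], X[rows, , drop = FALSE])
      goleft <- dv < 0
      for (side in c("l", "r")) {
        rr <- rows[if (side == "l") goleft else !goleft]
        child <- if (side == "l") g$child_l else g$child_r
        labs <- if (side == "l") g$left else g$right
        if (!length(rr)) next
        if (child < 0) out[rr] <<- labs
        else descend(rr, child)
      }
    }
    descend(seq_len(nrow(X)), root)
    out
  }
}

# ---- Gaussian decoder ------------------------------------------------------

# per-class Gaussian with ridge Sigma + lambda*I; lambda chosen on a held-out
# 20% validation split of the training data by conditional log-likelihood
.fit_gaussian_decoder <- function(X, y, classes, spec, prior, seed) {
  if (is.null(prior)) {
    prior <- as.numeric(table(factor(y, classes))) / length(y)
  }
  set.seed(seed)
  vi <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl); sample(idx, max(1L, round(0.2 * length(idx))))
  }))
  ti <- setdiff(seq_along(y), vi)
  stats_of <- function(rows) {
    lapply(classes, function(cl) {
      Xi <- X[rows[y[rows] == cl], , drop = FALSE]
      list(mu = colMeans(Xi), S = stats::cov(Xi), n = nrow(Xi))
    })
  }
  st_tr <- stats_of(ti)
  scale0 <- mean(vapply(st_tr, function(s) mean(diag(s$S)), numeric(1)))
  if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1
  lambdas <- spec$lambda_grid * scale0
  best <- NULL; best_ll <- -Inf
  for (lam in lambdas) {
    mods <- lapply(st_tr, function(s) .gauss_chol(s$mu, s$S, lam))
    if (any(vapply(mods, is.null, logical(1)))) next
    ll <- 0
    for (j in seq_along(classes)) {
      rows <- vi[y[vi] == classes[j]]
      if (length(rows))
        ll <- ll + sum(.gauss_logdens(mods[[j]], X[rows, , drop = FALSE]))
    }
    if (ll > best_ll) { best_ll <- ll; best <- lam }
  }
  if (is.null(best))
    stop("ill-conditioned covariance for every lambda in the grid; ",
         "widen lambda_grid")
  # refit on the full training data at the chosen lambda
  st_all <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xi), S = stats::cov(Xi))
  })
  mods <- lapply(st_all, function(s) .gauss_chol(s$mu, s$S, best))
  if (any(vapply(mods, is.null, logical(1))))
    stop("ill-conditioned covariance after regularization at lambda = ", best)
  list(classes = classes, prior = prior, lambda = best, models = mods)
}

.gauss_chol <- function(mu, S, lambda) {
  Sr <- S + diag(lambda, nrow(S))
  R <- tryCatch(chol(Sr), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  list(mu = mu, R = R, logdet = 2 * sum(log(diag(R))))
}

# multivariate normal log density (natural log) via the Cholesky factor
.gauss_logdens <- function(m, X) {
  Z <- backsolve(m$R, t(sweep(X, 2L, m$mu)), transpose = TRUE)
  -0.5 * (colSums(Z^2) + m$logdet + ncol(X) * log(2 * pi))
}

.predict_gaussian_decoder <- function(fit, X) {
  scores <- vapply(seq_along(fit$classes), function(j)
    .gauss_logdens(fit$models[[j]], X) + log(fit$prior[j]),
    numeric(nrow(X)))
  if (nrow(X) == 1L) scores <- matrix(scores, 1L)
  fit$classes[max.col(scores, ties.method = "first")]
}

# ---- decoding information estimate ----------------------------------------

#' Decoding-based information estimate with train/test replication
#'
#' For each replicate: draw a stratified train/test split (default 70/30),
#' fit the decoder on the training part only, decode the held-out part,
#' build the confusion matrix and evaluate its plug-in information. Returns
#' mean and standard deviation over replicates. By the data processing
#' inequality the population value lower-bounds the trajectory information.
#'
#' @param data a [labeled_dataset()].
#' @param spec a [decoder_spec()].
#' @param train_frac training fraction (default 0.7).
#' @param replicates number of random re-splits (default 20).
#' @param seed seed controlling the splits and decoder initialization.
#' @return an \code{info_result} (bits), with per-replicate values and the
#'   last confusion matrix attached.
#' @export
estimate_info <- function(data, spec, train_frac = 0.7, replicates = 20L,
                          seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  y <- data$labels
  classes <- sort(unique(y))
  vals <- numeric(replicates)
  eps <- NULL
  for (r in seq_len(replicates)) {
    set.seed(.substream_seed(seed, 15485863L * r))
    tr <- unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(train_frac * length(idx))))
    }))
    te <- setdiff(seq_along(y), tr)
    train <- labeled_dataset(data$X[tr, , drop = FALSE], y[tr],
                             x0 = data$x0, dt = data$dt, T_end = data$T)
    dec <- fit_decoder(train, spec, seed = .substream_seed(seed, 32452843L * r))
    pred <- predict(dec, data$X[te, , drop = FALSE])
    eps <- confusion_matrix(y[te], pred, labels = classes)
    vals[r] <- info_from_confusion(eps)
  }
  structure(list(value = mean(vals), std = stats::sd(vals),
                 H_X = NA_real_, H_XgU = NA_real_,
                 N = length(y) / length(classes), mode = "decoder",
                 d = ncol(data$X), T = data$T, replicates = vals,
                 confusion = eps, method = spec$method),
            class = "info_result")
}

#' Shuffle the labels of a dataset (negative control)
#'
#' Random label permutation destroys all response-input dependence; any
#' estimator run on the shuffled data should report zero information within
#' its error bars, providing a small-sample bias control.
#'
#' @param data a [labeled_dataset()].
#' @param seed permutation seed.
#' @return the dataset with permuted labels.
#' @export
shuffle_labels <- function(data, seed = 1L) {
  set.seed(seed)
  data$labels <- sample(data$labels)
  data$provenance <- paste0(data$provenance, " [label-shuffled]")
  data
}

# ---- knn mutual information (discrete label, continuous response) ----------

#' k-nearest-neighbor mutual information between trajectories and labels
#'
#' Kraskov-type estimator specialized to a discrete label (Ross variant):
#' for every point, take the distance to its k-th nearest neighbour within
#' its own class, count how many points of the full sample fall within that
#' distance, and combine digamma terms:
#' \deqn{\hat I = \psi(N) - \langle\psi(N_u)\rangle + \psi(k) -
#'   \langle\psi(m_i)\rangle,}
#' converted to bits. The default metric is the max-norm of the classic
#' Kraskov construction; under it, integer-valued trajectories produce heavy
#' distance ties (whole lattice shells at the neighbour radius), which
#' inflate the counts \eqn{m_i} and can drive the estimate strongly
#' negative. Adding a small iid Gaussian jitter to every component
#' (\code{jitter_sd}) breaks the ties and is the documented repair. Negative
#' estimates are reported faithfully.
#'
#' @param data a [labeled_dataset()].
#' @param k number of neighbours (default 1, must be below the smallest
#'   class count).
#' @param jitter_sd standard deviation of the optional jitter (0 = none).
#' @param seed jitter seed.
#' @param metric \code{"chebyshev"} (max-norm, default) or
#'   \code{"euclidean"}.
#' @return estimated information in bits (may be negative).
#' @export
knn_mutual_information <- function(data, k = 1L, jitter_sd = 0, seed = 1L,
                                   metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  X <- data$X
  y <- data$labels
  n <- nrow(X)
  counts <- table(y)
  if (k >= min(counts)) stop("k must be smaller than the smallest class count")
  if (jitter_sd > 0) {
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), 0, jitter_sd), n)
  }
  r_i <- numeric(n)          # distance to kth same-class neighbour
  m_i <- numeric(n)          # neighbours within r_i in the full sample
  sq <- rowSums(X^2)
  ties <- FALSE
  chunk <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n)
    if (metric == "euclidean") {
      D2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
      D2[D2 < 0] <- 0
      D <- sqrt(D2)
    } else {
      D <- matrix(0, length(rows), n)
      for (j in seq_len(ncol(X)))
        D <- pmax(D, abs(outer(X[rows, j], X[, j], "-")))
    }
    for (ii in seq_along(rows)) {
      i <- rows[ii]
      same <- which(y == y[i]); same <- same[same != i]
      ds <- D[ii, same]
      r <- sort(ds, partial = k)[k]
      if (r == 0) ties <- TRUE
      r_i[i] <- r
      m_i[i] <- sum(D[ii, ] <= r) - 1L    # exclude the point itself
    }
  }
  if (ties && jitter_sd == 0)
    warning("zero kth-neighbour distances (tied points); counts include all ",
            "coincident points -- consider jitter_sd > 0")
  (digamma(n) - mean(digamma(as.numeric(counts[y]))) +
      digamma(k) - mean(digamma(pmax(m_i, 1)))) / log(2)
}

# ---- Gaussian approximation of the information -----------------------------

#' Gaussian-approximation information (parametric baseline)
#'
#' Fits a multivariate Gaussian per class; the conditional entropy is the
#' analytic \eqn{H_G(X|u) = \frac12 \log_2\det(2\pi e\,\Sigma(u))}, the
#' mixture entropy \eqn{H_G(X)} is evaluated by Monte-Carlo draws from the
#' fitted mixture scored against the mixture density. Unlike the decoding
#' estimators this approximation is not a bound: it can overshoot the true
#' information (a warning is attached when the value exceeds the label
#' entropy).
#'
#' @param data a [labeled_dataset()].
#' @param n_mc Monte-Carlo sample size for the mixture entropy.
#' @param lambda optional ridge added to each class covariance.
#' @param seed Monte-Carlo seed.
#' @return information estimate in bits.
#' @export
gaussian_approximation_info <- function(data, n_mc = 5000L, lambda = 0,
                                        seed = 1L) {
  X <- data$X; y <- data$labels
  classes <- sort(unique(y))
  q <- length(classes)
  prior <- as.numeric(table(factor(y, classes))) / length(y)
  d <- ncol(X)
  mods <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    S <- stats::cov(Xi)
    m <- .gauss_chol(colMeans(Xi), S, lambda)
    if (is.null(m))
      stop("non-positive-definite class covariance; supply lambda > 0")
    m
  })
  # H(X|U): analytic, in bits
  HXgU <- sum(prior * vapply(mods, function(m)
    0.5 * (m$logdet + d * log(2 * pi * exp(1))) / log(2), numeric(1)))
  # H(X): MC over the fitted mixture
  set.seed(seed)
  ns <- stats::rmultinom(1L, n_mc, prior)[, 1L]
  lp <- numeric(0)
  for (j in seq_len(q)) {
    if (ns[j] == 0L) next
    Sj <- crossprod(mods[[j]]$R)
    Z <- MASS::mvrnorm(ns[j], mods[[j]]$mu, Sj)
    if (ns[j] == 1L) Z <- matrix(Z, 1L)
    comp <- vapply(seq_len(q), function(l)
      .gauss_logdens(mods[[l]], Z) + log(prior[l]), numeric(ns[j]))
    if (ns[j] == 1L) comp <- matrix(comp, 1L)
    mx <- apply(comp, 1L, max)
    lp <- c(lp, (mx + log(rowSums(exp(comp - mx)))) / log(2))
  }
  HX <- -mean(lp)
  out <- HX - HXgU
  if (out > log2(q) + 1e-9)
    warning("Gaussian approximation exceeds the label entropy (overestimate)")
  out
}

# ---- exponential filtering -------------------------------------------------

#' Causal exponential (low-pass) filtering of trajectories
#'
#' Row-wise exponential moving average along the time axis with timescale
#' \eqn{\tau} (same units as the grid spacing): \eqn{y_i = a y_{i-1} +
#' (1-a) x_i}, \eqn{a = e^{-\Delta t/\tau}}, initialized at \eqn{y_1 = x_1}
#' so constant rows pass through unchanged. As \eqn{\tau \to 0} the filter
#' approaches the identity.
#'
#' @param data a [labeled_dataset()].
#' @param tau filter timescale (> 0).
#' @return the dataset with real-valued filtered trajectories.
#' @export
exponential_filter <- function(data, tau) {
  if (tau <= 0) stop("tau must be > 0")
  dt <- if (!is.null(data$dt)) data$dt else 1
  a <- exp(-dt / tau)
  X <- data$X
  n <- nrow(X); d <- ncol(X)
  Y <- matrix(0, n, d)
  prev <- X[, 1L]
  Y[, 1L] <- prev
  for (i in seq_len(d)[-1L]) {
    prev <- a * prev + (1 - a) * X[, i]
    Y[, i] <- prev
  }
  data$X <- Y
  data$provenance <- paste0(data$provenance, sprintf(" [exp-filtered tau=%g]", tau))
  data
}
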