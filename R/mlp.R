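# Minimal multilayer perceptron classifier (fully connected, ELU units,
# He initialization, Adam, batch normalization, inverted dropout, softmax
# cross-entropy, early stopping on a validation split). Written in base R
# matrix operations; no deep-learning library is available in this stack.

.elu <- function(z, alpha = 1) ifelse(z > 0, z, alpha * (exp(pmin(z, 0)) - 1))
.elu_grad <- function(z, alpha = 1) ifelse(z > 0, 1, alpha * exp(pmin(z, 0)))

.mlp_init <- function(sizes, seed) {
  set.seed(seed)
  L <- length(sizes) - 1L
  lapply(seq_len(L), function(l) {
    nin <- sizes[l]; nout <- sizes[l + 1L]
    list(W = matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
         gamma = rep(1, nout), beta = rep(0, nout),
         run_mean = rep(0, nout), run_var = rep(1, nout))
  })
}

# forward pass; batchnorm in train mode uses batch statistics and updates
# running averages in-place (returned), hidden layers get dropout mask
.mlp_forward <- function(layers, X, train, dropout, momentum = 0.9) {
  L <- length(layers)
  acts <- vector("list", L + 1L)
  cache <- vector("list", L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    ly <- layers[[l]]
    Z <- acts[[l]] %*% ly$W
    if (train) {
      mu <- colMeans(Z)
      va <- colMeans(Z^2) - mu^2
      layers[[l]]$run_mean <- momentum * ly$run_mean + (1 - momentum) * mu
      layers[[l]]$run_var <- momentum * ly$run_var + (1 - momentum) * va
    } else {
      mu <- ly$run_mean; va <- ly$run_var
    }
    sdv <- sqrt(va + 1e-5)
    Zh <- sweep(sweep(Z, 2L, mu), 2L, sdv, "/")
    Zs <- sweep(sweep(Zh, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    if (l < L) {
      A <- .elu(Zs)
      if (train && dropout > 0) {
        mask <- matrix(stats::rbinom(length(A), 1L, 1 - dropout), nrow(A)) /
          (1 - dropout)
        A <- A * mask
      } else mask <- NULL
      cache[[l]] <- list(Z = Z, Zh = Zh, Zs = Zs, mu = mu, sdv = sdv, mask = mask)
      acts[[l + 1L]] <- A
    } else {
      cache[[l]] <- list(Z = Z, Zh = Zh, Zs = Zs, mu = mu, sdv = sdv)
      acts[[l + 1L]] <- Zs        # logits
    }
  }
  list(layers = layers, acts = acts, cache = cache)
}

.softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

# backward pass; returns gradients for W, gamma, beta per layer
.mlp_backward <- function(layers, fw, Y1hot) {
  L <- length(layers)
  n <- nrow(Y1hot)
  grads <- vector("list", L)
  P <- .softmax(fw$acts[[L + 1L]])
  dZs <- (P - Y1hot) / n                       # dLoss/dlogits
  for (l in L:1) {
    ca <- fw$cache[[l]]
    if (l < L) {
      if (!is.null(ca$mask)) dZs <- dZs * ca$mask
      dZs <- dZs * .elu_grad(ca$Zs)
    }
    dgamma <- colSums(dZs * ca$Zh)
    dbeta <- colSums(dZs)
    # backprop through batch normalization
    dZh <- sweep(dZs, 2L, layers[[l]]$gamma, "*")
    m <- nrow(dZh)
    dZ <- sweep(dZh - matrix(colMeans(dZh), m, ncol(dZh), byrow = TRUE) -
                  sweep(ca$Zh, 2L, colMeans(dZh * ca$Zh), "*"),
                2L, ca$sdv, "/")
    dW <- crossprod(fw$acts[[l]], dZ)
    grads[[l]] <- list(W = dW, gamma = dgamma, beta = dbeta)
    if (l > 1L) dZs <- tcrossprod(dZ, layers[[l]]$W)
  }
  grads
}

.mlp_train <- function(X, y, hidden = c(300L, 200L), dropout = 0.2,
                       lr = 1e-3, batch = 128L, epochs = 200L,
                       val_frac = 0.15, patience = 15L, seed = 1L) {
  classes <- sort(unique(y))
  q <- length(classes)
  Y <- match(y, classes)
  sizes <- c(ncol(X), hidden, q)
  layers <- .mlp_init(sizes, seed)
  L <- length(layers)
  # standardize inputs (helps Adam at these scales); constants kept for predict
  mu_x <- colMeans(X); sd_x <- pmax(apply(X, 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, mu_x), 2L, sd_x, "/")
  set.seed(seed + 1L)
  n <- nrow(Xs)
  # stratified validation split for early stopping
  vi <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(val_frac * length(idx))))
  }))
  ti <- setdiff(seq_len(n), vi)
  Xtr <- Xs[ti, , drop = FALSE]; Ytr <- Y[ti]
  Xva <- Xs[vi, , drop = FALSE]; Yva <- Y[vi]
  # Adam state
  mstate <- lapply(layers, function(ly) list(W = ly$W * 0, gamma = ly$gamma * 0,
                                             beta = ly$beta * 0))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; epsd <- 1e-8
  step <- 0L
  best_loss <- Inf; best_layers <- layers; stall <- 0L
  ntr <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    for (start in seq(1L, ntr, by = batch)) {
      bi <- ord[start:min(start + batch - 1L, ntr)]
      if (length(bi) < 2L) next           # batchnorm needs >= 2 rows
      Y1 <- matrix(0, length(bi), q); Y1[cbind(seq_along(bi), Ytr[bi])] <- 1
      fw <- .mlp_forward(layers, Xtr[bi, , drop = FALSE], train = TRUE,
                         dropout = dropout)
      layers <- fw$layers                 # running batchnorm stats
      gr <- .mlp_backward(layers, fw, Y1)
      step <- step + 1L
      for (l in seq_len(L)) {
        for (p in c("W", "gamma", "beta")) {
          g <- gr[[l]][[p]]
          mstate[[l]][[p]] <- b1 * mstate[[l]][[p]] + (1 - b1) * g
          vstate[[l]][[p]] <- b2 * vstate[[l]][[p]] + (1 - b2) * g^2
          mhat <- mstate[[l]][[p]] / (1 - b1^step)
          vhat <- vstate[[l]][[p]] / (1 - b2^step)
          layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + epsd)
        }
      }
    }
    # validation cross-entropy for early stopping
    fv <- .mlp_forward(layers, Xva, train = FALSE, dropout = 0)
    P <- .softmax(fv$acts[[L + 1L]])
    vloss <- -mean(log(pmax(P[cbind(seq_along(Yva), Yva)], 1e-12)))
    if (vloss < best_loss - 1e-5) {
      best_loss <- vloss; best_layers <- layers; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  list(layers = best_layers, classes = classes, mu_x = mu_x, sd_x = sd_x,
       val_loss = best_loss)
}

.mlp_predict <- function(fit, X) {
  Xs <- sweep(sweep(X, 2L, fit$mu_x), 2L, fit$sd_x, "/")
  L <- length(fit$layers)
  fw <- .mlp_forward(fit$layers, Xs, train = FALSE, dropout = 0)
  fit$classes[max.col(fw$acts[[L + 1L]], ties.method = "first")]
}
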