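#' MAP decoding of a single trajectory
#'
#' Returns the input label maximizing the log-posterior
#' \eqn{\log p(x|u) + \log p_U(u)} under the exact path-likelihood model,
#' for continuous or resampled trajectories. Ties are broken deterministically
#' in favour of the smallest label index.
#'
#' @param traj a \code{ctraj} or \code{dtraj}.
#' @param model a [path_model()].
#' @return list with \code{decoded} (label), \code{scores} (named per-input
#'   log2-posterior scores, up to the shared marginal normalizer).
#' @export
map_decode <- function(traj, model) {
  ens <- model$ensemble
  scores <- vapply(ens$labels, function(u) .cond_loglik(traj, model, u),
                   numeric(1)) + log2(ens$prior)
  if (all(!is.finite(scores))) stop("decode failure: all inputs impossible")
  list(decoded = ens$labels[which.max(scores)], scores = scores)
}

#' Confusion matrix of true versus decoded inputs
#'
#' Joint frequency table: entry \eqn{(i, j)} is the fraction of test paths
#' with true input \eqn{u^{(i)}} decoded as \eqn{u^{(j)}}; all entries sum
#' to one.
#'
#' @param true vector of true labels.
#' @param decoded vector of decoded labels (same length).
#' @param labels the full ordered label set (so empty rows/columns are kept).
#' @return a q x q matrix of class \code{confusion_matrix} with attribute
#'   \code{N_test}.
#' @export
confusion_matrix <- function(true, decoded, labels = sort(unique(true))) {
  stopifnot(length(true) == length(decoded))
  f <- function(v) factor(as.character(v), levels = labels)
  tab <- table(true = f(true), decoded = f(decoded))
  eps <- unclass(tab) / length(true)
  attr(eps, "N_test") <- length(true)
  class(eps) <- c("confusion_matrix", "matrix")
  eps
}

#' Plug-in mutual information of a confusion matrix
#'
#' \deqn{I(\hat U; U) = \sum_{ij} \epsilon_{ij} \log_2
#'   \frac{\epsilon_{ij}}{(\sum_k \epsilon_{kj})(\sum_l \epsilon_{il})}}
#' with the convention \eqn{0 \log 0 = 0}. This is the decoding lower bound
#' on the trajectory information, by the data processing inequality.
#'
#' @param eps q x q joint frequency table (entries sum to 1).
#' @return information in bits, in \eqn{[0, \log_2 q]}.
#' @export
info_from_confusion <- function(eps) {
  eps <- unclass(as.matrix(eps))
  if (any(eps < 0)) stop("confusion matrix entries must be non-negative")
  if (abs(sum(eps) - 1) > 1e-8) stop("confusion matrix must sum to 1")
  rs <- rowSums(eps); cs <- colSums(eps)
  nz <- eps > 0
  sum(eps[nz] * log2(eps[nz] / (outer(rs, cs)[nz])))
}

# phi and alpha of the confusion-matrix upper bound, built from floor/ceiling
# of 1/(1-pi); phi(0) = 0 and phi caps at log2(q) as pi -> 1
.phi_alpha <- function(pi_err, qmax = Inf) {
  stopifnot(pi_err >= 0, pi_err <= 1)
  if (pi_err >= 1) return(list(phi = log2(qmax), alpha = NA_real_))
  inv <- 1 / (1 - pi_err)
  fl <- floor(inv + 1e-12); ce <- ceiling(inv - 1e-12)
  al <- fl * ((1 - pi_err) * ce - 1)
  phi <- al * log2(fl) + (1 - al) * log2(ce)
  if (is.finite(qmax)) phi <- min(phi, log2(qmax))
  list(phi = phi, alpha = al)
}

#' Confusion-matrix upper bound on the mutual information
#'
#' An improvement of the Feder-Merhav bound that uses the full MAP confusion
#' matrix rather than the overall error probability:
#' \deqn{I(U;X) \le H(U) - \sum_{\hat u} p_{\hat U}(\hat u)\,
#'   \phi(\pi_{\hat u}),}
#' where \eqn{\pi_{\hat u} = 1 - \Pr(U = \hat u \mid \hat U = \hat u)} is the
#' column-conditional error and \eqn{\phi} interpolates \eqn{\log_2} between
#' the floor and ceiling of \eqn{1/(1-\pi)}. Valid when the confusion matrix
#' comes from MAP decoding. A column that is never decoded contributes zero
#' weight; a fully wrong column (\eqn{\pi = 1}) has \eqn{\phi} capped at
#' \eqn{\log_2 q}.
#'
#' @param eps q x q joint confusion matrix (rows true, columns decoded).
#' @param prior prior over true inputs; defaults to the row sums of
#'   \code{eps}.
#' @return upper bound in bits.
#' @export
info_upper_bound <- function(eps, prior = NULL) {
  eps <- unclass(as.matrix(eps))
  q <- nrow(eps)
  if (is.null(prior)) prior <- rowSums(eps)
  HU <- -sum(ifelse(prior > 0, prior * log2(prior), 0))
  cs <- colSums(eps)
  acc <- 0
  for (j in seq_len(q)) {
    if (cs[j] <= 0) next
    pi_j <- 1 - eps[j, j] / cs[j]
    acc <- acc + cs[j] * .phi_alpha(pi_j, qmax = q)$phi
  }
  HU - acc
}

#' MAP decoding bound: lower and upper information bounds from one dataset
#'
#' Decodes every path in \code{data} with [map_decode()], builds the joint
#' confusion matrix, and returns the plug-in information (lower bound) and
#' the confusion-matrix upper bound.
#'
#' @param model a [path_model()].
#' @param data a \code{traj_set} or \code{labeled_dataset} with true labels.
#' @return list with \code{I_MAP}, \code{I_UB}, \code{confusion},
#'   \code{accuracy}.
#' @export
map_info_bound <- function(model, data) {
  ens <- model$ensemble
  if (inherits(data, "traj_set")) {
    true <- data$labels
    dec <- vapply(data$paths, function(p) map_decode(p, model)$decoded,
                  character(1))
  } else {
    true <- data$labels
    dec <- character(nrow(data$X))
    for (i in seq_len(nrow(data$X))) {
      tr <- structure(list(values = matrix(as.integer(data$X[i, ]),
                                           ncol = length(model$space$caps)),
                           x0 = data$x0, d = ncol(data$X), dt = data$dt),
                      class = "dtraj")
      dec[i] <- map_decode(tr, model)$decoded
    }
  }
  eps <- confusion_matrix(true, dec, labels = ens$labels)
  list(I_MAP = info_from_confusion(eps),
       I_UB = info_upper_bound(eps, prior = ens$prior),
       confusion = eps,
       accuracy = mean(true == dec))
}

#' Replicated MAP bound with error bars
#'
#' Repeats simulate + decode over independent datasets and reports means and
#' standard deviations of the lower and upper bounds.
#'
#' @inheritParams exact_info_mc
#' @return list with \code{I_MAP}, \code{I_MAP_std}, \code{I_UB},
#'   \code{I_UB_std}, and per-replicate values.
#' @export
map_info_bound_mc <- function(network, ensemble, x0, T_end, n_per_input,
                              mode = c("continuous", "discrete"), d = NULL,
                              replicates = 20L, seed = 1L, caps = NULL) {
  mode <- match.arg(mode)
  if (mode == "discrete" && is.null(d)) stop("d required in discrete mode")
  lo <- numeric(replicates); hi <- numeric(replicates)
  model <- NULL
  for (r in seq_len(replicates)) {
    tset <- simulate_dataset(network, ensemble, x0, T_end, n_per_input,
                             seed = .substream_seed(seed, 104729L * r))
    if (is.null(model) || any(.observed_caps(tset) > model$space$caps)) {
      if (is.null(caps)) caps <- default_state_cap(network, x0)
      caps <- pmax(caps, .observed_caps(tset) + 2L)
      model <- path_model(network, ensemble, x0, T_end, caps = caps)
    }
    dat <- if (mode == "continuous") tset else resample_dataset(tset, d)
    b <- map_info_bound(model, dat)
    lo[r] <- b$I_MAP; hi[r] <- b$I_UB
  }
  list(I_MAP = mean(lo), I_MAP_std = stats::sd(lo),
       I_UB = mean(hi), I_UB_std = stats::sd(hi),
       replicates = list(I_MAP = lo, I_UB = hi))
}
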