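#' Labeled dataset of discrete trajectories
#'
#' The basic container consumed by all model-free estimators: an
#' \eqn{N \times d} matrix of trajectories sampled on a uniform grid (rows =
#' cells/realizations) plus an input label per row. Values are integer
#' molecule counts when simulator-produced, but real values (e.g. imported
#' fluorescence traces) are accepted.
#'
#' @param X numeric matrix, one row per trajectory.
#' @param labels vector of input labels, length \code{nrow(X)}.
#' @param x0 known initial state (optional, used by model-based likelihoods).
#' @param dt grid spacing (optional).
#' @param T_end horizon (optional).
#' @param provenance free-form provenance string.
#' @return object of class \code{labeled_dataset}.
#' @export
labeled_dataset <- function(X, labels, x0 = NULL, dt = NULL, T_end = NULL,
                            provenance = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("one label per row required")
  if (anyNA(X)) stop("dataset contains missing values")
  structure(list(X = X, labels = labels, x0 = x0, dt = dt, T = T_end,
                 provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("Labeled dataset:", nrow(x$X), "trajectories x d =", ncol(x$X),
      "samples;", length(tab), "inputs (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  invisible(x)
}

#' Monte-Carlo approximation of the exact mutual information
#'
#' Computes \eqn{I = \tilde H(X) - \tilde H(X|U)} where both entropies are
#' Monte-Carlo averages of exact model-based log-likelihoods over the
#' supplied sample paths: \eqn{\tilde H(X)} averages the marginal
#' \eqn{-\log_2 p_X(x)} and \eqn{\tilde H(X|U)} averages the conditional
#' \eqn{-\log_2 p(x|u)} within each input, weighted by the prior. For
#' continuous-time paths this approximates the full-path information
#' \eqn{I^*}; for resampled paths it approximates the (smaller) discrete-time
#' information, which converges to \eqn{I^*} as the grid is refined.
#'
#' @param model a [path_model()].
#' @param data a \code{traj_set} (continuous mode) or a
#'   \code{labeled_dataset} of integer trajectories (discrete mode; requires
#'   \code{x0} and \code{dt}).
#' @return object of class \code{info_result}: \code{value} (bits),
#'   \code{std} (NA for a single pass; see [exact_info_mc()]),
#'   \code{H_X}, \code{H_XgU}, \code{N} (paths per input), \code{mode},
#'   \code{d}, \code{T}.
#' @export
exact_info <- function(model, data) {
  ens <- model$ensemble
  if (inherits(data, "traj_set")) {
    labels <- data$labels
    n <- length(data$paths)
    condmat <- matrix(NA_real_, n, ens$q, dimnames = list(NULL, ens$labels))
    for (i in seq_len(n)) {
      condmat[i, ] <- vapply(ens$labels, function(u)
        loglik_continuous(data$paths[[i]], model, u), numeric(1))
    }
    mode <- "continuous"; d <- NA_integer_
  } else if (inherits(data, "labeled_dataset")) {
    labels <- data$labels
    n <- nrow(data$X)
    condmat <- matrix(NA_real_, n, ens$q, dimnames = list(NULL, ens$labels))
    for (i in seq_len(n)) {
      tr <- structure(list(values = matrix(as.integer(data$X[i, ]),
                                           ncol = length(model$space$caps)),
                           x0 = data$x0, d = ncol(data$X), dt = data$dt),
                      class = "dtraj")
      condmat[i, ] <- vapply(ens$labels, function(u)
        loglik_discrete(tr, model, u), numeric(1))
    }
    mode <- "discrete"; d <- ncol(data$X)
  } else stop("data must be a traj_set or labeled_dataset")

  marg <- apply(condmat, 1L, function(v) .lse2(v + log2(ens$prior)))
  if (any(!is.finite(marg)))
    stop("some paths are impossible under every input: dataset/model mismatch")
  HX <- 0; HXgU <- 0
  for (j in seq_len(ens$q)) {
    rows <- labels == ens$labels[j]
    if (!any(rows)) stop("no paths for input ", ens$labels[j])
    HX <- HX - ens$prior[j] * mean(marg[rows])
    HXgU <- HXgU - ens$prior[j] * mean(condmat[rows, j])
  }
  structure(list(value = HX - HXgU, std = NA_real_, H_X = HX, H_XgU = HXgU,
                 N = n / ens$q, mode = mode, d = d, T = model$T,
                 conditionals = condmat, labels = labels),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("Mutual information (%s mode): %.4f bits", x$mode, x$value))
  if (is.finite(x$std)) cat(sprintf(" +- %.4f (std over replicates)", x$std))
  cat("\n")
  invisible(x)
}

#' Replicated exact Monte-Carlo information with error bars
#'
#' Runs [exact_info()] on \code{replicates} independently simulated datasets
#' of \code{n_per_input} paths per input and reports the mean and standard
#' deviation across replicates.
#'
#' @param network a [reaction_network()].
#' @param ensemble an [input_ensemble()].
#' @param x0 initial state.
#' @param T_end horizon.
#' @param n_per_input paths per input per replicate.
#' @param mode \code{"continuous"} or \code{"discrete"}.
#' @param d grid size (discrete mode only).
#' @param replicates number of independent re-runs (default 20).
#' @param seed master seed.
#' @param caps optional truncation caps.
#' @return an \code{info_result} with \code{std} filled in and per-replicate
#'   values in \code{$replicates}.
#' @export
exact_info_mc <- function(network, ensemble, x0, T_end, n_per_input,
                          mode = c("continuous", "discrete"), d = NULL,
                          replicates = 20L, seed = 1L, caps = NULL) {
  mode <- match.arg(mode)
  if (mode == "discrete" && is.null(d)) stop("d required in discrete mode")
  model <- NULL
  vals <- numeric(replicates)
  for (r in seq_len(replicates)) {
    tset <- simulate_dataset(network, ensemble, x0, T_end, n_per_input,
                             seed = .substream_seed(seed, 7919L * r))
    if (is.null(model)) {
      if (is.null(caps)) {
        caps <- default_state_cap(network, x0)
        caps <- pmax(caps, .observed_caps(tset) + 2L)
      }
      model <- path_model(network, ensemble, x0, T_end, caps = caps)
    } else {
      oc <- .observed_caps(tset)
      if (any(oc > model$space$caps)) {
        caps <- pmax(model$space$caps, oc + 2L)
        model <- path_model(network, ensemble, x0, T_end, caps = caps)
      }
    }
    dat <- if (mode == "continuous") tset else resample_dataset(tset, d)
    vals[r] <- exact_info(model, dat)$value
  }
  structure(list(value = mean(vals), std = stats::sd(vals),
                 H_X = NA_real_, H_XgU = NA_real_,
                 N = n_per_input, mode = mode,
                 d = if (mode == "discrete") d else NA_integer_,
                 T = T_end, replicates = vals),
            class = "info_result")
}

# per-species maximum copy number observed in a trajectory set
.observed_caps <- function(tset) {
  m <- ncol(tset$paths[[1]]$states)
  mx <- integer(m)
  for (p in tset$paths) {
    for (i in seq_len(m)) mx[i] <- max(mx[i], max(p$states[, i]))
  }
  mx
}
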