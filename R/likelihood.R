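#' Model-based likelihoods for continuous and resampled trajectories
#'
#' Bundles, for every input label, the truncated CME generators of each
#' piecewise-constant rate segment, so that exact path log-likelihoods can be
#' evaluated for continuous-time event lists (product of jump rates and
#' exponential survival factors) and for uniformly resampled trajectories
#' (products of matrix-exponential propagators \eqn{W = e^{M\Delta t}}).
#'
#' @param network a [reaction_network()].
#' @param ensemble an [input_ensemble()].
#' @param x0 deterministic initial state (a distribution over the truncated
#'   space may be supplied instead via \code{p0}).
#' @param T_end horizon.
#' @param caps per-species truncation caps; defaults to
#'   [default_state_cap()].
#' @param p0 optional initial probability vector over the state space
#'   (overrides the point mass at \code{x0}).
#' @return object of class \code{path_model}.
#' @export
path_model <- function(network, ensemble, x0, T_end, caps = NULL, p0 = NULL) {
  if (is.null(caps)) caps <- default_state_cap(network, x0)
  space <- state_space(caps)
  x0 <- as.integer(x0)
  i0 <- .state_index(space, x0)
  if (is.na(i0)) stop("x0 outside the truncated state space")
  if (is.null(p0)) { p0 <- numeric(space$n); p0[i0] <- 1 }
  if (length(p0) != space$n || any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("p0 must be a probability vector over the state space")
  segs <- list()
  for (u in ensemble$labels) {
    bps <- sort(unique(c(0, unlist(lapply(network$reactions, function(rx)
      rx$schedule[[u]]$breakpoints)))))
    bps <- bps[bps < T_end]
    Ms <- lapply(bps, function(t0) build_generator(network, u, t0, space))
    segs[[u]] <- list(start = bps, end = c(bps[-1], T_end), M = Ms)
  }
  structure(list(network = network, ensemble = ensemble, space = space,
                 x0 = x0, p0 = p0, T = T_end, segments = segs,
                 wcache = new.env(parent = emptyenv())),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path likelihood model:", x$space$n, "states, inputs:",
      paste(x$ensemble$labels, collapse = ", "), "| T =", x$T, "\n")
  invisible(x)
}

LOG2E <- 1 / log(2)

#' Exact log-likelihood of a continuous-time trajectory
#'
#' Evaluates, in log base 2,
#' \deqn{p(x|u) = p(s_1) e^{M_{s_1 s_1} t_1} \prod_{i=2}^{r} M_{s_i s_{i-1}}
#'   e^{M_{s_i s_i} t_i},}
#' the product of jump rates and exponential survival factors along the event
#' list; the final interval contributes survival only. Dwell intervals that
#' span a rate breakpoint contribute segment-wise survival terms under the
#' respective generators, and each jump factor uses the generator active at
#' the jump time. A transition that is impossible under this input yields
#' \code{-Inf} (an explicit sentinel, not an error).
#'
#' @param traj a \code{ctraj}.
#' @param model a [path_model()].
#' @param input input label.
#' @return log2-likelihood (possibly \code{-Inf}).
#' @export
loglik_continuous <- function(traj, model, input) {
  seg <- model$segments[[input]]
  if (is.null(seg)) stop("unknown input label: ", input)
  idx <- .state_indices(model$space, traj$states)
  r <- length(idx)
  entry <- c(0, cumsum(traj$dwell))        # entry[i] = time state i entered
  ll <- log2(model$p0[idx[1]])
  if (!is.finite(ll)) return(-Inf)
  nseg <- length(seg$start)
  # survival: for each occupied state, accumulate M_ss * overlap per segment
  for (s in seq_len(nseg)) {
    a <- pmax(entry[seq_len(r)], seg$start[s])
    b <- pmin(entry[-1L], seg$end[s])
    ov <- pmax(b - a, 0)
    keep <- ov > 0
    if (any(keep)) {
      dd <- diag(seg$M[[s]])[idx[keep]]
      ll <- ll + sum(dd * ov[keep]) * LOG2E
    }
  }
  if (r >= 2L) {
    jt <- entry[2:r]                       # jump times
    sidx <- findInterval(jt, seg$start)    # active segment at each jump
    to <- idx[2:r]; from <- idx[seq_len(r - 1L)]
    for (s in unique(sidx)) {
      sel <- sidx == s
      rates <- seg$M[[s]][cbind(to[sel], from[sel])]
      if (any(rates <= 0)) return(-Inf)
      ll <- ll + sum(log2(rates))
    }
  }
  ll
}

# row indices for a matrix of states (rows); errors if any falls outside
.state_indices <- function(space, states) {
  bad <- FALSE
  for (i in seq_len(ncol(states))) {
    if (any(states[, i] < 0L) || any(states[, i] > space$caps[i])) bad <- TRUE
  }
  if (bad) stop("trajectory state outside the truncated space; raise caps")
  as.integer(1L + states %*% space$strides)
}

#' Discrete-time propagator over one step
#'
#' \eqn{W = e^{M\Delta t}} for a truncated generator; columns sum to one
#' minus the truncation leak.
#'
#' @param M generator matrix (column convention).
#' @param dt step length (>= 0).
#' @return dense propagator matrix.
#' @export
discrete_propagator <- function(M, dt) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(diag(nrow(M)))
  W <- as.matrix(Matrix::expm(Matrix::Matrix(M * dt)))
  if (any(!is.finite(W))) stop("non-finite propagator entries")
  W
}

#' Exact log-likelihood of a uniformly resampled trajectory
#'
#' Evaluates \eqn{\log_2 p(x) = \log_2 p(x^0) + \sum_{i=1}^{d}
#' \log_2 W_{x^i x^{i-1}}}: one propagator factor per grid step starting from
#' the known initial state \eqn{x^0}. Grid steps spanning a rate breakpoint
#' use the product of segment propagators. Zero transition probability yields
#' \code{-Inf}.
#'
#' @param x a \code{dtraj} (or a plain numeric vector of d sampled values for
#'   single-species models, with the model's \code{x0} assumed).
#' @param model a [path_model()].
#' @param input input label.
#' @return log2-likelihood.
#' @export
loglik_discrete <- function(x, model, input) {
  if (!inherits(x, "dtraj")) {
    v <- matrix(as.integer(x), ncol = length(model$space$caps))
    x <- list(values = v, x0 = model$x0, d = nrow(v), dt = model$T / nrow(v))
  }
  d <- x$d
  idx <- c(.state_indices(model$space, matrix(as.integer(x$x0), nrow = 1L)),
           .state_indices(model$space, x$values))
  ll <- log2(model$p0[idx[1L]])
  if (!is.finite(ll)) return(-Inf)
  gp <- .grid_propagators(model, input, d, x$dt)
  to <- idx[-1L]; from <- idx[-(d + 1L)]
  for (g in seq_along(gp$W)) {
    sel <- gp$which == g
    w <- gp$W[[g]][cbind(to[sel], from[sel])]
    if (any(w <= 0)) return(-Inf)
    ll <- ll + sum(log2(w))
  }
  ll
}

# distinct step propagators for a uniform grid of d steps of length dt under
# one input: returns list(W = list of matrices, which = step -> matrix index);
# steps falling inside the same rate segment share a single expm
.grid_propagators <- function(model, input, d, dt) {
  key <- paste0("grid:", input, ":", d, ":", format(dt, digits = 12))
  got <- model$wcache[[key]]
  if (!is.null(got)) return(got)
  seg <- model$segments[[input]]
  t0s <- (seq_len(d) - 1) * dt
  t1s <- seq_len(d) * dt
  eps <- dt * 1e-9
  s0 <- findInterval(t0s + eps, seg$start)  # segment just after the step start
  s1 <- findInterval(t1s - eps, seg$start)  # segment just before the step end
  sig <- ifelse(s0 == s1, paste0("in", s0), paste0("x", seq_len(d)))
  usig <- unique(sig)
  which_ <- match(sig, usig)
  W <- vector("list", length(usig))
  for (g in seq_along(usig)) {
    i <- which(which_ == g)[1L]
    W[[g]] <- .one_step_propagator(model, seg, t0s[i], t1s[i])
  }
  out <- list(W = W, which = which_)
  model$wcache[[key]] <- out
  out
}

.one_step_propagator <- function(model, seg, t0, t1) {
  W <- NULL
  for (s in seq_along(seg$start)) {
    a <- max(t0, seg$start[s]); b <- min(t1, seg$end[s])
    if (b > a + 1e-12) {
      Ws <- discrete_propagator(seg$M[[s]], b - a)
      W <- if (is.null(W)) Ws else Ws %*% W
    }
  }
  if (is.null(W)) W <- diag(model$space$n)
  W
}

# log2-sum-exp
.lse2 <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(-Inf)
  mx + log2(sum(2^(v - mx)))
}

#' Marginal log-likelihood under the input prior
#'
#' \eqn{\log_2 p_X(x) = \log_2 \sum_i p(x|u^{(i)}) p_U(u^{(i)})}, evaluated
#' by log-sum-exp over the per-input conditionals; works for continuous and
#' discrete paths.
#'
#' @param traj a \code{ctraj} or \code{dtraj}.
#' @param model a [path_model()].
#' @return log2 marginal likelihood, and the per-input conditional log2
#'   likelihoods in attribute \code{"conditionals"}.
#' @export
marginal_loglik <- function(traj, model) {
  ens <- model$ensemble
  lls <- vapply(ens$labels, function(u) .cond_loglik(traj, model, u), numeric(1))
  out <- .lse2(lls + log2(ens$prior))
  attr(out, "conditionals") <- lls
  out
}

.cond_loglik <- function(traj, model, input) {
  if (inherits(traj, "ctraj")) loglik_continuous(traj, model, input)
  else loglik_discrete(traj, model, input)
}
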