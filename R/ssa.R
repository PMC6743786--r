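#' Exact stochastic simulation of one trajectory (Gillespie algorithm)
#'
#' Draws one continuous-time sample path of the network on \eqn{[0, T]} for a
#' fixed input. Piecewise-constant rate schedules are handled exactly: a
#' proposed dwell interval that would overshoot the next rate breakpoint is
#' discarded and re-proposed from the breakpoint with the new rates, which is
#' valid by the memoryless property of exponential dwell times.
#'
#' @param network a [reaction_network()].
#' @param input input label.
#' @param x0 non-negative integer initial state.
#' @param T_end trajectory horizon (> 0).
#' @param seed optional integer seed (set before sampling for reproducibility).
#' @return object of class \code{ctraj}: list with \code{states} (r x m
#'   integer matrix of visited states), \code{dwell} (length-r vector of times
#'   spent in each state, summing to \code{T_end}), \code{input},
#'   \code{T} and \code{x0}.
#' @export
ssa_simulate <- function(network, input, x0, T_end, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (T_end <= 0) stop("T_end must be > 0")
  x0 <- as.integer(x0)
  if (any(x0 < 0L)) stop("x0 must be non-negative")
  m <- length(network$species)
  if (length(x0) != m) stop("x0 length must equal number of species")
  K <- length(network$reactions)
  changes <- lapply(network$reactions, `[[`, "change")
  reacts <- lapply(network$reactions, `[[`, "reactants")

  # per-reaction schedule for this input; global breakpoint grid
  scheds <- lapply(seq_len(K), function(k) network$reactions[[k]]$schedule[[input]])
  if (any(vapply(scheds, is.null, logical(1)))) stop("unknown input label: ", input)
  bps <- sort(unique(c(0, unlist(lapply(scheds, `[[`, "breakpoints")))))
  bps <- bps[bps < T_end]
  seg_end <- c(bps[-1], Inf)
  theta_seg <- vapply(seq_len(K), function(k)
    scheds[[k]]$values[findInterval(bps, scheds[[k]]$breakpoints)],
    numeric(length(bps)))
  if (length(bps) == 1L) theta_seg <- matrix(theta_seg, nrow = 1L)

  cap <- 256L
  st <- matrix(0L, cap, m)
  dw <- numeric(cap)
  r <- 1L
  st[1L, ] <- x0
  x <- x0
  t_now <- 0
  entered <- 0           # time the current state was entered
  seg <- 1L

  a <- numeric(K)
  repeat {
    th <- theta_seg[seg, ]
    for (k in seq_len(K)) {
      ak <- th[k]
      if (ak > 0) {
        nu <- reacts[[k]]
        for (i in seq_len(m)) if (nu[i] > 0L) ak <- ak * choose(x[i], nu[i])
      }
      a[k] <- ak
    }
    a0 <- sum(a)
    if (!is.finite(a0)) stop("non-finite total propensity")
    t_next <- if (a0 > 0) t_now + stats::rexp(1L, a0) else Inf
    bnd <- seg_end[seg]
    if (t_next >= min(bnd, T_end)) {
      if (bnd < T_end) {         # cross into next rate segment, resample there
        t_now <- bnd
        seg <- seg + 1L
        next
      }
      dw[r] <- T_end - entered   # survive to the horizon
      break
    }
    # fire a reaction at t_next
    k <- sample.int(K, 1L, prob = a)
    dw[r] <- t_next - entered
    x <- x + changes[[k]]
    r <- r + 1L
    if (r > cap) {
      cap <- cap * 2L
      st <- rbind(st, matrix(0L, cap / 2L, m))
      dw <- c(dw, numeric(cap / 2L))
    }
    st[r, ] <- x
    t_now <- t_next
    entered <- t_next
  }
  structure(list(states = st[seq_len(r), , drop = FALSE],
                 dwell = dw[seq_len(r)],
                 input = input, T = T_end, x0 = x0),
            class = "ctraj")
}

#' @export
print.ctraj <- function(x, ...) {
  cat("Continuous trajectory: input", x$input, "| T =", x$T, "|",
      nrow(x$states), "states visited\n")
  invisible(x)
}

#' Resample a continuous trajectory on a uniform time grid
#'
#' Samples the right-continuous step function \eqn{x(t)} at times
#' \eqn{i\Delta t}, \eqn{i = 1..d}, \eqn{\Delta t = T/d}; the state at a jump
#' instant is the post-jump state. The known initial state \eqn{x^0} is kept
#' separately.
#'
#' @param traj a \code{ctraj}.
#' @param d number of grid points (>= 1).
#' @return object of class \code{dtraj}: list with \code{values} (d x m
#'   integer matrix), \code{x0}, \code{d}, \code{dt}, \code{T}, \code{input}.
#' @export
resample_discrete <- function(traj, d) {
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  dt <- traj$T / d
  # state occupied at time t: entry times are cumsum(dwell) shifted;
  # right-continuous convention => index = findInterval(t, entry_times)
  entry <- c(0, cumsum(traj$dwell))
  tt <- seq_len(d) * dt
  idx <- findInterval(tt, entry[-length(entry)], left.open = FALSE)
  # guard the horizon endpoint against rounding
  idx[idx > nrow(traj$states)] <- nrow(traj$states)
  structure(list(values = traj$states[idx, , drop = FALSE],
                 x0 = traj$x0, d = d, dt = dt, T = traj$T, input = traj$input),
            class = "dtraj")
}

#' Simulate a labeled dataset of trajectories
#'
#' Draws \code{n_per_input} SSA paths for every label of the ensemble.
#' Trajectory \eqn{i} uses a deterministically derived seed substream so
#' datasets are reproducible regardless of generation order.
#'
#' @param network a [reaction_network()] or a network sampler created by
#'   [add_extrinsic_noise()].
#' @param ensemble an [input_ensemble()].
#' @param x0 initial state (shared across inputs).
#' @param T_end horizon.
#' @param n_per_input paths per input label.
#' @param seed integer master seed.
#' @return object of class \code{traj_set}: list with \code{paths} (list of
#'   \code{ctraj}), \code{labels}, \code{ensemble}, \code{x0}, \code{T}.
#' @export
simulate_dataset <- function(network, ensemble, x0, T_end, n_per_input, seed = 1L) {
  sampler <- if (inherits(network, "network_sampler")) network else NULL
  paths <- vector("list", n_per_input * ensemble$q)
  labels <- character(length(paths))
  i <- 0L
  for (j in seq_len(ensemble$q)) {
    u <- ensemble$labels[j]
    for (r in seq_len(n_per_input)) {
      i <- i + 1L
      sub <- .substream_seed(seed, i)
      # the extrinsic-noise draw gets its own substream so it is independent
      # of the SSA event stream of the same cell
      net_i <- if (is.null(sampler)) network else sampler(.substream_seed(sub, 999983L))
      paths[[i]] <- ssa_simulate(net_i, u, x0, T_end, seed = sub)
      labels[i] <- u
    }
  }
  structure(list(paths = paths, labels = labels, ensemble = ensemble,
                 x0 = x0, T = T_end),
            class = "traj_set")
}

# deterministic 31-bit substream seed for trajectory i of a dataset
.substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

#' @export
print.traj_set <- function(x, ...) {
  cat("Trajectory set:", length(x$paths), "paths, inputs:",
      paste(x$ensemble$labels, collapse = ", "), "| T =", x$T, "\n")
  invisible(x)
}

#' Resample every trajectory of a set onto a uniform grid
#'
#' @param tset a \code{traj_set}.
#' @param d grid size.
#' @return a [labeled_dataset()] of discrete trajectories (single-species
#'   networks only; multivariate trajectories are flattened column-wise by
#'   species).
#' @export
resample_dataset <- function(tset, d) {
  n <- length(tset$paths)
  m <- ncol(tset$paths[[1]]$states)
  X <- matrix(0, n, d * m)
  for (i in seq_len(n)) {
    v <- resample_discrete(tset$paths[[i]], d)$values
    X[i, ] <- as.numeric(v)
  }
  labeled_dataset(X, tset$labels, x0 = tset$x0, dt = tset$T / d, T_end = tset$T)
}
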