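#' Packaged benchmark birth-death networks
#'
#' Three single-species birth-death processes
#' \eqn{\emptyset \rightarrow X \rightarrow \emptyset} with input-dependent
#' production rate \eqn{\alpha} and degradation rate \eqn{\beta}, stylizing
#' common signaling behaviours:
#' \describe{
#'   \item{Example 1}{input encoded in the steady-state mean: \eqn{x(0)=0},
#'     \eqn{\beta = 0.01}, \eqn{\alpha = 0.1} vs \eqn{0.07}.}
#'   \item{Example 2}{transient (adapted) response: \eqn{x(0)=0},
#'     \eqn{\beta = 0.01}, \eqn{\alpha = 0.1} vs \eqn{0.05} for
#'     \eqn{t < 1000}, then \eqn{\alpha = 5\times10^{-4}} for both inputs.}
#'   \item{Example 3}{input encoded only in temporal correlations: the mean
#'     is pinned at 10 for both inputs (\eqn{x(0)=10},
#'     \eqn{\alpha = 0.1, \beta = 0.01} vs \eqn{\alpha = 0.05,
#'     \beta = 0.005}); fluctuation/mean-reversion timescales differ
#'     two-fold.}
#' }
#'
#' @param example_id 1, 2 or 3.
#' @return list with \code{network}, \code{ensemble} (uniform binary prior),
#'   \code{x0}, \code{T} (conventional horizon 2000).
#' @export
make_example <- function(example_id) {
  if (!example_id %in% 1:3) stop("unknown example_id: ", example_id)
  labs <- c("u1", "u2")
  if (example_id == 1L) {
    net <- reaction_network(
      species = "X",
      reactions = list(
        list(reactants = 0L, products = 1L, rate = list(u1 = 0.1, u2 = 0.07)),
        list(reactants = 1L, products = 0L, rate = 0.01)),
      inputs = labs)
    x0 <- 0L
  } else if (example_id == 2L) {
    net <- reaction_network(
      species = "X",
      reactions = list(
        list(reactants = 0L, products = 1L,
             rate = list(u1 = list(breakpoints = c(0, 1000), values = c(0.1, 5e-4)),
                         u2 = list(breakpoints = c(0, 1000), values = c(0.05, 5e-4)))),
        list(reactants = 1L, products = 0L, rate = 0.01)),
      inputs = labs)
    x0 <- 0L
  } else {
    net <- reaction_network(
      species = "X",
      reactions = list(
        list(reactants = 0L, products = 1L, rate = list(u1 = 0.1, u2 = 0.05)),
        list(reactants = 1L, products = 0L, rate = list(u1 = 0.01, u2 = 0.005))),
      inputs = labs)
    x0 <- 10L
  }
  list(network = net, ensemble = input_ensemble(labs), x0 = x0, T = 2000)
}

#' Multilevel extension of Example 2
#'
#' Extends the transient benchmark to \eqn{q} input levels: during the early
#' phase \eqn{t < 1000} the production rate takes \eqn{q} uniformly spaced
#' values \eqn{\alpha_i = 0.1\, i/q}, tiling the original two-level dynamic
#' range (so \eqn{q = 2} recovers \eqn{\{0.05, 0.1\}}); after \eqn{t = 1000}
#' all inputs share \eqn{\alpha = 5\times 10^{-4}} as in Example 2. The grid
#' deliberately excludes \eqn{\alpha = 0}, which would make the lowest level
#' degenerate with the post-switch regime. Prior is uniform \eqn{1/q}.
#'
#' @param q number of input levels (the benchmarks use 2..5; larger values
#'   are allowed with a warning).
#' @return list with \code{network}, \code{ensemble}, \code{x0}, \code{T}.
#' @export
make_multilevel_example2 <- function(q) {
  q <- as.integer(q)
  if (q < 2L) stop("q must be >= 2")
  if (q > 5L) warning("q > 5 is outside the benchmarked range")
  labs <- paste0("u", seq_len(q))
  rates <- lapply(seq_len(q), function(i)
    list(breakpoints = c(0, 1000), values = c(0.1 * i / q, 5e-4)))
  names(rates) <- labs
  net <- reaction_network(
    species = "X",
    reactions = list(
      list(reactants = 0L, products = 1L, rate = rates),
      list(reactants = 1L, products = 0L, rate = 0.01)),
    inputs = labs)
  list(network = net, ensemble = input_ensemble(labs), x0 = 0L, T = 2000)
}

#' Cell-to-cell (extrinsic) rate variability
#'
#' Wraps a network into a per-cell sampler emulating extrinsic noise: each
#' simulated cell perturbs the degradation rate(s) once, at the start of its
#' life, by an additive Gaussian draw that is then held fixed through time:
#' \eqn{\beta' = \max(\beta + N(0, sd), 10^{-6})} (the floor guards
#' positivity). Reactions with first-order (degradation-like) kinetics are
#' perturbed; zero-order production rates are left untouched.
#'
#' @param network a [reaction_network()].
#' @param sd standard deviation of the perturbation (>= 0).
#' @return a function of class \code{network_sampler}: called with a cell
#'   seed, returns the perturbed network for that cell (same seed, same
#'   network).
#' @export
add_extrinsic_noise <- function(network, sd) {
  if (sd < 0) stop("sd must be >= 0")
  force(network)
  f <- function(cell_seed) {
    if (sd == 0) return(network)
    set.seed(cell_seed)
    net <- network
    for (k in seq_along(net$reactions)) {
      if (sum(net$reactions[[k]]$reactants) == 1L) {
        shift <- stats::rnorm(1L, 0, sd)
        for (u in names(net$reactions[[k]]$schedule)) {
          v <- net$reactions[[k]]$schedule[[u]]$values
          net$reactions[[k]]$schedule[[u]]$values <- pmax(v + shift, 1e-6)
        }
      }
    }
    net
  }
  class(f) <- c("network_sampler", "function")
  f
}
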