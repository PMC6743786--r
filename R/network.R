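#' Construct a chemical reaction network with input-dependent rates
#'
#' A network is a set of \eqn{m} species and \eqn{K} mass-action reactions
#' \deqn{\nu'_{1k} X_1 + \ldots \rightarrow \nu''_{1k} X_1 + \ldots}
#' whose rate constants \eqn{\theta_k} may depend on a discrete input label
#' and, piecewise-constantly, on time. The propensity of reaction \eqn{k} in
#' state \eqn{x} is \eqn{a_k(x) = \theta_k \prod_i \binom{x_i}{\nu'_{ik}}}.
#'
#' @param species character vector of species identifiers (length \eqn{m}).
#' @param reactions list of reactions. Each reaction is a list with elements
#'   \code{reactants} and \code{products} (non-negative integer vectors of
#'   length \eqn{m}, stoichiometric coefficients) and \code{rate}. The rate is
#'   either a single non-negative number (input-independent, constant in
#'   time), a named list mapping input label to a number, or a named list
#'   mapping input label to \code{list(breakpoints =, values =)} describing a
#'   piecewise-constant schedule: \code{values[j]} applies on
#'   \code{[breakpoints[j], breakpoints[j+1])}, with \code{breakpoints[1] == 0}.
#' @param inputs character vector of admissible input labels. Defaults to the
#'   union of labels appearing in the rate tables, or \code{"u1"} if all rates
#'   are input-independent.
#'
#' @return an object of class \code{reaction_network}.
#' @seealso [propensity()], [build_generator()], [ssa_simulate()]
#' @export
reaction_network <- function(species, reactions, inputs = NULL) {
  stopifnot(is.character(species), length(species) >= 1L)
  m <- length(species)
  labs <- character(0)
  for (rx in reactions) {
    if (is.list(rx$rate)) labs <- union(labs, names(rx$rate))
  }
  if (is.null(inputs)) inputs <- if (length(labs)) labs else "u1"
  rxs <- lapply(seq_along(reactions), function(k) {
    rx <- reactions[[k]]
    nu_in <- as.integer(rx$reactants)
    nu_out <- as.integer(rx$products)
    if (length(nu_in) != m || length(nu_out) != m)
      stop("reaction ", k, ": stoichiometry length must equal number of species")
    if (any(nu_in < 0L) || any(nu_out < 0L))
      stop("reaction ", k, ": stoichiometric coefficients must be non-negative")
    sched <- .normalize_schedule(rx$rate, inputs, k)
    list(reactants = nu_in, products = nu_out,
         change = nu_out - nu_in, schedule = sched)
  })
  structure(list(species = species, reactions = rxs, inputs = inputs),
            class = "reaction_network")
}

# internal canonical form: per input label, list(breakpoints, values) with
# breakpoints[1] == 0 and strictly increasing breakpoints
.normalize_schedule <- function(rate, inputs, k) {
  one <- function(r) {
    if (is.numeric(r) && length(r) == 1L) r <- list(breakpoints = 0, values = r)
    if (!is.list(r) || is.null(r$breakpoints) || is.null(r$values))
      stop("reaction ", k, ": rate must be a number or list(breakpoints=, values=)")
    bp <- as.numeric(r$breakpoints); v <- as.numeric(r$values)
    if (length(bp) != length(v)) stop("reaction ", k, ": breakpoints/values length mismatch")
    if (bp[1] != 0) stop("reaction ", k, ": first breakpoint must be 0")
    if (length(bp) > 1 && any(diff(bp) <= 0))
      stop("reaction ", k, ": breakpoints must be strictly increasing")
    if (any(v < 0) || any(!is.finite(v))) stop("reaction ", k, ": rates must be finite and >= 0")
    list(breakpoints = bp, values = v)
  }
  if (is.numeric(rate) && length(rate) == 1L) {
    out <- rep(list(one(rate)), length(inputs)); names(out) <- inputs; return(out)
  }
  if (!is.list(rate)) stop("reaction ", k, ": unsupported rate specification")
  if (!is.null(rate$breakpoints)) {       # one schedule for all inputs
    out <- rep(list(one(rate)), length(inputs)); names(out) <- inputs; return(out)
  }
  missing <- setdiff(inputs, names(rate))
  if (length(missing))
    stop("reaction ", k, ": no rate given for input(s) ", paste(missing, collapse = ", "))
  out <- lapply(inputs, function(u) one(rate[[u]])); names(out) <- inputs
  out
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions, inputs:",
      paste(x$inputs, collapse = ", "), "\n")
  for (k in seq_along(x$reactions)) {
    rx <- x$reactions[[k]]
    side <- function(co) {
      nz <- which(co > 0L)
      if (!length(nz)) return("0")
      paste(ifelse(co[nz] > 1L, paste0(co[nz], " "), ""), x$species[nz],
            sep = "", collapse = " + ")
    }
    cat(sprintf("  R%d: %s -> %s\n", k, side(rx$reactants), side(rx$products)))
  }
  invisible(x)
}

#' Discrete input ensemble
#'
#' The input \eqn{U} takes one of \eqn{q \ge 2} values \eqn{u^{(1)},\ldots,
#' u^{(q)}} with prior \eqn{p_U} (uniform by default).
#'
#' @param labels character vector of q distinct labels.
#' @param prior numeric vector of prior probabilities (defaults to uniform).
#' @return object of class \code{input_ensemble} with fields \code{labels},
#'   \code{prior}, \code{q}.
#' @export
input_ensemble <- function(labels, prior = NULL) {
  labels <- as.character(labels)
  q <- length(labels)
  if (q < 2L) stop("need at least two input labels")
  if (anyDuplicated(labels)) stop("input labels must be distinct")
  if (is.null(prior)) prior <- rep(1 / q, q)
  if (length(prior) != q || any(prior < 0) || abs(sum(prior) - 1) > 1e-12)
    stop("prior must be length-q, non-negative, and sum to 1")
  structure(list(labels = labels, prior = prior, q = q), class = "input_ensemble")
}

# rate theta_k(u, t) for reaction k; schedules are right-continuous step
# functions of time
.rate_at <- function(network, k, input, t) {
  sch <- network$reactions[[k]]$schedule[[input]]
  if (is.null(sch)) stop("unknown input label: ", input)
  sch$values[findInterval(t, sch$breakpoints)]
}

#' Propensity of a reaction in a given state
#'
#' Mass-action propensity \eqn{a_k(x) = \theta_k(u,t)\prod_i
#' \binom{x_i}{\nu'_{ik}}}; zero whenever any reactant count falls short.
#'
#' @param network a [reaction_network()].
#' @param k reaction index.
#' @param state non-negative integer state vector.
#' @param input input label.
#' @param t time at which the (piecewise-constant) rate is evaluated.
#' @return non-negative propensity.
#' @export
propensity <- function(network, k, state, input, t = 0) {
  if (any(state < 0)) stop("invalid state: negative component")
  rx <- network$reactions[[k]]
  th <- .rate_at(network, k, input, t)
  th * prod(choose(state, rx$reactants))
}

#' Truncated state space for the chemical master equation
#'
#' Enumerates the rectangular lattice \eqn{\{0..cap_1\}\times\ldots\times
#' \{0..cap_m\}} so the (in principle infinite) CME generator can be stored
#' as a finite matrix. For a single species this is simply \eqn{0..X_{max}}.
#'
#' @param caps integer vector of per-species maximum copy numbers.
#' @return object of class \code{state_space} with the enumeration matrix
#'   \code{states} (rows are states, in column-major lattice order) and
#'   \code{n} the number of states. State vector \code{x} maps to row index
#'   \code{1 + sum(x * strides)}.
#' @export
state_space <- function(caps) {
  caps <- as.integer(caps)
  if (any(caps < 0L)) stop("caps must be non-negative")
  sizes <- caps + 1L
  n <- prod(sizes)
  grids <- lapply(sizes, function(s) 0:(s - 1L))
  states <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- NULL
  strides <- cumprod(c(1L, sizes[-length(sizes)]))
  structure(list(caps = caps, states = states, strides = strides, n = n),
            class = "state_space")
}

# row index of a state (1-based); NA if outside the lattice
.state_index <- function(space, state) {
  if (any(state < 0L) || any(state > space$caps)) return(NA_integer_)
  as.integer(1L + sum(state * space$strides))
}

#' Default truncation cap for the packaged birth-death style networks
#'
#' For networks whose mean dynamics are linear (all reactions of total
#' reactant order at most one), solves the steady-state mean per input and
#' rate segment and returns \code{ceil(max mean) + ceil(10 sqrt(max mean))},
#' floored at \code{x0 + 20}. Poisson-like tails make the truncation leak
#' negligible at this cap. Non-linear networks must supply a cap explicitly.
#'
#' @param network a [reaction_network()].
#' @param x0 initial state vector.
#' @return integer vector of per-species caps.
#' @export
default_state_cap <- function(network, x0) {
  m <- length(network$species)
  ords <- vapply(network$reactions, function(rx) sum(rx$reactants), numeric(1))
  if (any(ords > 1))
    stop("default_state_cap only applies to networks with linear mean dynamics; ",
         "supply caps explicitly")
  # mean ODE: dx/dt = b(u,t) + A(u,t) x ; steady state solves A x = -b
  max_mean <- numeric(m)
  for (u in network$inputs) {
    bps <- sort(unique(unlist(lapply(network$reactions, function(rx)
      rx$schedule[[u]]$breakpoints))))
    for (t0 in bps) {
      A <- matrix(0, m, m); b <- numeric(m)
      for (k in seq_along(network$reactions)) {
        rx <- network$reactions[[k]]
        th <- .rate_at(network, k, u, t0)
        if (sum(rx$reactants) == 0L) {
          b <- b + th * rx$change
        } else {
          i <- which(rx$reactants == 1L)
          A[, i] <- A[, i] + th * rx$change
        }
      }
      xs <- tryCatch(solve(A, -b), error = function(e) rep(NA_real_, m))
      ok <- is.finite(xs) & xs >= 0
      max_mean[ok] <- pmax(max_mean[ok], xs[ok])
    }
  }
  pmax(ceiling(max_mean) + ceiling(10 * sqrt(pmax(max_mean, 0))),
       as.integer(x0) + 20L)
}

#' Build the truncated CME generator for one input at one time
#'
#' Returns the transition-rate matrix \eqn{M} of \eqn{\dot p = M p} on the
#' truncated space (column convention: \code{M[to, from]}). Off-diagonal
#' entries are reaction propensities of the source state; diagonals are minus
#' the total outflow, so interior columns sum to zero. Transitions leaving
#' the truncation are dropped; their total rate per boundary state is
#' reported in the \code{"leak"} attribute (a vector of per-state dropped
#' outflow rates).
#'
#' @param network a [reaction_network()].
#' @param input input label.
#' @param t time (selects the active rate-schedule segment).
#' @param space a [state_space()].
#' @return dense matrix \eqn{n \times n} with attribute \code{leak}.
#' @export
build_generator <- function(network, input, t, space) {
  n <- space$n
  if (n < 1L) stop("empty state space")
  M <- matrix(0, n, n)
  leak <- numeric(n)
  states <- space$states
  for (k in seq_along(network$reactions)) {
    rx <- network$reactions[[k]]
    th <- .rate_at(network, k, input, t)
    if (th < 0) stop("negative rate encountered")
    if (th == 0) next
    # vectorized propensity over all source states
    a <- rep(th, n)
    for (i in seq_along(rx$reactants)) {
      if (rx$reactants[i] > 0L) a <- a * choose(states[, i], rx$reactants[i])
    }
    dest <- sweep(states, 2L, rx$change, "+")
    inside <- rep(TRUE, n)
    for (i in seq_len(ncol(dest)))
      inside <- inside & dest[, i] >= 0L & dest[, i] <= space$caps[i]
    di <- as.integer(1L + dest %*% space$strides)
    src <- which(a > 0)
    for (j in src) {
      if (inside[j]) {
        M[di[j], j] <- M[di[j], j] + a[j]
        M[j, j] <- M[j, j] - a[j]
      } else {
        # destination outside truncation: drop the transition but keep note;
        # the source column then sums to -leak, not zero
        leak[j] <- leak[j] + a[j]
        M[j, j] <- M[j, j] - a[j]
      }
    }
  }
  attr(M, "leak") <- leak
  M
}
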