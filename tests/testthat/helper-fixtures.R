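# Shared fixtures, built in code. Heavier simulated datasets are created
# lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

# a 2-input single-species birth-death network with identical channels
identical_channel_network <- function() {
  reaction_network(
    species = "X",
    reactions = list(
      list(reactants = 0L, products = 1L, rate = list(u1 = 0.1, u2 = 0.1)),
      list(reactants = 1L, products = 0L, rate = 0.01)),
    inputs = c("u1", "u2"))
}

# small Example-1 trajectory set + model, reused across tests
fix_ex1_small <- function() {
  if (is.null(.fix$ex1_small)) {
    ex <- make_example(1)
    tset <- simulate_dataset(ex$network, ex$ensemble, ex$x0, 1000, 150, seed = 11L)
    model <- path_model(ex$network, ex$ensemble, ex$x0, 1000,
                        caps = max(45L, max(sapply(tset$paths, function(p)
                          max(p$states))) + 2L))
    .fix$ex1_small <- list(ex = ex, tset = tset, model = model)
  }
  .fix$ex1_small
}

# two well-separated Gaussian classes in 2-D (decoder sanity data)
fix_blobs <- function(n = 80, gap = 2.5, seed = 5L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * 2, 0), n), matrix(rnorm(n * 2, gap), n))
  labeled_dataset(X, rep(c("a", "b"), each = n))
}

# concentric rings: not linearly separable, trivially rbf-separable
fix_rings <- function(n = 80, seed = 6L) {
  set.seed(seed)
  r <- c(sqrt(runif(n)), sqrt(runif(n)) + 1.8)
  th <- runif(2 * n) * 2 * pi
  labeled_dataset(cbind(r * cos(th), r * sin(th)),
                  rep(c("in", "out"), each = n))
}
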