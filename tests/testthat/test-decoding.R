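test_that("MAP decoding maximizes likelihood plus log-prior", {
  fx <- fix_ex1_small()
  tr <- fx$tset$paths[[1]]
  rec <- map_decode(tr, fx$model)
  expect_equal(rec$decoded, names(which.max(rec$scores)))
  # a strong prior can overturn equal likelihoods
  net <- identical_channel_network()
  skew <- input_ensemble(c("u1", "u2"), prior = c(0.9, 0.1))
  mod <- path_model(net, skew, 0L, 200, caps = 40L)
  tr2 <- ssa_simulate(net, "u2", 0L, 200, seed = 4L)
  expect_equal(map_decode(tr2, mod)$decoded, "u1")
})

test_that("confusion matrix is a joint frequency table", {
  eps <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                          labels = c("a", "b"))
  expect_equal(sum(eps), 1)
  expect_equal(eps["a", "a"], 0.25)
  expect_equal(eps["a", "b"], 0.25)
  expect_equal(eps["b", "b"], 0.5)
  expect_equal(attr(eps, "N_test"), 4L)
})

test_that("plug-in confusion information matches hand-computed cases", {
  expect_equal(info_from_confusion(diag(c(0.5, 0.5))), 1)
  expect_equal(info_from_confusion(matrix(0.25, 2, 2)), 0)
  eps <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  # direct evaluation: 2*(0.4*log2(0.4/0.25) + 0.1*log2(0.1/0.25))
  expect_equal(info_from_confusion(eps),
               2 * (0.4 * log2(1.6) + 0.1 * log2(0.4)))
  expect_equal(info_from_confusion(eps), 0.2781, tolerance = 5e-4)
  # permutation-diagonal tables saturate at log2 q
  perm <- matrix(0, 3, 3); perm[cbind(1:3, c(2, 3, 1))] <- 1 / 3
  expect_equal(info_from_confusion(perm), log2(3))
  expect_error(info_from_confusion(matrix(c(0.6, -0.1, 0.3, 0.2), 2)),
               "non-negative")
  expect_error(info_from_confusion(matrix(0.3, 2, 2)), "sum to 1")
})

test_that("phi/alpha take their closed-form values at pi in {0, 1/3, 1/2}", {
  pa0 <- trajinfo:::.phi_alpha(0)
  expect_equal(pa0$phi, 0)
  pa3 <- trajinfo:::.phi_alpha(1 / 3)
  expect_equal(pa3$alpha, 1 / 3)
  expect_equal(pa3$phi, 2 / 3)
  pa5 <- trajinfo:::.phi_alpha(0.5)
  expect_equal(pa5$alpha, 0)
  expect_equal(pa5$phi, 1)
  # phi is non-decreasing over the evaluated range
  grid <- seq(0, 0.9, by = 0.05)
  phis <- vapply(grid, function(p) trajinfo:::.phi_alpha(p)$phi, numeric(1))
  expect_true(all(diff(phis) >= -1e-12))
})

test_that("confusion upper bound hits its boundary values", {
  # perfect decoding: I_UB = H(U) = 1 bit
  expect_equal(info_upper_bound(diag(c(0.5, 0.5))), 1)
  # chance decoding: pi = 1/2 both columns -> I_UB = 0
  expect_equal(info_upper_bound(matrix(0.25, 2, 2)), 0)
  # pi = 1/3 in both columns, uniform: I_UB = 1 - phi(1/3) = 1/3
  eps <- matrix(c(1 / 3, 1 / 6, 1 / 6, 1 / 3), 2, 2)
  expect_equal(info_upper_bound(eps), 1 / 3)
  # the upper bound dominates the plug-in lower bound
  expect_gte(info_upper_bound(eps), info_from_confusion(eps))
  # degenerate fully-wrong column: phi capped, bound stays finite
  bad <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_true(is.finite(info_upper_bound(bad)))
})

test_that("upper bound dominates the lower bound on decoded datasets", {
  fx <- fix_ex1_small()
  b <- map_info_bound(fx$model, resample_dataset(fx$tset, 20L))
  expect_gte(b$I_UB + 1e-9, b$I_MAP)
  expect_true(b$I_MAP >= 0 && b$I_MAP <= 1)
  expect_equal(sum(b$confusion), 1)
})

test_that("identical channels decode at chance: both bounds near zero", {
  net <- identical_channel_network()
  ens <- input_ensemble(c("u1", "u2"))
  tset <- simulate_dataset(net, ens, 0L, 400, 80, seed = 13L)
  model <- path_model(net, ens, 0L, 400, caps = 45L)
  b <- map_info_bound(model, tset)
  expect_lt(b$I_MAP, 0.05)
  expect_lt(abs(b$accuracy - 0.5), 0.2)
})

test_that("fine-grid discrete decoding converges to continuous-time decoding", {
  # at dt = 1 (well below the 1/beta = 100 relaxation timescale) the sampled
  # representation preserves essentially all decodable evidence
  ex <- make_example(1)
  tset <- simulate_dataset(ex$network, ex$ensemble, ex$x0, 2000, 250,
                           seed = 55L)
  caps <- max(45L, max(vapply(tset$paths, function(p) max(p$states),
                              numeric(1))) + 2L)
  model <- path_model(ex$network, ex$ensemble, ex$x0, 2000, caps = caps)
  dec_c <- vapply(tset$paths, function(p) map_decode(p, model)$decoded,
                  character(1))
  fine <- resample_dataset(tset, 2000L)
  dec_d <- character(0)
  for (i in seq_len(nrow(fine$X))) {
    tr <- structure(list(values = matrix(as.integer(fine$X[i, ]), ncol = 1),
                         x0 = 0L, d = 2000L, dt = 1), class = "dtraj")
    dec_d[i] <- map_decode(tr, model)$decoded
  }
  expect_gte(mean(dec_c == dec_d), 0.99)
})
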