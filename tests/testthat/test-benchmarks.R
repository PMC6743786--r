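test_that("packaged examples carry the published rate parameterizations", {
  ex1 <- make_example(1)
  expect_equal(ex1$x0, 0L)
  expect_equal(propensity(ex1$network, 1, 0L, "u1"), 0.1)
  expect_equal(propensity(ex1$network, 1, 0L, "u2"), 0.07)
  expect_equal(propensity(ex1$network, 2, 1L, "u1"), 0.01)
  expect_equal(propensity(ex1$network, 2, 1L, "u2"), 0.01)
  expect_equal(ex1$ensemble$prior, c(0.5, 0.5))

  ex2 <- make_example(2)
  expect_equal(propensity(ex2$network, 1, 0L, "u1", 0), 0.1)
  expect_equal(propensity(ex2$network, 1, 0L, "u2", 0), 0.05)
  # both inputs share the tiny post-switch production rate
  expect_equal(propensity(ex2$network, 1, 0L, "u1", 1000), 5e-4)
  expect_equal(propensity(ex2$network, 1, 0L, "u2", 1500), 5e-4)

  ex3 <- make_example(3)
  expect_equal(ex3$x0, 10L)
  # both inputs pin the mean at alpha/beta = 10; timescales differ two-fold
  expect_equal(propensity(ex3$network, 1, 0L, "u1") /
                 propensity(ex3$network, 2, 1L, "u1"), 10)
  expect_equal(propensity(ex3$network, 1, 0L, "u2") /
                 propensity(ex3$network, 2, 1L, "u2"), 10)
  expect_equal(propensity(ex3$network, 2, 1L, "u1"), 0.01)
  expect_equal(propensity(ex3$network, 2, 1L, "u2"), 0.005)

  expect_error(make_example(4), "unknown")
})

test_that("multilevel extension tiles the production-rate range", {
  m2 <- make_multilevel_example2(2L)
  # q = 2 recovers the original Example 2 rates exactly
  expect_equal(propensity(m2$network, 1, 0L, "u1", 0), 0.05)
  expect_equal(propensity(m2$network, 1, 0L, "u2", 0), 0.1)
  m5 <- make_multilevel_example2(5L)
  early <- vapply(paste0("u", 1:5), function(u)
    propensity(m5$network, 1, 0L, u, 0), numeric(1))
  expect_equal(unname(early), c(0.02, 0.04, 0.06, 0.08, 0.10))
  late <- vapply(paste0("u", 1:5), function(u)
    propensity(m5$network, 1, 0L, u, 1500), numeric(1))
  expect_equal(unname(late), rep(5e-4, 5))
  expect_equal(m5$ensemble$prior, rep(0.2, 5))
  expect_error(make_multilevel_example2(1L), ">= 2")
  expect_warning(make_multilevel_example2(6L), "range")
})

test_that("extrinsic noise perturbs degradation once per cell, reproducibly", {
  ex <- make_example(1)
  sam0 <- add_extrinsic_noise(ex$network, 0)
  expect_identical(sam0(123L), ex$network)
  sam <- add_extrinsic_noise(ex$network, 0.001)
  n1 <- sam(123L); n2 <- sam(123L); n3 <- sam(124L)
  b1 <- n1$reactions[[2]]$schedule$u1$values
  expect_identical(b1, n2$reactions[[2]]$schedule$u1$values)  # same cell seed
  expect_false(identical(b1, n3$reactions[[2]]$schedule$u1$values))
  expect_gt(b1, 0)                                  # positivity floor
  # production (zero-order) rates stay untouched
  expect_identical(n1$reactions[[1]]$schedule$u1$values,
                   ex$network$reactions[[1]]$schedule$u1$values)
})

test_that("extrinsic noise inflates across-cell late-time variance", {
  ex <- make_example(1)
  late_var <- function(net_or_sampler, seed) {
    tset <- simulate_dataset(net_or_sampler, ex$ensemble, ex$x0, 1200, 150,
                             seed = seed)
    fin <- vapply(tset$paths, function(p) p$states[nrow(p$states), 1],
                  numeric(1))
    var(fin[tset$labels == "u1"])
  }
  v0 <- late_var(ex$network, 31L)
  # sd = 0.001 on beta = 0.01 is a 10% rate spread: variance clearly inflates
  vn <- late_var(add_extrinsic_noise(ex$network, 0.001), 31L)
  expect_gt(vn, v0)
})

test_that("benchmark harness emits a tidy ordered results table", {
  res <- run_benchmark(example_id = 1, methods = c("exact", "map", "knn"),
                       n_per_input = 40L, d = 10L, T_end = 400,
                       replicates = 2L, seed = 3L)
  expect_true(all(c("method", "example", "q", "d", "N", "replicates",
                    "info_bits_mean", "info_bits_std", "seed") %in%
                    names(res)))
  expect_setequal(res$method, c("exact", "map", "map-upper", "knn"))
  ex_row <- res[res$method == "exact", ]
  map_row <- res[res$method == "map", ]
  ub_row <- res[res$method == "map-upper", ]
  # decoding sandwich on identical data (loose: 2 replicates only)
  expect_lte(map_row$info_bits_mean,
             ex_row$info_bits_mean + 3 * (map_row$info_bits_std + 1e-3))
  expect_gte(ub_row$info_bits_mean + 3 * (ub_row$info_bits_std + 1e-3),
             map_row$info_bits_mean)
})

test_that("Example 2 accumulates no information after the switch", {
  # production is input-independent for t >= 1000: extending the horizon
  # from 1200 to 2000 must leave the exact information flat within error
  ex <- make_example(2)
  v <- vapply(c(1200, 2000), function(Tend) {
    tset <- simulate_dataset(ex$network, ex$ensemble, ex$x0, Tend, 250,
                             seed = 71L)
    model <- path_model(ex$network, ex$ensemble, ex$x0, Tend, caps = 50L)
    exact_info(model, tset)$value
  }, numeric(1))
  expect_lt(abs(v[2] - v[1]), 0.05)
})
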