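# decision values frozen from an independent reference SVM implementation
# (tol 1e-6 QP solution) on a 12-point planar fixture
test_that("SVM dual solver reproduces reference decision values", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 2, 2, 1, 2, -1, 0, 3, 3, 3, 2, 2, 3,
                0, 2, 1, 1, 4, 4), ncol = 2, byrow = TRUE)
  y <- c(-1, -1, -1, 1, 1, -1, 1, 1, 1, -1, -1, 1)
  f_lin <- trajinfo:::.svm_binary_fit(X, y, "linear", NA, 1)
  expect_equal(trajinfo:::.svm_binary_decision(f_lin, X),
               c(-3, -2, -2, 1, 0, -4, 3, 2, 2, -1, -1, 5),
               tolerance = 0.01)
  # rbf with kernel width sigma = 1 (gamma = 1/2)
  f_rbf <- trajinfo:::.svm_binary_fit(X, y, "rbf", 1, 1)
  expect_equal(trajinfo:::.svm_binary_decision(f_rbf, X),
               c(-1.131850, -1.000000, -1.241345, 1.000000, 0.147663,
                 -1.000000, 1.039824, 1.000000, 1.000000, -0.779806,
                 -0.839591, 0.999999),
               tolerance = 0.01)
})

test_that("every decoder separates trivially separable classes", {
  X <- rbind(matrix(0, 30, 5), matrix(1, 30, 5)) +
    matrix(rnorm(300, 0, 1e-3), 60)
  dat <- labeled_dataset(X, rep(c("lo", "hi"), each = 30))
  for (m in c("svm-linear", "svm-rbf", "gaussian-decoder", "mlp")) {
    sp <- decoder_spec(m, C_grid = 1, sigma_mult = 1, cv_folds = 2,
                       hidden = c(16L, 8L), epochs = 40L)
    dec <- fit_decoder(dat, sp, seed = 3L)
    expect_equal(mean(predict(dec, X) == dat$labels), 1,
                 info = paste("method:", m))
  }
})

test_that("rbf kernel separates rings where the linear kernel cannot", {
  dat <- fix_rings()
  rbf <- fit_decoder(dat, decoder_spec("svm-rbf", C_grid = c(1, 10),
                                       sigma_mult = c(0.5, 1, 2),
                                       cv_folds = 3), seed = 2L)
  lin <- fit_decoder(dat, decoder_spec("svm-linear", C_grid = 1,
                                       cv_folds = 2), seed = 2L)
  expect_gt(mean(predict(rbf, dat$X) == dat$labels), 0.95)
  expect_lt(mean(predict(lin, dat$X) == dat$labels), 0.75)
})

test_that("gaussian decoder is chance-level on statistically identical classes", {
  set.seed(21)
  X <- matrix(rnorm(200 * 4), 200, 4)
  dat <- labeled_dataset(X, rep(c("a", "b"), 100))
  dec <- fit_decoder(dat, decoder_spec("gaussian-decoder"), seed = 4L)
  set.seed(22)
  Xtest <- matrix(rnorm(400 * 4), 400, 4)
  acc <- mean(predict(dec, Xtest) == rep(c("a", "b"), 200))
  expect_lt(abs(acc - 0.5), 0.12)
})

test_that("dendrogram-SVM handles more than two classes", {
  set.seed(31)
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  X <- do.call(rbind, lapply(1:4, function(j)
    sweep(matrix(rnorm(60), 30, 2), 2, centers[j, ], "+")))
  dat <- labeled_dataset(X, rep(paste0("c", 1:4), each = 30))
  dec <- fit_decoder(dat, decoder_spec("svm-linear", C_grid = 1, cv_folds = 2),
                     seed = 5L)
  expect_gt(mean(predict(dec, X) == dat$labels), 0.95)
})

test_that("estimate_info runs the split/refit/decode protocol", {
  dat <- fix_blobs()
  res <- estimate_info(dat, decoder_spec("svm-linear", C_grid = c(0.1, 1),
                                         cv_folds = 3),
                       replicates = 4L, seed = 2L)
  expect_length(res$replicates, 4L)
  expect_gt(res$value, 0.5)          # well-separated blobs: near 1 bit
  expect_lte(res$value, 1)
  expect_gte(res$std, 0)
  # shuffle control: no real structure survives the label permutation
  sh <- estimate_info(shuffle_labels(dat, 5L),
                      decoder_spec("svm-linear", C_grid = 1, cv_folds = 2),
                      replicates = 4L, seed = 2L)
  expect_lt(sh$value, 0.08)
})

test_that("knn mutual information recovers a numerically integrated truth", {
  # 1-D two-Gaussian mixture: truth via quadrature of the mixture entropy
  set.seed(12)
  n <- 800
  X <- matrix(c(rnorm(n, 0, 1), rnorm(n, 2, 1)), ncol = 1)
  dat <- labeled_dataset(X, rep(c("a", "b"), each = n))
  mix <- function(x) 0.5 * dnorm(x, 0, 1) + 0.5 * dnorm(x, 2, 1)
  HX <- stats::integrate(function(x) -mix(x) * log2(mix(x)), -8, 10)$value
  truth <- HX - 0.5 * log2(2 * pi * exp(1))
  est <- knn_mutual_information(dat, k = 3L)
  expect_equal(est, truth, tolerance = 0.08)
  # labels independent of the data: estimate collapses to zero
  shuf <- knn_mutual_information(shuffle_labels(dat, 3L), k = 3L)
  expect_lt(abs(shuf), 0.05)
  expect_error(knn_mutual_information(dat, k = 800L), "class count")
})

test_that("tied integer points trigger the documented warning, jitter clears it", {
  X <- matrix(rep(c(0, 0, 1, 1), each = 10), ncol = 1)
  dat <- labeled_dataset(X, rep(c("a", "b"), 20))
  expect_warning(knn_mutual_information(dat, k = 1L), "tied")
  expect_silent(knn_mutual_information(dat, k = 1L, jitter_sd = 1e-3))
})

test_that("gaussian approximation: zero for identical classes, 1 bit when far", {
  set.seed(41)
  Z <- matrix(rnorm(600), ncol = 2)
  same <- labeled_dataset(rbind(Z, Z), rep(c("a", "b"), each = 300))
  expect_lt(abs(gaussian_approximation_info(same, n_mc = 20000L)), 0.05)
  far <- labeled_dataset(matrix(c(rnorm(400), rnorm(400, 25)), ncol = 1),
                         rep(c("a", "b"), each = 400))
  expect_equal(suppressWarnings(gaussian_approximation_info(far, n_mc = 20000L)),
               1, tolerance = 0.05)
})

test_that("exponential filter: identity limit, constants, step response", {
  X <- matrix(c(0, 0, 0, 1, 1, 1,
                5, 5, 5, 5, 5, 5), 2, byrow = TRUE)
  dat <- labeled_dataset(X, c("a", "b"), dt = 1)
  # constant rows pass through unchanged
  expect_equal(exponential_filter(dat, tau = 7)$X[2, ], rep(5, 6))
  # tau -> 0 approaches the identity
  expect_equal(exponential_filter(dat, tau = 1e-8)$X[1, ], X[1, ])
  # step response follows 1 - exp(-i dt / tau) past the step
  tau <- 2
  f <- exponential_filter(dat, tau)$X[1, ]
  a <- exp(-1 / tau)
  expect_equal(f[4:6], 1 - a^(1:3), tolerance = 1e-12)
  expect_error(exponential_filter(dat, 0), "tau")
})
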