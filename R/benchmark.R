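#' Run the estimator comparison harness on a packaged example
#'
#' For each replicate, simulates a fresh labeled dataset from the chosen
#' benchmark network, resamples it on a uniform grid, and evaluates the
#' requested quantities on identical data: the exact Monte-Carlo information
#' (discrete mode), the MAP decoding bounds, any requested model-free
#' decoding estimators, the knn and Gaussian-approximation baselines, and
#' optionally a label-shuffle control. Results are aggregated over
#' replicates into a tidy table.
#'
#' @param example_id 1, 2 or 3, or \code{"multilevel2"} (with \code{q}).
#' @param methods character vector among \code{"exact"}, \code{"map"},
#'   \code{"svm-linear"}, \code{"svm-rbf"}, \code{"gaussian-decoder"},
#'   \code{"mlp"}, \code{"knn"}, \code{"gauss-approx"}.
#' @param n_per_input paths per input per replicate (paper scale: 1000; the
#'   scaled-down default keeps a laptop run in minutes).
#' @param d grid size for the discrete representation.
#' @param q input levels (multilevel example only).
#' @param T_end horizon.
#' @param replicates independent repeats.
#' @param shuffle_control also evaluate every decoding method on
#'   label-shuffled data.
#' @param spec_overrides named list of [decoder_spec()] arguments applied to
#'   every decoder (e.g. smaller grids for quick runs).
#' @param seed master seed.
#' @return data.frame with columns method, example, q, d, N, replicates,
#'   info_bits_mean, info_bits_std, seed.
#' @export
run_benchmark <- function(example_id = 1, methods = c("exact", "map", "svm-rbf"),
                          n_per_input = 300L, d = 50L, q = 2L, T_end = 2000,
                          replicates = 5L, shuffle_control = FALSE,
                          spec_overrides = list(), seed = 1L) {
  ex <- if (identical(example_id, "multilevel2")) make_multilevel_example2(q)
        else make_example(as.integer(example_id))
  ex$T <- T_end
  decoder_methods <- intersect(methods, c("svm-linear", "svm-rbf",
                                          "gaussian-decoder", "mlp"))
  acc <- list()
  model <- NULL
  for (r in seq_len(replicates)) {
    tset <- simulate_dataset(ex$network, ex$ensemble, ex$x0, ex$T, n_per_input,
                             seed = .substream_seed(seed, 2654435761 %% 2^31 + r))
    dat <- resample_dataset(tset, d)
    if (("exact" %in% methods) || ("map" %in% methods)) {
      if (is.null(model) || any(.observed_caps(tset) > model$space$caps)) {
        caps <- pmax(default_state_cap(ex$network, ex$x0),
                     .observed_caps(tset) + 2L)
        model <- path_model(ex$network, ex$ensemble, ex$x0, ex$T, caps = caps)
      }
      if ("exact" %in% methods)
        acc <- .bench_add(acc, "exact", r, exact_info(model, dat)$value)
      if ("map" %in% methods) {
        b <- map_info_bound(model, dat)
        acc <- .bench_add(acc, "map", r, b$I_MAP)
        acc <- .bench_add(acc, "map-upper", r, b$I_UB)
      }
    }
    for (m in decoder_methods) {
      sp <- do.call(decoder_spec, c(list(method = m), spec_overrides))
      est <- estimate_info(dat, sp, replicates = 1L,
                           seed = .substream_seed(seed, 7001L + r))
      acc <- .bench_add(acc, m, r, est$value)
    }
    if ("knn" %in% methods)
      acc <- .bench_add(acc, "knn", r,
                        knn_mutual_information(dat, k = 1L,
                                               seed = .substream_seed(seed, r)))
    if ("gauss-approx" %in% methods)
      acc <- .bench_add(acc, "gauss-approx", r,
                        gaussian_approximation_info(dat, seed = .substream_seed(seed, r)))
    if (shuffle_control) {
      sh <- shuffle_labels(dat, seed = .substream_seed(seed, 999L + r))
      for (m in decoder_methods) {
        sp <- do.call(decoder_spec, c(list(method = m), spec_overrides))
        est <- estimate_info(sh, sp, replicates = 1L,
                             seed = .substream_seed(seed, 1999L + r))
        acc <- .bench_add(acc, paste0(m, "-shuffled"), r, est$value)
      }
    }
  }
  do.call(rbind, lapply(names(acc), function(m) {
    data.frame(method = m, example = as.character(example_id),
               q = ex$ensemble$q, d = d, N = n_per_input,
               replicates = length(acc[[m]]),
               info_bits_mean = mean(acc[[m]]),
               info_bits_std = if (length(acc[[m]]) > 1L) stats::sd(acc[[m]]) else NA_real_,
               seed = seed, stringsAsFactors = FALSE)
  }))
}

.bench_add <- function(acc, method, r, value) {
  acc[[method]] <- c(acc[[method]], value)
  acc
}
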