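#' Read a labeled discrete-trajectory table
#'
#' Reads a delimited text table with one row per cell/trajectory: an id
#' column (optional), a label column, and d numeric sample columns — the
#' layout of typical single-cell time-series exports. Metadata lines of the
#' form \code{# key=value} (dt, T, x0) before the header are honoured.
#'
#' @param path file path.
#' @param label_col name of the label column (default \code{"input_label"}).
#' @param sep field separator (default comma).
#' @return a [labeled_dataset()].
#' @export
read_discrete_dataset <- function(path, label_col = "input_label", sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 20L)
  meta <- list()
  for (ln in hdr[startsWith(hdr, "#")]) {
    kv <- regmatches(ln, regexec("#\\s*(\\w+)\\s*=\\s*([-0-9.eE+]+)", ln))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- as.numeric(kv[3])
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop("empty dataset: ", path)
  if (!label_col %in% names(df))
    stop("missing label column '", label_col, "' in ", path)
  labels <- as.character(df[[label_col]])
  drop <- c(label_col, intersect("trajectory_id", names(df)))
  V <- df[, setdiff(names(df), drop), drop = FALSE]
  for (j in seq_along(V)) {
    v <- suppressWarnings(as.numeric(V[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric or missing value at row ", bad, ", column '",
           names(V)[j], "'")
    }
    V[[j]] <- v
  }
  labeled_dataset(as.matrix(V), labels,
                  x0 = meta$x0, dt = meta$dt, T_end = meta$T,
                  provenance = paste0("file:", path))
}

#' Write a labeled discrete-trajectory table
#'
#' Wide CSV (trajectory_id, input_label, x_1..x_d) preceded by \code{# dt=},
#' \code{# T=}, \code{# x0=} metadata comment lines; round-trips through
#' [read_discrete_dataset()] bit-exactly.
#'
#' @param data a [labeled_dataset()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_discrete_dataset <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("dt", "T", "x0")) {
    v <- data[[if (key == "T") "T" else key]]
    if (!is.null(v)) writeLines(sprintf("# %s=%.17g", key, v[1L]), con)
  }
  df <- data.frame(trajectory_id = seq_len(nrow(data$X)),
                   input_label = data$labels, data$X,
                   check.names = FALSE)
  names(df)[-(1:2)] <- paste0("x_", seq_len(ncol(data$X)))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a continuous trajectory set as an event-list CSV
#'
#' Long format with columns (trajectory_id, input_label, state, dwell_time);
#' multi-species states are serialized as colon-separated counts.
#'
#' @param tset a \code{traj_set}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_event_list <- function(tset, path) {
  rows <- lapply(seq_along(tset$paths), function(i) {
    p <- tset$paths[[i]]
    data.frame(trajectory_id = i, input_label = p$input,
               state = apply(p$states, 1L, paste, collapse = ":"),
               dwell_time = p$dwell, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a network specification from JSON
#'
#' Layout: \code{species} (array), \code{reactions} (array of objects with
#' \code{reactants}, \code{products} and \code{rate}), optional
#' \code{inputs}. A rate is a number, an object mapping input label to a
#' number, or an object mapping input label to
#' \code{\{"breakpoints": [...], "values": [...]\}}.
#'
#' @param path JSON file path.
#' @return a [reaction_network()].
#' @export
read_network_json <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  reaction_network(species = unlist(js$species),
                   reactions = js$reactions,
                   inputs = if (!is.null(js$inputs)) unlist(js$inputs) else NULL)
}

#' Write a results table with a JSON sidecar
#'
#' CSV in the fixed column order (method, example, q, d, N, replicates,
#' info_bits_mean, info_bits_std, seed); the sidecar \code{<path>.json}
#' records the full configuration, the seed, and the package version so a
#' run can be reproduced.
#'
#' @param results data.frame as produced by [run_benchmark()].
#' @param path output CSV path.
#' @param config named list of run settings recorded in the sidecar.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path, config = list()) {
  if (!nrow(results)) stop("empty results table")
  cols <- c("method", "example", "q", "d", "N", "replicates",
            "info_bits_mean", "info_bits_std", "seed")
  missing <- setdiff(cols, names(results))
  if (length(missing)) stop("results missing columns: ",
                            paste(missing, collapse = ", "))
  utils::write.csv(results[, cols], path, row.names = FALSE, quote = FALSE)
  sidecar <- c(config,
               list(package_version =
                      as.character(utils::packageVersion("trajinfo")),
                    written = "trajinfo::write_results"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
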