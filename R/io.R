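#' Read and write the delimited formats used by the pipeline
#'
#' Feature tables are headered comma-separated text, one row per
#' participant. Waveforms are two-column (`time_s`, `angle_deg`) CSV;
#' relocation-trial markers live in a sidecar CSV (`trial_id`,
#' `start_sample`, `end_sample`). Correlation and weight matrices are
#' square headered CSV.
#'
#' @param table Data frame to write.
#' @param path File path.
#' @name necknet-io
NULL

#' @rdname necknet-io
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname necknet-io
#' @export
read_feature_table <- function(path) {
  read.csv(path, check.names = FALSE)
}

#' @rdname necknet-io
#' @param w A `necknet_waveform`.
#' @export
write_angle_waveform <- function(w, path) {
  stopifnot(inherits(w, "necknet_waveform"))
  t_s <- (seq_along(w$samples) - 1) / w$fs_hz
  write.csv(data.frame(time_s = t_s, angle_deg = w$samples), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname necknet-io
#' @param plane Movement-plane label to attach on read.
#' @export
read_angle_waveform <- function(path, plane = "flexion-extension") {
  d <- read.csv(path)
  if (!all(c("time_s", "angle_deg") %in% names(d)))
    stop(path, ": expected columns time_s, angle_deg")
  dt <- diff(d$time_s)
  if (length(dt) < 1 || any(dt <= 0))
    stop(path, ": time_s must be strictly increasing")
  angle_waveform(d$angle_deg, fs_hz = 1 / median(dt), plane = plane)
}

#' @rdname necknet-io
#' @param m Square numeric matrix.
#' @export
write_square_matrix <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname necknet-io
#' @export
read_square_matrix <- function(path) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  rownames(m) <- colnames(m)
  m
}

#' Export a network's edges
#'
#' @param network A `necknet_network`.
#' @param path Output file.
#' @param zero_tol Edges at or below this absolute weight are omitted.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(network, path, zero_tol = 1e-8) {
  w <- network$weights
  ut <- which(upper.tri(w) & abs(w) > zero_tol, arr.ind = TRUE)
  df <- data.frame(node_a = rownames(w)[ut[, 1]],
                   node_b = colnames(w)[ut[, 2]],
                   weight = w[ut])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  w <- network$weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
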