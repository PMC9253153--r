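#' Node strength
#'
#' Sum of absolute edge weights incident to each node.
#'
#' @param weights Symmetric partial-correlation (edge-weight) matrix with
#'   zero diagonal.
#' @return Named numeric vector.
#' @export
node_strength <- function(weights) {
  check_weights(weights)
  rowSums(abs(weights))
}

check_weights <- function(weights) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("weights must be a square matrix")
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("weights must be symmetric")
  if (any(diag(weights) != 0))
    stop("weights must have a zero diagonal")
  invisible(weights)
}

# igraph representation with the conventional edge length 1 / |w|.
weights_to_graph <- function(weights) {
  a <- abs(weights)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Shortest-path distance matrix of a weighted network
#'
#' Edges are assigned length `1 / |w_ij|` (strong associations are short)
#' and distances are shortest paths over those lengths (Dijkstra).
#' Unreachable pairs get `Inf`.
#'
#' @inheritParams node_strength
#' @return Symmetric distance matrix with zero diagonal.
#' @export
node_distances <- function(weights) {
  check_weights(weights)
  g <- weights_to_graph(weights)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(weights), ncol(weights), dimnames = dimnames(weights))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = igraph::E(g)$length, algorithm = "dijkstra")
}

#' Closeness centrality
#'
#' Inverse of the summed shortest-path distance from each node to all
#' others; a node with any unreachable peer gets closeness 0.
#'
#' @inheritParams node_strength
#' @return Named numeric vector.
#' @export
node_closeness <- function(weights) {
  d <- node_distances(weights)
  tot <- rowSums(d)
  ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
}

#' Betweenness centrality
#'
#' Number of shortest paths (with edge lengths `1 / |w|`) between other node
#' pairs that pass through each node, with equal fractional credit among
#' tied shortest paths (Brandes' accumulation).
#'
#' @inheritParams node_strength
#' @return Named numeric vector.
#' @export
node_betweenness <- function(weights) {
  check_weights(weights)
  g <- weights_to_graph(weights)
  if (igraph::ecount(g) == 0)
    return(setNames(numeric(nrow(weights)), rownames(weights)))
  igraph::betweenness(g, weights = igraph::E(g)$length, directed = FALSE)
}

#' Centrality profile of a network
#'
#' @param network A `necknet_network` from [select_network()], or a raw
#'   weight matrix.
#' @param standardize Return z-standardized indices instead of raw values.
#' @return Data frame with columns `node`, `strength`, `closeness`,
#'   `betweenness`.
#' @export
#' @examples
#' centrality_profile(neck_pain_network())
centrality_profile <- function(network, standardize = FALSE) {
  w <- if (inherits(network, "necknet_network")) network$weights else network
  out <- data.frame(
    node = if (!is.null(rownames(w))) rownames(w) else paste0("V", 1:nrow(w)),
    strength = unname(node_strength(w)),
    closeness = unname(node_closeness(w)),
    betweenness = unname(node_betweenness(w)),
    stringsAsFactors = FALSE)
  if (standardize)
    for (j in c("strength", "closeness", "betweenness"))
      out[[j]] <- as.numeric(scale(out[[j]]))
  out
}
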