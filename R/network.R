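#' Binary network container
#'
#' An undirected, unweighted network on a fixed node order, stored as a
#' symmetric, hollow 0/1 adjacency matrix. All generative-model, rewiring,
#' and evaluation code in the package consumes and produces this class.
#'
#' @param A square numeric/integer matrix; coerced to 0/1. Must be symmetric
#'   with an all-zero diagonal.
#' @return An object of class `binary_network` with elements `A` (adjacency
#'   matrix), `n` (node count) and `m` (edge count).
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
#' net <- binary_network(A)
#' net$m
#' @export
binary_network <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop_input("adjacency must be a square matrix")
  }
  storage.mode(A) <- "double"
  if (!all(A %in% c(0, 1))) stop_input("adjacency entries must be 0 or 1")
  if (any(diag(A) != 0)) stop_input("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    stop_input("adjacency must be symmetric")
  }
  dimnames(A) <- NULL
  structure(
    list(A = A, n = nrow(A), m = as.integer(sum(A) / 2)),
    class = "binary_network"
  )
}

#' Build a network from an edge list
#'
#' @param edges two-column matrix/data.frame of node indices (1-based in R;
#'   see [read_network()] for the 0-based file convention). Duplicate and
#'   reversed pairs collapse to a single undirected edge.
#' @param n node count.
#' @return A [binary_network()].
#' @export
network_from_edges <- function(edges, n) {
  edges <- as.matrix(edges)
  if (length(edges) && (any(edges < 1) || any(edges > n))) {
    stop_input("edge references node outside 1..n")
  }
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    A[cbind(edges[, 1], edges[, 2])] <- 1
    A[cbind(edges[, 2], edges[, 1])] <- 1
  }
  diag(A) <- 0
  binary_network(A)
}

#' Edge list of a network
#'
#' @param net a [binary_network()].
#' @return two-column integer matrix of edges with i < j, in pair-id order.
#' @export
network_edges <- function(net) {
  idx <- which(net$A == 1 & upper.tri(net$A), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(pair_id(idx[, 1], idx[, 2], net$n)), , drop = FALSE]
}

# pair ids (upper-tri order) of present edges
edge_pair_ids <- function(net) {
  which(net$A[pair_linear_index(net$n)] == 1)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (density %.3f)\n",
              x$n, x$m, 2 * x$m / (x$n * (x$n - 1))))
  invisible(x)
}

# convert to an igraph object (vertices kept even when isolated)
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$A, mode = "undirected", diag = FALSE)
}
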