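#' Spatial embedding of network nodes
#'
#' Holds node coordinates (mm), the pairwise Euclidean wiring-cost matrix
#' `D`, and a surface-adjacency graph used only for feature smoothing.
#' Wiring cost between two regions is approximated by the Euclidean distance
#' between their centroids.
#'
#' @param coords numeric matrix, one row per node, 3 columns (x, y, z in mm).
#' @param node_ids optional character vector of node labels.
#' @param neighbor_graph optional symmetric hollow 0/1 matrix marking nodes
#'   treated as adjacent for smoothing; defaults to a symmetrized k-nearest
#'   neighbour graph (see [make_embedding()]).
#' @param k neighbours used when `neighbor_graph` is built from `coords`.
#' @return Object of class `spatial_embedding` with elements `node_ids`,
#'   `coords`, `D`, `neighbor_graph`, `n`.
#' @export
spatial_embedding <- function(coords, node_ids = NULL, neighbor_graph = NULL,
                              k = 6) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (nrow(coords) < 2) stop_input("need at least 2 nodes")
  if (ncol(coords) != 3) stop_input("coords must have 3 columns (x, y, z)")
  n <- nrow(coords)
  node_ids <- node_ids %||% paste0("node", seq_len(n) - 1L)
  D <- as.matrix(dist(coords))
  dimnames(D) <- NULL
  if (any(D[upper.tri(D)] == 0)) {
    stop_input("degenerate geometry: duplicate coordinates give zero distance")
  }
  if (is.null(neighbor_graph)) {
    neighbor_graph <- knn_graph(D, k = k)
  } else {
    neighbor_graph <- check_neighbor_graph(neighbor_graph, n)
  }
  structure(
    list(node_ids = node_ids, coords = coords, D = D,
         neighbor_graph = neighbor_graph, n = n),
    class = "spatial_embedding"
  )
}

check_neighbor_graph <- function(G, n) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (nrow(G) != n || ncol(G) != n) stop_input("neighbor_graph has wrong size")
  if (!all(G %in% c(0, 1)) || any(diag(G) != 0) || !isTRUE(all.equal(G, t(G)))) {
    stop_input("neighbor_graph must be a symmetric hollow 0/1 matrix")
  }
  G
}

# symmetrized (union) k-nearest-neighbour graph; components joined through
# their closest cross-component pair so the graph is always connected
knn_graph <- function(D, k = 6) {
  n <- nrow(D)
  k <- min(k, n - 1L)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    G[i, nb] <- 1
  }
  G <- pmax(G, t(G))
  comp <- graph_components(G)
  while (max(comp) > 1L) {
    in1 <- comp == 1L
    Dx <- D[in1, !in1, drop = FALSE]
    hit <- which(Dx == min(Dx), arr.ind = TRUE)[1, ]
    i <- which(in1)[hit[1]]
    j <- which(!in1)[hit[2]]
    G[i, j] <- G[j, i] <- 1
    comp <- graph_components(G)
  }
  G
}

# connected-component labels by BFS on a 0/1 adjacency matrix
graph_components <- function(G) {
  n <- nrow(G)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(G[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Generate a random spatial embedding
#'
#' Draws `n` node coordinates in one of three geometries and packages them
#' as a [spatial_embedding()]:
#' * `"shell"` — uniform points on a hemispheric shell of radius `scale`,
#'   mimicking a cortical hemisphere;
#' * `"sheet"` — uniform points on a `scale` x `scale` flat patch;
#' * `"cloud"` — uniform points in a cube of side `scale`.
#'
#' @param n node count (>= 2).
#' @param geometry one of `"shell"`, `"sheet"`, `"cloud"`.
#' @param scale linear size in mm (> 0).
#' @param k neighbours for the surface-adjacency graph (symmetrized union).
#' @param seed integer seed; identical inputs reproduce coordinates exactly.
#' @return A [spatial_embedding()].
#' @examples
#' emb <- make_embedding(50, "shell", scale = 100, seed = 1)
#' range(emb$D[upper.tri(emb$D)])
#' @export
make_embedding <- function(n, geometry = c("shell", "sheet", "cloud"),
                           scale = 100, k = 6, seed = 1) {
  geometry <- match.arg(geometry)
  if (n < 2) stop_input("n must be >= 2")
  if (scale <= 0) stop_input("scale must be positive")
  coords <- withr::with_seed(as.integer(seed), {
    switch(geometry,
      shell = {
        # uniform on the z >= 0 half of a sphere of radius `scale`
        z <- runif(n, 0, 1)
        phi <- runif(n, 0, 2 * pi)
        r <- sqrt(1 - z^2)
        scale * cbind(r * cos(phi), r * sin(phi), z)
      },
      sheet = cbind(runif(n, 0, scale), runif(n, 0, scale), 0),
      cloud = cbind(runif(n, 0, scale), runif(n, 0, scale), runif(n, 0, scale))
    )
  })
  spatial_embedding(coords, k = k)
}

#' @export
print.spatial_embedding <- function(x, ...) {
  cat(sprintf("<spatial_embedding> %d nodes, distances %.1f-%.1f mm\n",
              x$n, min(x$D[upper.tri(x$D)]), max(x$D)))
  invisible(x)
}
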