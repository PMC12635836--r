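#' Random spatially autocorrelated nodal features
#'
#' Builds a node-by-feature table of random values with spatial
#' autocorrelation imposed by neighbour smoothing: each feature starts as an
#' independent uniform(0, 1) draw per node, then undergoes `n_smooth`
#' synchronous rounds in which every node's value is replaced by the mean of
#' its neighbours' values on the embedding's surface-adjacency graph. The
#' update is synchronous: all means are computed from the pre-round state
#' before any node is updated.
#'
#' @param embedding a [spatial_embedding()] whose `neighbor_graph` is
#'   connected with no isolated node.
#' @param n_features number of independent feature columns (default 20).
#' @param n_smooth smoothing rounds (default 5); `0` returns the raw draws.
#' @param seed integer seed.
#' @param init optional node x feature matrix overriding the uniform
#'   initialization (used to inject degenerate starting states).
#' @return Object of class `feature_table`: `values` (node x feature matrix),
#'   `n_features`, and `provenance` (generator parameters).
#' @export
smooth_random_features <- function(embedding, n_features = 20, n_smooth = 5,
                                   seed = 1, init = NULL) {
  G <- embedding$neighbor_graph
  deg <- rowSums(G)
  if (any(deg == 0)) {
    stop_input("neighbor_graph has isolated node(s): ",
               paste(which(deg == 0), collapse = ", "))
  }
  n <- embedding$n
  vals <- if (is.null(init)) {
    withr::with_seed(as.integer(seed), matrix(runif(n * n_features), n, n_features))
  } else {
    v <- as.matrix(init)
    if (nrow(v) != n || ncol(v) != n_features) stop_input("init has wrong shape")
    v
  }
  for (r in seq_len(n_smooth)) {
    vals <- (G %*% vals) / deg
  }
  vals <- unname(as.matrix(vals))
  structure(
    list(values = vals, n_features = n_features,
         provenance = list(seed = seed, n_smooth = n_smooth,
                           n_features = n_features,
                           injected_init = !is.null(init))),
    class = "feature_table"
  )
}

#' Interregional similarity from nodal feature profiles
#'
#' Correlates every pair of node feature profiles (Pearson, across feature
#' columns) and rescales the correlation to the unit interval. Two
#' orientations are supported:
#' * `"similarity"` (default): `F = (r + 1) / 2`, so 1 marks perfectly
#'   correlated profiles — the orientation under which a positive feature
#'   exponent rewards similar regions;
#' * `"distance"`: the Pearson distance `1 - r` rescaled to `[0, 1]`,
#'   i.e. `F = (1 - r) / 2` (the literal correlation-to-distance reading).
#'
#' Flipping orientation maps `F` to `1 - F` exactly.
#'
#' @param features a [smooth_random_features()] table, or a plain node x
#'   feature matrix.
#' @param orientation `"similarity"` or `"distance"`.
#' @return Object of class `similarity_matrix`: `F` (symmetric node x node
#'   matrix in `[0, 1]`, unit diagonal under `"similarity"`; consumers
#'   ignore the diagonal) and `orientation`.
#' @export
feature_similarity <- function(features,
                               orientation = c("similarity", "distance")) {
  orientation <- match.arg(orientation)
  vals <- if (inherits(features, "feature_table")) features$values else as.matrix(features)
  if (ncol(vals) < 2) stop_input("need at least 2 features to correlate profiles")
  profile_sd <- apply(vals, 1, sd)
  if (any(profile_sd == 0)) {
    stop_input("zero-variance node profile(s): ",
               paste(which(profile_sd == 0), collapse = ", "))
  }
  r <- cor(t(vals))
  Fm <- if (orientation == "similarity") (r + 1) / 2 else (1 - r) / 2
  Fm <- (Fm + t(Fm)) / 2           # guard against asymmetric rounding
  Fm <- pmin(pmax(Fm, 0), 1)
  dimnames(Fm) <- NULL
  similarity_matrix(Fm, orientation)
}

#' Similarity matrix container
#'
#' @param F symmetric node x node matrix with entries in `[0, 1]`.
#' @param orientation `"similarity"` (large = alike) or `"distance"`
#'   (large = unalike); recorded so consumers know the reading.
#' @return Object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(F, orientation = c("similarity", "distance")) {
  orientation <- match.arg(orientation)
  F <- as.matrix(F)
  if (nrow(F) != ncol(F)) stop_input("similarity matrix must be square")
  if (!isTRUE(all.equal(F, t(F)))) stop_input("similarity matrix must be symmetric")
  if (any(F < 0) || any(F > 1)) stop_input("similarity entries must lie in [0, 1]")
  structure(list(F = F, orientation = orientation), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d nodes, orientation = %s\n",
              nrow(x$F), x$orientation))
  invisible(x)
}
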