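#' Synthetic target network with planted long-range hub edges
#'
#' Builds a spatially embedded binary network whose background edges follow
#' an exponentially distance-dependent connection probability
#' (`Pr(edge) proportional to exp(-lambda * D_ij)`), optionally with a set of
#' long-range edges planted between spatially dispersed hub nodes. The
#' planted edges give the target the property that its degree topography is
#' shaped by a minority of long connections — the regime in which
#' cost-penalising generative models are expected to fail.
#'
#' @param embedding a [spatial_embedding()].
#' @param m total edge count (exactly; planted edges included).
#' @param lambda exponential decay rate of the background sampling weight,
#'   1/mm; `0` gives a uniform random graph.
#' @param hub_spec optional `list(n_hubs, long_cutoff, n_planted)`: `n_hubs`
#'   hubs are placed by farthest-point sampling on the coordinates, and
#'   `n_planted` inter-hub edges of length `>= long_cutoff` mm are planted.
#' @param seed integer seed.
#' @return Object of class `planted_target`: `network` ([binary_network()]),
#'   `planted_long_edges` (two-column matrix, possibly 0 rows), `hub_nodes`,
#'   `lambda`, `long_cutoff`.
#' @examples
#' emb <- make_embedding(60, "shell", seed = 1)
#' tgt <- plant_target(emb, m = 150, lambda = 0.1,
#'                     hub_spec = list(n_hubs = 6, long_cutoff = 90,
#'                                     n_planted = 10), seed = 2)
#' tgt$network$m
#' @export
plant_target <- function(embedding, m, lambda, hub_spec = NULL, seed = 1) {
  n <- embedding$n
  D <- embedding$D
  n_pairs <- n * (n - 1) / 2
  if (m > n_pairs) stop_input("m exceeds the number of node pairs")
  pt <- pair_table(n)
  dvec <- D[pair_linear_index(n)]

  hub_nodes <- integer(0)
  planted <- integer(0)
  n_planted <- 0L
  long_cutoff <- NA_real_

  seeds <- derive_seeds(seed, 3)

  if (!is.null(hub_spec)) {
    n_hubs <- hub_spec$n_hubs
    long_cutoff <- hub_spec$long_cutoff
    n_planted <- as.integer(hub_spec$n_planted)
    if (n_planted > m) stop_input("hub_spec infeasible: n_planted exceeds m")
    hub_nodes <- farthest_point_sample(D, n_hubs, seed = seeds[1])
    is_hub_pair <- pt[, 1] %in% hub_nodes & pt[, 2] %in% hub_nodes
    eligible <- which(is_hub_pair & dvec >= long_cutoff)
    if (length(eligible) < n_planted) {
      stop_input("hub_spec infeasible: only ", length(eligible),
                 " inter-hub pairs at or beyond the long cutoff, need ",
                 n_planted)
    }
    planted <- withr::with_seed(seeds[2], {
      eligible[sample.int(length(eligible), n_planted)]
    })
  }

  remaining <- setdiff(seq_len(n_pairs), planted)
  w <- exp(-lambda * dvec[remaining])
  # exponential-race weighted sample without replacement (robust when
  # lambda * D spans many orders of magnitude)
  filler <- withr::with_seed(seeds[3], {
    keys <- -log(runif(length(remaining))) / w
    remaining[order(keys, runif(length(remaining)))[seq_len(m - n_planted)]]
  })
  ids <- c(planted, filler)
  net <- network_from_edges(pt[ids, , drop = FALSE], n)
  structure(
    list(network = net,
         planted_long_edges = pt[planted, , drop = FALSE],
         hub_nodes = hub_nodes, lambda = lambda, long_cutoff = long_cutoff),
    class = "planted_target"
  )
}

# farthest-point sampling: random first pick, then greedy max-min distance
farthest_point_sample <- function(D, k, seed) {
  n <- nrow(D)
  if (k > n) stop_input("hub_spec infeasible: more hubs than nodes")
  first <- withr::with_seed(as.integer(seed), sample.int(n, 1))
  chosen <- first
  while (length(chosen) < k) {
    mind <- apply(D[, chosen, drop = FALSE], 1, min)
    mind[chosen] <- -Inf
    chosen <- c(chosen, which.max(mind))
  }
  sort(chosen)
}

#' Cohort of perturbed individual networks
#'
#' Derives `n_subjects` "individual" networks from a common base network by
#' applying `n_swaps` length-matched edge relocations to each (random edge
#' order, similar-length targets, via the rewiring engine). Every subject
#' keeps exactly the base edge count, and retains exactly
#' `(m - n_swaps) / m` of the base's edges.
#'
#' @param base a [binary_network()].
#' @param embedding the matching [spatial_embedding()].
#' @param n_subjects cohort size.
#' @param n_swaps edge relocations per subject (`<=` base edge count).
#' @param seed integer seed; one child seed per subject.
#' @return List of [binary_network()] objects.
#' @export
make_cohort <- function(base, embedding, n_subjects, n_swaps, seed = 1) {
  if (n_swaps > base$m) stop_input("n_swaps exceeds base edge count")
  seeds <- derive_seeds(seed, n_subjects)
  lapply(seq_len(n_subjects), function(s) {
    rewire_pass(base, embedding,
                ordering = "random", target_rule = "similar",
                n_rewires = n_swaps, seed = seeds[s])$network
  })
}
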