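#' Rewiring null-model configuration
#'
#' A single-pass, density-preserving rewiring null: every original edge is
#' processed exactly once, deleted, and replaced by a pair that was absent
#' in the original network (used replacement slots never re-enter the
#' candidate pool, and vacated slots are never refilled, so after t rewires
#' the overlap with the original network is exactly (m - t) / m).
#'
#' @param ordering order in which original edges are processed:
#'   `"random"`, `"ascending_length"` (shortest first), or
#'   `"descending_length"`; length ties are broken at random.
#' @param target_rule how the replacement pair is chosen from the remaining
#'   candidates: `"random"` (uniform), `"similar"` (minimum absolute length
#'   difference from the processed edge; ties at random), or `"dissimilar"`
#'   (maximum difference).
#' @param n_runs number of independent runs for ensemble curves.
#' @param checkpoint_step edges between metric snapshots; default
#'   `max(1, floor(m / 100))`.
#' @return Object of class `rewiring_config`.
#' @export
rewiring_config <- function(ordering = c("random", "ascending_length",
                                         "descending_length"),
                            target_rule = c("random", "similar", "dissimilar"),
                            n_runs = 30, checkpoint_step = NULL) {
  ordering <- match.arg(ordering)
  target_rule <- match.arg(target_rule)
  if (n_runs < 1) stop_input("n_runs must be >= 1")
  if (!is.null(checkpoint_step) && checkpoint_step < 1) {
    stop_input("checkpoint_step must be >= 1")
  }
  structure(list(ordering = ordering, target_rule = target_rule,
                 n_runs = n_runs, checkpoint_step = checkpoint_step),
            class = "rewiring_config")
}

# Core single-pass engine. Processes `n_rewires` original edges (in the
# configured order) and relocates each to an originally-absent pair.
# Returns the final network and, when `checkpoint_step` is given, a
# per-checkpoint data.frame of fit metrics against the original network.
rewire_pass <- function(net, embedding, ordering, target_rule, n_rewires,
                        seed, checkpoint_step = NULL, include_alt = FALSE) {
  n <- net$n
  m <- net$m
  if (m < 1) stop_input("network has no edges to rewire")
  dvec <- embedding$D[pair_linear_index(n)]
  orig_ids <- edge_pair_ids(net)
  pool <- setdiff(seq_len(n * (n - 1) / 2), orig_ids)
  if (n_rewires > length(pool)) {
    stop_input("candidate pool exhausted: ", n_rewires,
               " rewires requested but only ", length(pool),
               " originally absent pairs exist")
  }
  if (n_rewires > m) stop_input("cannot rewire more edges than the network has")
  pt <- pair_table(n)
  A <- net$A
  tv_orig <- if (!is.null(checkpoint_step)) topology_vectors(net, embedding)
  checks <- if (!is.null(checkpoint_step)) {
    unique(c(seq(checkpoint_step, n_rewires, by = checkpoint_step), n_rewires))
  } else {
    integer(0)
  }
  rows <- vector("list", length(checks))
  len_processed <- numeric(n_rewires)
  len_target <- numeric(n_rewires)

  withr::with_seed(as.integer(seed), {
    len_e <- dvec[orig_ids]
    ord <- switch(ordering,
      random = sample.int(m),
      ascending_length = order(len_e, runif(m)),
      descending_length = order(-len_e, runif(m))
    )
    process <- orig_ids[ord][seq_len(n_rewires)]
    avail <- pool
    ci <- 1L
    for (t in seq_len(n_rewires)) {
      e <- process[t]
      target <- switch(target_rule,
        random = avail[sample.int(length(avail), 1)],
        similar = {
          dif <- abs(dvec[avail] - dvec[e])
          cand <- which(dif == min(dif))
          avail[cand[sample.int(length(cand), 1)]]
        },
        dissimilar = {
          dif <- abs(dvec[avail] - dvec[e])
          cand <- which(dif == max(dif))
          avail[cand[sample.int(length(cand), 1)]]
        }
      )
      avail <- avail[avail != target]
      len_processed[t] <- dvec[e]
      len_target[t] <- dvec[target]
      A[pt[e, 1], pt[e, 2]] <- A[pt[e, 2], pt[e, 1]] <- 0
      A[pt[target, 1], pt[target, 2]] <- A[pt[target, 2], pt[target, 1]] <- 1
      if (ci <= length(checks) && t == checks[ci]) {
        cur <- binary_network(A)
        fr <- fit_result(cur, net, embedding, include_alt = include_alt,
                         tv_target = tv_orig)
        rows[[ci]] <- cbind(data.frame(n_rewired = t, prop_rewired = t / m), fr)
        ci <- ci + 1L
      }
    }
  })

  list(network = binary_network(A),
       checkpoints = if (length(rows)) do.call(rbind, rows) else NULL,
       swaps = data.frame(len_processed = len_processed,
                          len_target = len_target),
       seed = seed)
}

#' One full rewiring run
#'
#' Processes every edge of the network once under the configured ordering
#' and replacement rule, recording fit metrics against the original
#' network at regular checkpoints. The final checkpoint always sits at
#' proportion rewired = 1.
#'
#' @param network a [binary_network()] with at least one edge and at least
#'   as many originally absent pairs as edges.
#' @param embedding the matching [spatial_embedding()].
#' @param config a [rewiring_config()].
#' @param seed integer seed.
#' @param include_alt also record [alt_measures()] at checkpoints (slower).
#' @return Object of class `rewiring_trajectory`: `checkpoints` (data.frame
#'   with `n_rewired`, `prop_rewired`, and [fit_result()] columns),
#'   `network` (fully rewired), `swaps` (per-rewire processed and
#'   replacement edge lengths), `seed`, `config`.
#' @export
rewire_once <- function(network, embedding, config, seed = 1,
                        include_alt = FALSE) {
  step <- config$checkpoint_step %||% max(1L, floor(network$m / 100))
  res <- rewire_pass(network, embedding, config$ordering, config$target_rule,
                     n_rewires = network$m, seed = seed,
                     checkpoint_step = step, include_alt = include_alt)
  structure(list(checkpoints = res$checkpoints, network = res$network,
                 swaps = res$swaps, seed = seed, config = config),
            class = "rewiring_trajectory")
}

#' Ensemble of rewiring runs
#'
#' Runs [rewire_once()] `config$n_runs` times with independent child seeds.
#'
#' @inheritParams rewire_once
#' @return List of `rewiring_trajectory` objects.
#' @export
rewire_ensemble <- function(network, embedding, config, seed = 1,
                            include_alt = FALSE) {
  seeds <- derive_seeds(seed, config$n_runs)
  lapply(seeds, function(s) {
    rewire_once(network, embedding, config, seed = s, include_alt = include_alt)
  })
}

#' Mean rewiring curve across runs
#'
#' Pointwise mean and standard deviation of a selected fit measure across
#' a set of rewiring trajectories sharing the same checkpoint grid.
#'
#' @param trajectories list of `rewiring_trajectory` objects.
#' @param measure column of the checkpoint table to average (e.g. `"maxKS"`,
#'   `"KS_c"`, `"R"`).
#' @return data.frame `n_rewired`, `prop_rewired`, `mean`, `sd`.
#' @export
rewiring_curves <- function(trajectories, measure = "maxKS") {
  grids <- lapply(trajectories, function(tr) tr$checkpoints$n_rewired)
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop_input("trajectories have mismatched checkpoint grids")
  }
  vals <- vapply(trajectories, function(tr) tr$checkpoints[[measure]],
                 numeric(length(grids[[1]])))
  vals <- matrix(vals, nrow = length(grids[[1]]))
  data.frame(n_rewired = grids[[1]],
             prop_rewired = trajectories[[1]]$checkpoints$prop_rewired,
             mean = rowMeans(vals),
             sd = apply(vals, 1, sd))
}
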