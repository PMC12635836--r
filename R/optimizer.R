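#' Parameter search space
#'
#' Box bounds for the wiring-rule parameters actively searched. Inactive
#' parameters are `NULL` and held at the model template's value.
#'
#' @param eta `c(lo, hi)` for the distance penalty.
#' @param gamma `c(lo, hi)` for the feature exponent, or `NULL`.
#' @param alpha `c(lo, hi)` for the additive feature weight, or `NULL`.
#' @return Object of class `search_space`.
#' @export
search_space <- function(eta = c(0, 2), gamma = NULL, alpha = NULL) {
  check_bounds <- function(b, nm) {
    if (is.null(b)) return(NULL)
    if (length(b) != 2 || b[1] > b[2]) stop_input("invalid bounds for ", nm)
    b
  }
  structure(list(eta = check_bounds(eta, "eta"),
                 gamma = check_bounds(gamma, "gamma"),
                 alpha = check_bounds(alpha, "alpha")),
            class = "search_space")
}

#' Default search space for a model specification
#'
#' Standard fitting boxes: `eta` in `[0, 2]` for exponential decay or
#' `[0, 10]` for power-law; `gamma` in `[-20, 200]` for static similarity
#' features or `[-10, 10]` for topological (matching) features; `alpha` in
#' `[0, 10]` for additive feature models.
#'
#' @param spec a [model_spec()].
#' @return A [search_space()].
#' @export
default_search_space <- function(spec) {
  eta <- if (spec$params$decay == "exponential") c(0, 2) else c(0, 10)
  if (spec$feature_source == "spatial") {
    return(search_space(eta = eta))
  }
  gamma <- if (spec$feature_source == "static") c(-20, 200) else c(-10, 10)
  alpha <- if (spec$params$form == "additive") c(0, 10) else NULL
  search_space(eta = eta, gamma = gamma, alpha = alpha)
}

active_params <- function(space) {
  names(space)[!vapply(space, is.null, logical(1))]
}

#' Uniform initial sample of the search box
#'
#' @param space a [search_space()].
#' @param n number of points.
#' @param seed integer seed.
#' @return Matrix with one column per active parameter.
#' @export
initial_sample <- function(space, n = 2000, seed = 1) {
  act <- active_params(space)
  widths <- vapply(act, function(p) diff(space[[p]]), numeric(1))
  if (all(widths == 0) && n > 1) {
    warning("all parameter bounds are degenerate; sampled points are duplicates")
  }
  withr::with_seed(as.integer(seed), {
    pts <- vapply(act, function(p) runif(n, space[[p]][1], space[[p]][2]),
                  numeric(n))
    matrix(pts, nrow = n, dimnames = list(NULL, act))
  })
}

# rescale points to the unit box so no parameter's range dominates the
# tessellation distances
to_unit_box <- function(points, space) {
  act <- colnames(points)
  for (p in act) {
    lo <- space[[p]][1]; w <- diff(space[[p]])
    points[, p] <- if (w > 0) (points[, p] - lo) / w else 0
  }
  points
}

# nearest evaluated point (Voronoi cell membership) for each candidate row,
# computed in chunks to bound memory
nearest_cell <- function(candidates, points) {
  k <- nrow(points)
  out <- integer(nrow(candidates))
  chunk <- max(1L, floor(5e6 / k))
  for (start in seq(1L, nrow(candidates), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(candidates))
    d2 <- matrix(0, length(idx), k)
    for (j in seq_len(ncol(points))) {
      d2 <- d2 + outer(candidates[idx, j], points[, j], "-")^2
    }
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Voronoi preferential resampling
#'
#' Draws `n_new` parameter points concentrated in low-score regions: the
#' Voronoi cells of the evaluated points (nearest-neighbour membership in
#' the unit-rescaled box) are sampled multinomially with probability
#' proportional to `score^(-beta)` (scores floored at `1e-6`), and a point
#' inside each drawn cell is produced by rejection sampling — uniform box
#' candidates kept when their nearest evaluated point is the drawn cell's
#' seed. Cells not filled after 1,000 candidate batches fall back to a
#' Gaussian perturbation of the cell seed (sd = 5% of each box width,
#' clipped to the box).
#'
#' @param points matrix of evaluated parameter points (columns = active
#'   parameters).
#' @param scores their objective values (finite, >= 0).
#' @param space the [search_space()].
#' @param n_new number of points to draw (> 0).
#' @param beta resampling exponent; `0` ignores scores.
#' @param seed integer seed.
#' @return Matrix of `n_new` new points with the same columns as `points`.
#' @export
voronoi_resample <- function(points, scores, space, n_new = 2000, beta,
                             seed = 1) {
  if (n_new <= 0) stop_input("n_new must be positive")
  if (nrow(points) < 2) stop_input("need at least 2 evaluated points")
  if (any(!is.finite(scores)) || any(scores < 0)) {
    stop_input("scores must be finite and >= 0")
  }
  act <- colnames(points)
  unit_pts <- to_unit_box(points, space)
  probs <- pmax(scores, 1e-6)^(-beta)
  probs <- probs / sum(probs)
  lo <- vapply(act, function(p) space[[p]][1], numeric(1))
  wd <- vapply(act, function(p) diff(space[[p]]), numeric(1))

  withr::with_seed(as.integer(seed), {
    cells <- sample.int(nrow(points), n_new, replace = TRUE, prob = probs)
    need <- tabulate(cells, nbins = nrow(points))
    got <- vector("list", nrow(points))
    batches <- 0L
    while (sum(need) > 0 && batches < 1000L) {
      batches <- batches + 1L
      nb <- max(200L, 4L * sum(need))
      cand_unit <- matrix(runif(nb * length(act)), nb, length(act))
      owner <- nearest_cell(cand_unit, unit_pts)
      keep <- which(need[owner] > 0)
      for (i in keep) {
        cl <- owner[i]
        if (need[cl] > 0) {
          got[[cl]] <- c(got[[cl]], list(cand_unit[i, ]))
          need[cl] <- need[cl] - 1L
        }
      }
    }
    # fallback for sliver cells the rejection sampler failed to hit
    for (cl in which(need > 0)) {
      for (r in seq_len(need[cl])) {
        pert <- unit_pts[cl, ] + rnorm(length(act), 0, 0.05)
        got[[cl]] <- c(got[[cl]], list(pmin(pmax(pert, 0), 1)))
      }
      need[cl] <- 0L
    }
    unit_new <- do.call(rbind, unlist(got, recursive = FALSE, use.names = FALSE))
    unit_new <- matrix(unit_new, ncol = length(act))
    new_pts <- sweep(sweep(unit_new, 2, wd, "*"), 2, lo, "+")
    colnames(new_pts) <- act
    new_pts
  })
}

spec_with_params <- function(spec, theta) {
  p <- spec$params
  eta <- if ("eta" %in% names(theta)) unname(theta["eta"]) else p$eta
  gamma <- if ("gamma" %in% names(theta)) unname(theta["gamma"]) else p$gamma
  alpha <- if ("alpha" %in% names(theta)) unname(theta["alpha"]) else p$alpha
  model_spec(gnm_params(eta, gamma, alpha, form = p$form, decay = p$decay),
             feature = spec$feature, label = spec$label)
}

#' Fit wiring-rule parameters by Voronoi-tessellation resampling
#'
#' Minimises the max(KS) objective against one target network (or the mean
#' max(KS) over an ensemble of targets) over the parameter box. The search
#' draws an initial uniform sample, then repeats rounds of Voronoi
#' preferential resampling with an increasing exponent schedule, evaluating
#' each sampled point by growing one stochastic network (per-point growth
#' seeds are varied and recorded).
#'
#' @param spec a [model_spec()] template supplying the feature source, rule
#'   form, and decay; the searched parameters override its values.
#' @param targets a [binary_network()] or list of them (ensemble fitting:
#'   the objective is the mean of the per-target max(KS) values).
#' @param embedding the shared [spatial_embedding()].
#' @param space a [search_space()]; default [default_search_space()].
#' @param m_target edges to grow per evaluation; defaults to the (first)
#'   target's edge count.
#' @param budget list with `init` (initial sample size), `rounds`,
#'   `per_round`, and `beta` (per-round exponent schedule). The standard
#'   schedule is 2,000 initial points plus four rounds of 2,000 with beta
#'   0.5, 1, 1.5, 2; see [budget_preset()] for scaled-down versions.
#' @param seed integer seed; drives sampling and all growth seeds.
#' @param n_realizations networks grown per evaluated point (scores
#'   averaged); default 1.
#' @param n_final networks regrown at the best parameters after the search.
#' @return Object of class `gnm_fit`: `best_params`, `best_score`,
#'   `best_network`, `evaluations` (data.frame with parameter columns,
#'   `round`, `score`, `seed`, and per-component KS of the first target),
#'   `final_networks`.
#' @export
optimize_gnm <- function(spec, targets, embedding, space = NULL,
                         m_target = NULL,
                         budget = budget_preset("paper"), seed = 1,
                         n_realizations = 1, n_final = 0) {
  if (inherits(targets, "binary_network")) targets <- list(targets)
  if (!length(targets)) stop_input("targets must be nonempty")
  space <- space %||% default_search_space(spec)
  m_target <- m_target %||% targets[[1]]$m
  stopifnot(budget$init > 0, budget$rounds >= 0,
            length(budget$beta) >= budget$rounds)
  tvs <- lapply(targets, topology_vectors, embedding = embedding)
  fast <- spec$feature_source != "matching"

  n_total <- budget$init + budget$rounds * budget$per_round
  seeds <- derive_seeds(seed, 1 + budget$rounds + n_total + max(n_final, 1))
  sample_seeds <- seeds[seq_len(1 + budget$rounds)]
  eval_seeds <- seeds[1 + budget$rounds + seq_len(n_total)]
  final_seed <- seeds[length(seeds)]

  best <- list(score = Inf, network = NULL, params = NULL)
  evaluate <- function(theta, ev_seed) {
    sp <- spec_with_params(spec, theta)
    rseeds <- if (n_realizations == 1) ev_seed else derive_seeds(ev_seed, n_realizations)
    scores <- numeric(n_realizations)
    first_ks <- NULL
    for (r in seq_len(n_realizations)) {
      gr <- grow_network(embedding, sp, m_target, seed = rseeds[r],
                         method = if (fast) "successive" else "sequential")
      tvm <- topology_vectors(gr$network, embedding)
      per_target <- vapply(tvs, function(tv) {
        max_ks(NULL, NULL, embedding, tvA = tvm, tvB = tv)$maxKS
      }, numeric(1))
      scores[r] <- mean(per_target)
      if (r == 1) {
        first_ks <- max_ks(NULL, NULL, embedding, tvA = tvm, tvB = tvs[[1]])
        first_net <- gr$network
      }
    }
    sc <- mean(scores)
    if (sc < best$score) {
      best <<- list(score = sc, network = first_net,
                    params = sp$params)
    }
    c(score = sc, KS_k = first_ks$KS_k, KS_c = first_ks$KS_c,
      KS_b = first_ks$KS_b, KS_e = first_ks$KS_e)
  }

  act <- active_params(space)
  all_pts <- initial_sample(space, budget$init, seed = sample_seeds[1])
  rounds <- rep(0L, budget$init)
  res <- matrix(NA_real_, n_total, 5,
                dimnames = list(NULL, c("score", "KS_k", "KS_c", "KS_b", "KS_e")))
  for (i in seq_len(budget$init)) {
    res[i, ] <- evaluate(all_pts[i, ], eval_seeds[i])
  }
  done <- budget$init
  for (r in seq_len(budget$rounds)) {
    new_pts <- voronoi_resample(all_pts, res[seq_len(done), "score"], space,
                                n_new = budget$per_round,
                                beta = budget$beta[r],
                                seed = sample_seeds[1 + r])
    for (i in seq_len(nrow(new_pts))) {
      res[done + i, ] <- evaluate(new_pts[i, ], eval_seeds[done + i])
    }
    all_pts <- rbind(all_pts, new_pts)
    rounds <- c(rounds, rep(r, budget$per_round))
    done <- done + budget$per_round
  }

  evaluations <- data.frame(all_pts, round = rounds,
                            score = res[, "score"],
                            seed = eval_seeds,
                            res[, c("KS_k", "KS_c", "KS_b", "KS_e")])
  final_networks <- if (n_final > 0) {
    fseeds <- derive_seeds(final_seed, n_final)
    sp <- model_spec(best$params, feature = spec$feature, label = spec$label)
    lapply(fseeds, function(s) {
      grow_network(embedding, sp, m_target, seed = s,
                   method = if (fast) "successive" else "sequential")$network
    })
  } else {
    list()
  }
  structure(list(best_params = best$params, best_score = best$score,
                 best_network = best$network, evaluations = evaluations,
                 final_networks = final_networks, space = space,
                 budget = budget, seed = seed),
            class = "gnm_fit")
}

#' Optimization budget presets
#'
#' @param name `"paper"` (2,000 + 4 x 2,000, beta 0.5-2), `"small"`
#'   (500 + 4 x 250, same schedule), or `"tiny"` (60 + 2 x 30, beta 1, 2).
#' @return Budget list for [optimize_gnm()].
#' @export
budget_preset <- function(name = c("paper", "small", "tiny")) {
  name <- match.arg(name)
  switch(name,
    paper = list(init = 2000, rounds = 4, per_round = 2000,
                 beta = c(0.5, 1, 1.5, 2)),
    small = list(init = 500, rounds = 4, per_round = 250,
                 beta = c(0.5, 1, 1.5, 2)),
    tiny = list(init = 60, rounds = 2, per_round = 30, beta = c(1, 2))
  )
}

#' @export
print.gnm_fit <- function(x, ...) {
  p <- x$best_params
  cat(sprintf("<gnm_fit> best maxKS = %.4f at eta = %.3f, gamma = %.3f, alpha = %.3f (%d evaluations)\n",
              x$best_score, p$eta, p$gamma, p$alpha, nrow(x$evaluations)))
  invisible(x)
}
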