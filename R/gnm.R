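#' Generative-model parameters
#'
#' Parameters of the cost-versus-feature wiring rule. A candidate edge
#' (i, j) receives weight
#' \deqn{w_{ij} = \frac{e^{-\eta D_{ij}}}{\max e^{-\eta D}} +
#'   \alpha \frac{F_{ij}^{\gamma}}{\max F^{\gamma}}}
#' in the additive form, or the product of the two normalized terms (without
#' `alpha`) in the multiplicative form; each maximum is taken over pairs not
#' yet connected. A power-law decay replaces `exp(-eta * D)` with `D^-eta`.
#'
#' @param eta distance-penalty strength (>= 0). With exponential decay the
#'   default optimizer box is `[0, 2]`; with power-law, `[0, 10]`.
#' @param gamma feature exponent (any real).
#' @param alpha feature-term weight (>= 0, additive form only). The
#'   multiplicative form has no `alpha`; passing a nonzero value there is an
#'   error rather than silently ignored.
#' @param form `"additive"` or `"multiplicative"`.
#' @param decay `"exponential"` or `"powerlaw"`.
#' @return Object of class `gnm_params`.
#' @export
gnm_params <- function(eta, gamma = 0, alpha = 0,
                       form = c("additive", "multiplicative"),
                       decay = c("exponential", "powerlaw")) {
  form <- match.arg(form)
  decay <- match.arg(decay)
  if (eta < 0) stop_input("eta must be >= 0")
  if (alpha < 0) stop_input("alpha must be >= 0")
  if (form == "multiplicative" && alpha != 0) {
    stop_input("the multiplicative form has no alpha parameter; got alpha = ",
               alpha)
  }
  structure(list(eta = eta, gamma = gamma, alpha = alpha,
                 form = form, decay = decay),
            class = "gnm_params")
}

#' Model specification
#'
#' Bundles wiring-rule parameters with a feature source:
#' * `feature = NULL` — pure spatial model (feature term absent: dropped in
#'   the additive form, factor 1 in the multiplicative form);
#' * a [similarity_matrix()] — static interregional similarity model;
#' * `"matching"` — dynamic topological homophily: the matching index of the
#'   growing network, recomputed after every added edge.
#'
#' @param params a [gnm_params()].
#' @param feature `NULL`, a [similarity_matrix()], or `"matching"`.
#' @param label display label.
#' @return Object of class `model_spec` with `feature_source` one of
#'   `"spatial"`, `"static"`, `"matching"`.
#' @export
model_spec <- function(params, feature = NULL, label = NULL) {
  stopifnot(inherits(params, "gnm_params"))
  source <- if (is.null(feature)) {
    "spatial"
  } else if (inherits(feature, "similarity_matrix")) {
    "static"
  } else if (identical(feature, "matching")) {
    "matching"
  } else {
    stop_input("feature must be NULL, a similarity_matrix, or \"matching\"")
  }
  label <- label %||% switch(source, spatial = "spatial",
                             static = "static-similarity", matching = "matching")
  structure(list(params = params, feature_source = source,
                 feature = feature, label = label),
            class = "model_spec")
}

# floor applied to feature values before powering, so F = 0 stays defined
# for any gamma (including the all-zero matching matrix on an empty network)
F_CLAMP <- 1e-6

#' Wiring-rule weights over absent pairs
#'
#' Evaluates the wiring rule for every node pair not currently connected.
#' Each term is normalized by its extremum over absent pairs, computed in
#' log space so that extreme exponents (`gamma` up to 200) cannot underflow:
#' the normalized feature term is `exp(gamma * (log F - log F_ref))` with
#' `F_ref` the max (for `gamma > 0`) or min (for `gamma < 0`) of the clamped
#' feature over absent pairs, which equals `F^gamma / max(F^gamma)` exactly.
#'
#' @param D pairwise distance matrix (mm).
#' @param F `NULL` (spatial) or a node x node feature matrix in `[0, 1]`
#'   (either a [similarity_matrix()] or a plain matrix such as a matching
#'   index). Values are clamped below at `1e-6` before powering.
#' @param A current adjacency matrix (0/1, symmetric, hollow).
#' @param params a [gnm_params()].
#' @return List with `pair_ids` (upper-triangle pair ids of absent pairs)
#'   and `w` (their weights, same order).
#' @export
wiring_weights <- function(D, F = NULL, A, params) {
  n <- nrow(D)
  lin <- pair_linear_index(n)
  absent <- which(A[lin] == 0)
  if (!length(absent)) stop_input("no absent pairs left")
  d <- D[lin][absent]
  if (params$decay == "powerlaw" && any(d <= 0)) {
    stop_input("power-law decay requires strictly positive distances")
  }
  dist_term <- if (params$decay == "exponential") {
    exp(-params$eta * (d - min(d)))
  } else {
    exp(-params$eta * (log(d) - log(min(d))))
  }
  if (is.null(F)) {
    return(list(pair_ids = absent, w = dist_term))
  }
  Fm <- if (inherits(F, "similarity_matrix")) F$F else F
  f <- pmax(Fm[lin][absent], F_CLAMP)
  feat_term <- if (params$gamma == 0) {
    rep(1, length(f))
  } else {
    f_ref <- if (params$gamma > 0) max(f) else min(f)
    exp(params$gamma * (log(f) - log(f_ref)))
  }
  w <- if (params$form == "additive") {
    dist_term + params$alpha * feat_term
  } else {
    dist_term * feat_term
  }
  list(pair_ids = absent, w = w)
}

#' Convert wiring weights to connection probabilities
#'
#' Each absent pair's probability is its weight divided by the sum of all
#' absent-pair weights; present pairs have probability zero by construction.
#'
#' @param weights result of [wiring_weights()] (or any list with `pair_ids`
#'   and `w`).
#' @return List with `pair_ids` and `p` (probabilities summing to 1).
#' @export
connection_probabilities <- function(weights) {
  w <- weights$w
  if (!length(w)) stop_input("no absent pairs")
  if (any(!is.finite(w)) || any(w < 0)) stop_input("weights must be finite and >= 0")
  s <- sum(w)
  if (s == 0) stop_input("all wiring weights are zero; no probability defined")
  list(pair_ids = weights$pair_ids, p = w / s)
}

#' Matching index of a binary network
#'
#' Topological homophily: for nodes i and j, the number of shared
#' neighbours divided by the size of the union of their neighbourhoods,
#' with the nodes themselves excluded from both sets; 0 when the union is
#' empty. Diagonal set to 0.
#'
#' @param A adjacency matrix of a [binary_network()], or the network itself.
#' @return Symmetric node x node matrix with entries in `[0, 1]`.
#' @examples
#' tri <- matrix(1, 3, 3); diag(tri) <- 0
#' matching_index(tri)   # every pair shares exactly the third node: all 1
#' @export
matching_index <- function(A) {
  if (inherits(A, "binary_network")) A <- A$A
  deg <- colSums(A)
  common <- A %*% A
  # union excluding i and j: deg_i + deg_j - |common| minus i,j themselves
  # which appear in the union iff the edge (i,j) exists
  denom <- outer(deg, deg, "+") - common - 2 * A
  M <- matrix(0, nrow(A), ncol(A))
  pos <- denom > 0
  M[pos] <- common[pos] / denom[pos]
  diag(M) <- 0
  M
}

# O(n) update of common-neighbour counts after adding edge (u, v) to A_old
update_common <- function(common, A_old, u, v) {
  common[, v] <- common[, v] + A_old[, u]
  common[, u] <- common[, u] + A_old[, v]
  common[v, ] <- common[v, ] + A_old[u, ]
  common[u, ] <- common[u, ] + A_old[v, ]
  common[u, u] <- common[u, u] + 1
  common[v, v] <- common[v, v] + 1
  common
}

#' Grow a network under a generative wiring rule
#'
#' Starting from an empty adjacency matrix, repeats `m_target` times:
#' evaluate the wiring rule over absent pairs, convert to probabilities,
#' sample exactly one pair, and add it. For the matching model the feature
#' matrix is recomputed after every addition (via an O(n) incremental
#' update of shared-neighbour counts, exactly equal to recomputation from
#' scratch). The growth trace accumulates, for every pair, the running mean
#' of its connection probability over the steps at which it was still
#' absent at the step start (so a pair added at step t averages steps
#' 1..t, and a never-added pair averages all `m_target` steps).
#'
#' For spatial and static-feature models the per-step weights differ only
#' by the normalizing constant, which cancels in the probabilities; when no
#' trace is requested (`method = "successive"`), the whole edge sequence is
#' then drawn as one weighted sample without replacement — the same
#' successive-sampling process, drawn in one call.
#'
#' @param embedding a [spatial_embedding()].
#' @param spec a [model_spec()].
#' @param m_target number of edges to grow (`<= n(n-1)/2`).
#' @param seed integer seed.
#' @param method `"sequential"` (default; full per-step trace) or
#'   `"successive"` (fast path; static models only, no trace).
#' @param debug if `TRUE`, assert at every step that the probabilities over
#'   absent pairs sum to 1 within `1e-12`, and (matching model) that the
#'   incrementally maintained matching matrix equals a from-scratch
#'   recomputation exactly.
#' @param keep_log if `TRUE`, retain the full per-step probability matrix
#'   (pairs x steps) in the trace; intended for small runs.
#' @return List with `network` ([binary_network()]) and `trace` (class
#'   `growth_trace`, or `NULL` under `method = "successive"`). The trace has
#'   `edge_order` (two-column matrix, addition order), `mean_P`,
#'   `step_count_P` (node x node matrices), and optionally `P_log`.
#' @export
grow_network <- function(embedding, spec, m_target, seed = 1,
                         method = c("sequential", "successive"),
                         debug = FALSE, keep_log = FALSE) {
  method <- match.arg(method)
  n <- embedding$n
  n_pairs <- n * (n - 1) / 2
  if (m_target > n_pairs) stop_input("m_target exceeds the number of node pairs")
  D <- embedding$D
  params <- spec$params

  if (method == "successive") {
    if (spec$feature_source == "matching") {
      stop_input("successive sampling requires a static wiring rule")
    }
    A0 <- matrix(0, n, n)
    F0 <- if (spec$feature_source == "static") spec$feature else NULL
    w <- wiring_weights(D, F0, A0, params)$w
    # exponential-race (Efraimidis-Spirakis) draw: the m pairs with the
    # smallest Exp(1)/w keys are distributed exactly as successive weighted
    # sampling without replacement, and the race stays numerically exact
    # when weights span hundreds of orders of magnitude
    ids <- withr::with_seed(as.integer(seed), {
      keys <- -log(runif(n_pairs)) / w
      order(keys, runif(n_pairs))[seq_len(m_target)]
    })
    pt <- pair_table(n)
    net <- network_from_edges(pt[ids, , drop = FALSE], n)
    return(list(network = net, trace = NULL))
  }

  pt <- pair_table(n)
  lin <- pair_linear_index(n)
  A <- matrix(0, n, n)
  Fm <- switch(spec$feature_source,
               spatial = NULL,
               static = spec$feature$F,
               matching = matrix(0, n, n))
  common <- if (spec$feature_source == "matching") matrix(0, n, n) else NULL
  sum_p <- numeric(n_pairs)
  cnt_p <- integer(n_pairs)
  edge_order <- matrix(0L, m_target, 2)
  P_log <- if (keep_log) matrix(0, n_pairs, m_target) else NULL

  withr::with_seed(as.integer(seed), {
    for (step in seq_len(m_target)) {
      wt <- wiring_weights(D, Fm, A, params)
      pr <- connection_probabilities(wt)
      if (debug) {
        stopifnot(abs(sum(pr$p) - 1) < 1e-12)
      }
      sum_p[pr$pair_ids] <- sum_p[pr$pair_ids] + pr$p
      cnt_p[pr$pair_ids] <- cnt_p[pr$pair_ids] + 1L
      if (keep_log) P_log[pr$pair_ids, step] <- pr$p
      pick <- pr$pair_ids[sample.int(length(pr$pair_ids), 1, prob = pr$p)]
      u <- pt[pick, 1]; v <- pt[pick, 2]
      edge_order[step, ] <- c(u, v)
      if (spec$feature_source == "matching") {
        common <- update_common(common, A, u, v)
      }
      A[u, v] <- A[v, u] <- 1
      if (spec$feature_source == "matching") {
        deg <- colSums(A)
        denom <- outer(deg, deg, "+") - common - 2 * A
        Fm <- matrix(0, n, n)
        pos <- denom > 0
        Fm[pos] <- common[pos] / denom[pos]
        diag(Fm) <- 0
        if (debug) {
          # incremental bookkeeping must equal from-scratch recomputation
          stopifnot(identical(Fm, matching_index(A)))
        }
      }
    }
  })

  mean_mat <- matrix(0, n, n)
  cnt_mat <- matrix(0L, n, n)
  if (m_target > 0) {
    mp <- sum_p / pmax(cnt_p, 1L)
    mean_mat[lin] <- mp
    mean_mat <- mean_mat + t(mean_mat)
    cnt_mat[lin] <- cnt_p
    cnt_mat <- cnt_mat + t(cnt_mat)
  }
  trace <- structure(
    list(edge_order = edge_order, mean_P = mean_mat, step_count_P = cnt_mat,
         P_log = P_log, n = n, m = m_target, complete = TRUE),
    class = "growth_trace"
  )
  list(network = binary_network(A), trace = trace)
}

#' Mean connection probability of a completed run
#'
#' The per-pair mean of the step-wise connection probabilities, averaged
#' only over steps at which the pair had not yet been added.
#'
#' @param trace a `growth_trace` from [grow_network()].
#' @return Symmetric node x node matrix; the step counts underlying each
#'   mean are exposed as attribute `"step_count"`.
#' @export
mean_connection_probability <- function(trace) {
  if (!inherits(trace, "growth_trace") || !isTRUE(trace$complete)) {
    stop_input("trace is missing or incomplete")
  }
  structure(trace$mean_P, step_count = trace$step_count_P)
}
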