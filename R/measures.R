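#' Nodal and edge topology vectors
#'
#' The four distributions entering the max(KS) fit statistic, plus the
#' per-node mean incident-edge length used by the matched-vector measures:
#' degree, binary local clustering, Brandes betweenness (raw dependency
#' counts, with unreachable pairs contributing 0), per-edge Euclidean
#' length, and per-node mean length of incident edges (0 for isolated
#' nodes, flagged).
#'
#' @param net a [binary_network()].
#' @param embedding the matching [spatial_embedding()].
#' @return Object of class `topology_vectors`: `degree`, `clustering`,
#'   `betweenness`, `edge_lengths`, `node_mean_length`,
#'   `isolated` (logical flag vector).
#' @export
topology_vectors <- function(net, embedding) {
  if (net$n != embedding$n) stop_input("network and embedding node counts differ")
  g <- as_igraph(net)
  deg <- colSums(net$A)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[deg < 2] <- 0
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  lens <- embedding$D[net$A == 1 & upper.tri(net$A)]
  nml <- ifelse(deg > 0, rowSums(net$A * embedding$D) / pmax(deg, 1), 0)
  structure(
    list(degree = as.numeric(deg), clustering = as.numeric(cl),
         betweenness = as.numeric(btw), edge_lengths = as.numeric(lens),
         node_mean_length = as.numeric(nml), isolated = deg == 0),
    class = "topology_vectors"
  )
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum of the absolute difference between the two empirical CDFs
#' (right-continuous step functions), evaluated at all pooled sample
#' points. Ties are handled exactly.
#'
#' @param x,y nonempty numeric samples.
#' @return A number in `[0, 1]`.
#' @examples
#' ks_stat(c(1, 2, 3), c(2, 3, 4))   # 1/3
#' @export
ks_stat <- function(x, y) {
  if (!length(x) || !length(y)) stop_input("both samples must be nonempty")
  xs <- sort(x); ys <- sort(y)
  z <- sort(unique(c(xs, ys)))
  Fx <- findInterval(z, xs) / length(xs)
  Fy <- findInterval(z, ys) / length(ys)
  max(abs(Fx - Fy))
}

#' Component and maximum KS statistics between two networks
#'
#' KS distances between the degree, clustering, betweenness, and
#' edge-length distributions of two networks on the same embedding, and
#' their maximum — the model-fit objective.
#'
#' @param netA,netB [binary_network()] objects on the same node set.
#' @param embedding the shared [spatial_embedding()].
#' @param tvA,tvB optional precomputed [topology_vectors()] (saves
#'   recomputation in optimization loops).
#' @return Named list `KS_k`, `KS_c`, `KS_b`, `KS_e`, `maxKS`.
#' @export
max_ks <- function(netA, netB, embedding, tvA = NULL, tvB = NULL) {
  tvA <- tvA %||% topology_vectors(netA, embedding)
  tvB <- tvB %||% topology_vectors(netB, embedding)
  out <- list(
    KS_k = ks_stat(tvA$degree, tvB$degree),
    KS_c = ks_stat(tvA$clustering, tvB$clustering),
    KS_b = ks_stat(tvA$betweenness, tvB$betweenness),
    KS_e = ks_stat(tvA$edge_lengths, tvB$edge_lengths)
  )
  out$maxKS <- max(out$KS_k, out$KS_c, out$KS_b, out$KS_e)
  out
}

#' Connection recovery, overlap, and false discovery
#'
#' Edge-set agreement between a model network and a target:
#' `R` = fraction of target edges present in the model; `jaccard` =
#' intersection over union; `fdr` = fraction of model edges absent from
#' the target.
#'
#' @param model_net,target_net [binary_network()] objects on the same node
#'   set. A warning is issued when their edge counts differ (the growth and
#'   rewiring procedures are density-matched by design).
#' @return List `R`, `jaccard`, `fdr`, `n_common`.
#' @export
recovery_overlap <- function(model_net, target_net) {
  if (target_net$m == 0) stop_input("target network has no edges")
  if (model_net$m != target_net$m) {
    warning("model and target edge counts differ (", model_net$m, " vs ",
            target_net$m, ")")
  }
  em <- edge_pair_ids(model_net)
  et <- edge_pair_ids(target_net)
  common <- length(intersect(em, et))
  list(R = common / length(et),
       jaccard = common / length(union(em, et)),
       fdr = 1 - common / length(em),
       n_common = common)
}

#' Degree-sequence correlation between two networks
#'
#' @param netA,netB [binary_network()] objects with the same node order.
#' @param method `"spearman"` (rank correlation with average-rank ties) or
#'   `"pearson"`.
#' @return Correlation coefficient; `NA` with attribute
#'   `undefined = TRUE` and a warning when either degree vector has zero
#'   variance.
#' @export
degree_correlation <- function(netA, netB, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  kA <- colSums(netA$A); kB <- colSums(netB$A)
  if (sd(kA) == 0 || sd(kB) == 0) {
    warning("degree correlation undefined: zero-variance degree vector")
    return(structure(NA_real_, undefined = TRUE))
  }
  cor(kA, kB, method = method)
}

# global topology summaries used by the TND measure; extensible registry
global_measure_registry <- function() {
  list(
    global_clustering = function(net, g) igraph::transitivity(g, type = "global"),
    global_efficiency = function(net, g) {
      d <- igraph::distances(g)
      inv <- 1 / d
      inv[!is.finite(inv)] <- 0
      diag(inv) <- 0
      sum(inv) / (net$n * (net$n - 1))
    },
    modularity_q = function(net, g) {
      if (net$m == 0) return(NA_real_)
      withr::with_seed(42L, igraph::modularity(igraph::cluster_louvain(g)))
    },
    assortativity = function(net, g) {
      suppressWarnings(igraph::assortativity_degree(g))
    }
  )
}

harmonic_closeness <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (net$n - 1)
}

#' Alternative network-similarity measures
#'
#' Four measures complementary to max(KS):
#' * `TND` — Euclidean distance between z-scored vectors of global topology
#'   summaries (global clustering, global efficiency, Louvain modularity Q,
#'   degree assortativity); z-scoring is relative to a catalog of networks
#'   (by default the compared pair itself; supply more via `catalog` to
#'   anchor the scale).
#' * `TF_diff` — Frobenius norm of the difference between the two 4x4
#'   cross-correlation matrices of nodal features (degree, clustering,
#'   betweenness, mean incident length).
#' * `max_rd` — maximum, over the four matched nodal/edge vectors, of one
#'   minus the Pearson correlation between the networks' vectors.
#' * `max_RMSE` — maximum root-mean-square difference over matched nodal
#'   vectors (degree, clustering, harmonic closeness, mean incident
#'   length), each min-max rescaled jointly across both networks.
#'
#' Components whose correlations are undefined (zero variance, or a global
#' summary undefined for either network) are dropped and listed in the
#' `flags` element rather than silently zeroed.
#'
#' @param netA,netB [binary_network()] objects on the same node set.
#' @param embedding the shared [spatial_embedding()].
#' @param catalog optional list of further [binary_network()] objects whose
#'   global summaries widen the z-scoring catalog for `TND`.
#' @return List `TND`, `TF_diff`, `max_rd`, `max_RMSE`, `flags`.
#' @export
alt_measures <- function(netA, netB, embedding, catalog = NULL) {
  flags <- character(0)
  tvA <- topology_vectors(netA, embedding)
  tvB <- topology_vectors(netB, embedding)

  reg <- global_measure_registry()
  nets <- c(list(netA, netB), catalog)
  gs <- vapply(nets, function(nt) {
    g <- as_igraph(nt)
    vapply(reg, function(f) as.numeric(f(nt, g)), numeric(1))
  }, numeric(length(reg)))
  mu <- rowMeans(gs)
  sg <- apply(gs, 1, sd)
  zA <- (gs[, 1] - mu) / sg
  zB <- (gs[, 2] - mu) / sg
  diffz <- zA - zB
  diffz[which(gs[, 1] == gs[, 2])] <- 0   # identical values: no contribution
  bad <- !is.finite(diffz)
  if (any(bad)) flags <- c(flags, paste0("TND:", names(reg)[bad]))
  TND <- sqrt(sum(diffz[!bad]^2))

  featA <- cbind(k = tvA$degree, c = tvA$clustering, b = tvA$betweenness,
                 e = tvA$node_mean_length)
  featB <- cbind(k = tvB$degree, c = tvB$clustering, b = tvB$betweenness,
                 e = tvB$node_mean_length)
  CA <- suppressWarnings(cor(featA))
  CB <- suppressWarnings(cor(featB))
  dC <- CA - CB
  naC <- !is.finite(dC)
  if (any(naC)) {
    flags <- c(flags, "TF_diff:undefined-entries")
    dC[naC] <- 0
  }
  TF_diff <- sqrt(sum(dC^2))

  matched <- list(degree = c("degree", "degree"),
                  clustering = c("clustering", "clustering"),
                  betweenness = c("betweenness", "betweenness"),
                  length = c("node_mean_length", "node_mean_length"))
  rds <- vapply(names(matched), function(nm) {
    a <- tvA[[matched[[nm]][1]]]; b <- tvB[[matched[[nm]][2]]]
    if (sd(a) == 0 || sd(b) == 0) {
      if (!isTRUE(all.equal(a, b))) return(NA_real_)
      return(0)
    }
    1 - cor(a, b)
  }, numeric(1))
  if (any(is.na(rds))) flags <- c(flags, paste0("max_rd:", names(rds)[is.na(rds)]))
  max_rd <- if (all(is.na(rds))) NA_real_ else max(rds, na.rm = TRUE)

  closA <- harmonic_closeness(netA)
  closB <- harmonic_closeness(netB)
  rmse_vecs <- list(degree = list(tvA$degree, tvB$degree),
                    clustering = list(tvA$clustering, tvB$clustering),
                    closeness = list(closA, closB),
                    length = list(tvA$node_mean_length, tvB$node_mean_length))
  rmses <- vapply(rmse_vecs, function(v) {
    rng <- range(c(v[[1]], v[[2]]))
    if (diff(rng) == 0) return(0)
    a <- (v[[1]] - rng[1]) / diff(rng)
    b <- (v[[2]] - rng[1]) / diff(rng)
    sqrt(mean((a - b)^2))
  }, numeric(1))
  list(TND = TND, TF_diff = TF_diff, max_rd = max_rd,
       max_RMSE = max(rmses), flags = flags)
}

#' Distance-binned connection recovery
#'
#' Connection recovery restricted to target edges whose length falls in
#' half-open distance bins `[lo, hi)` — by default short (< 30 mm), mid
#' (30-90 mm), and long (>= 90 mm) range.
#'
#' @param model_net,target_net [binary_network()] objects.
#' @param embedding the shared [spatial_embedding()].
#' @param bin_edges ascending bin boundaries in mm; must cover all target
#'   edge lengths.
#' @return data.frame with one row per bin: `lo`, `hi`, `n_target`,
#'   `n_recovered`, `recovery`, `applicable` (`FALSE`, with `recovery` NA,
#'   for bins containing no target edges).
#' @export
distance_binned_recovery <- function(model_net, target_net, embedding,
                                     bin_edges = c(0, 30, 90, Inf)) {
  et <- edge_pair_ids(target_net)
  if (!length(et)) stop_input("target network has no edges")
  em <- edge_pair_ids(model_net)
  dvec <- embedding$D[pair_linear_index(embedding$n)]
  lens <- dvec[et]
  if (any(lens < bin_edges[1]) || any(lens >= bin_edges[length(bin_edges)])) {
    stop_input("bin_edges do not cover all target edge lengths")
  }
  k <- length(bin_edges) - 1
  out <- data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
                    n_target = 0L, n_recovered = 0L,
                    recovery = NA_real_, applicable = FALSE)
  bin <- findInterval(lens, bin_edges)
  for (b in seq_len(k)) {
    in_bin <- et[bin == b]
    out$n_target[b] <- length(in_bin)
    if (length(in_bin)) {
      out$n_recovered[b] <- length(intersect(in_bin, em))
      out$recovery[b] <- out$n_recovered[b] / length(in_bin)
      out$applicable[b] <- TRUE
    }
  }
  out
}

#' Full fit result for a network pair
#'
#' One row combining the KS components, recovery/overlap, degree
#' correlation, and (optionally) the alternative similarity measures.
#'
#' @param model_net,target_net [binary_network()] objects.
#' @param embedding the shared [spatial_embedding()].
#' @param include_alt include the [alt_measures()] columns (slower).
#' @param tv_target optional precomputed target [topology_vectors()].
#' @return One-row data.frame with stable column names `KS_k`, `KS_c`,
#'   `KS_b`, `KS_e`, `maxKS`, `R`, `jaccard`, `fdr`, `rho_degree`, and when
#'   requested `TND`, `TF_diff`, `max_rd`, `max_RMSE`.
#' @export
fit_result <- function(model_net, target_net, embedding, include_alt = FALSE,
                       tv_target = NULL) {
  ks <- max_ks(model_net, target_net, embedding, tvB = tv_target)
  ov <- recovery_overlap(model_net, target_net)
  rho <- suppressWarnings(degree_correlation(model_net, target_net))
  row <- data.frame(KS_k = ks$KS_k, KS_c = ks$KS_c, KS_b = ks$KS_b,
                    KS_e = ks$KS_e, maxKS = ks$maxKS,
                    R = ov$R, jaccard = ov$jaccard, fdr = ov$fdr,
                    rho_degree = as.numeric(rho))
  if (include_alt) {
    am <- alt_measures(model_net, target_net, embedding)
    row$TND <- am$TND
    row$TF_diff <- am$TF_diff
    row$max_rd <- am$max_rd
    row$max_RMSE <- am$max_RMSE
  }
  row
}
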