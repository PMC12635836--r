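test_that("topology vectors are exact on canonical small graphs", {
  emb <- toy_embedding(3, seed = 1)
  K3 <- network_from_edges(rbind(c(1, 2), c(1, 3), c(2, 3)), 3)
  tv <- topology_vectors(K3, emb)
  expect_equal(tv$degree, c(2, 2, 2))
  expect_equal(tv$clustering, c(1, 1, 1))
  expect_equal(tv$betweenness, c(0, 0, 0))
  expect_equal(sort(tv$edge_lengths),
               sort(emb$D[upper.tri(emb$D)]))

  path <- network_from_edges(rbind(c(1, 2), c(2, 3)), 3)
  tv <- topology_vectors(path, emb)
  expect_equal(tv$betweenness, c(0, 1, 0))
  expect_equal(tv$clustering, c(0, 0, 0))
})

test_that("degree sums to twice the edge count on random graphs", {
  emb <- toy_embedding(12, seed = 2)
  for (s in 1:10) {
    set.seed(s)
    net <- binary_network(random_graph(12))
    tv <- topology_vectors(net, emb)
    expect_equal(sum(tv$degree), 2 * net$m)
    expect_identical(length(tv$edge_lengths), as.integer(net$m))
  }
})

test_that("two-sample KS statistic matches hand values and two oracles", {
  expect_equal(ks_stat(c(5, 1, 3), c(3, 5, 1)), 0)
  expect_equal(ks_stat(c(1, 2), c(10, 11, 12)), 1)
  expect_equal(ks_stat(c(1, 2, 3), c(2, 3, 4)), 1 / 3)

  set.seed(3)
  for (case in 1:1000) {
    nx <- sample(3:200, 1)
    ny <- sample(3:200, 1)
    # heavy ties half the time, mimicking degree-like integer samples
    if (case %% 2) {
      x <- sample(0:10, nx, replace = TRUE)
      y <- sample(0:10, ny, replace = TRUE)
    } else {
      x <- rnorm(nx)
      y <- rnorm(ny, 0.3)
    }
    expect_equal(ks_stat(x, y), ks_oracle(x, y), tolerance = 1e-12)
  }
  # classical implementation agrees on tie-free samples
  set.seed(4)
  x <- rnorm(57); y <- runif(43)
  expect_equal(ks_stat(x, y),
               unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
               tolerance = 1e-12)
})

test_that("max KS is symmetric, bounds its components, and zero on identity", {
  emb <- toy_embedding(8, seed = 5)
  set.seed(6)
  a <- binary_network(random_graph(8))
  b <- binary_network(random_graph(8))
  ks_ab <- max_ks(a, b, emb)
  ks_ba <- max_ks(b, a, emb)
  for (comp in c("KS_k", "KS_c", "KS_b", "KS_e")) {
    expect_equal(ks_ab[[comp]], ks_ba[[comp]])
    expect_lte(ks_ab[[comp]], ks_ab$maxKS)
  }
  self <- max_ks(a, a, emb)
  expect_equal(unlist(self), c(KS_k = 0, KS_c = 0, KS_b = 0, KS_e = 0, maxKS = 0))
})

test_that("recovery, overlap, and FDR follow set arithmetic", {
  n <- 5
  tgt <- network_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4)), n)
  mod <- network_from_edges(rbind(c(1, 2), c(2, 3), c(3, 5)), n)
  ov <- recovery_overlap(mod, tgt)
  expect_equal(ov$R, 2 / 3)
  expect_equal(ov$jaccard, 2 / 4)
  expect_equal(ov$fdr, 1 / 3)

  same <- recovery_overlap(tgt, tgt)
  expect_equal(c(same$R, same$jaccard, same$fdr), c(1, 1, 0))

  disj <- network_from_edges(rbind(c(1, 5), c(2, 5), c(4, 5)), n)
  ov <- recovery_overlap(disj, tgt)
  expect_equal(c(ov$R, ov$jaccard, ov$fdr), c(0, 0, 1))

  # counting identities hold exactly on random pairs
  emb <- toy_embedding(10, seed = 7)
  for (s in 1:20) {
    set.seed(s)
    a <- binary_network(random_graph(10))
    b <- binary_network(random_graph(10))
    if (a$m == 0 || b$m == 0) next
    ov <- suppressWarnings(recovery_overlap(a, b))
    expect_equal(ov$R * b$m, ov$n_common)
    expect_equal((1 - ov$fdr) * a$m, ov$n_common)
  }
})

test_that("degree correlation handles reversals, ties, and degenerate input", {
  n <- 5
  a <- network_from_edges(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3)), n)
  expect_equal(degree_correlation(a, a), 1)

  # explicit average-rank oracle on tied degree vectors
  emb <- toy_embedding(9, seed = 8)
  set.seed(9)
  x <- binary_network(random_graph(9, 0.5))
  y <- binary_network(random_graph(9, 0.5))
  expect_equal(degree_correlation(x, y, "spearman"),
               spearman_oracle(colSums(x$A), colSums(y$A)),
               tolerance = 1e-12)
  expect_equal(degree_correlation(x, y, "pearson"),
               pearson_oracle(colSums(x$A), colSums(y$A)),
               tolerance = 1e-12)

  ring <- network_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1)), 3)
  expect_warning(r <- degree_correlation(ring, ring), "zero-variance")
  expect_true(is.na(r))
})

test_that("alternative measures vanish on identity and are symmetric", {
  emb <- toy_embedding(10, seed = 10)
  set.seed(11)
  a <- binary_network(random_graph(10, 0.4))
  b <- binary_network(random_graph(10, 0.4))
  self <- alt_measures(a, a, emb)
  expect_equal(self$TND, 0)
  expect_equal(self$TF_diff, 0)
  expect_equal(self$max_rd, 0)
  expect_equal(self$max_RMSE, 0)

  ab <- alt_measures(a, b, emb)
  ba <- alt_measures(b, a, emb)
  for (comp in c("TND", "TF_diff", "max_rd", "max_RMSE")) {
    expect_equal(ab[[comp]], ba[[comp]], tolerance = 1e-12)
  }
})

test_that("alternative measures match longhand recomputation on fixed toys", {
  emb <- toy_embedding(10, seed = 12)
  set.seed(13)
  a <- binary_network(random_graph(10, 0.45))
  b <- binary_network(random_graph(10, 0.45))
  got <- alt_measures(a, b, emb)

  tv <- function(net) topology_vectors(net, emb)
  ta <- tv(a); tb <- tv(b)

  # TF_diff: correlation matrices entry by entry from the textbook formula
  feats <- function(t) list(t$degree, t$clustering, t$betweenness, t$node_mean_length)
  cmat <- function(fl) {
    C <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) C[i, j] <- pearson_oracle(fl[[i]], fl[[j]])
    C
  }
  dC <- cmat(feats(ta)) - cmat(feats(tb))
  expect_equal(got$TF_diff, sqrt(sum(dC^2)), tolerance = 1e-12)

  # max_rd from first-principles correlations of matched vectors
  rd <- c(1 - pearson_oracle(ta$degree, tb$degree),
          1 - pearson_oracle(ta$clustering, tb$clustering),
          1 - pearson_oracle(ta$betweenness, tb$betweenness),
          1 - pearson_oracle(ta$node_mean_length, tb$node_mean_length))
  expect_equal(got$max_rd, max(rd), tolerance = 1e-12)

  # max_RMSE with longhand joint min-max rescaling
  clos <- function(net) {
    d <- igraph::distances(igraph::graph_from_adjacency_matrix(
      net$A, mode = "undirected"))
    vapply(1:10, function(i) {
      v <- 1 / d[i, -i]; v[!is.finite(v)] <- 0; mean(v)
    }, numeric(1))
  }
  rmse <- function(u, v) {
    lo <- min(c(u, v)); hi <- max(c(u, v))
    if (hi == lo) return(0)
    sqrt(mean(((u - lo) / (hi - lo) - (v - lo) / (hi - lo))^2))
  }
  rmses <- c(rmse(ta$degree, tb$degree),
             rmse(ta$clustering, tb$clustering),
             rmse(clos(a), clos(b)),
             rmse(ta$node_mean_length, tb$node_mean_length))
  expect_equal(got$max_RMSE, max(rmses), tolerance = 1e-12)

  # TND: z-scoring across the pair then Euclidean distance, longhand
  gl <- function(net) {
    g <- igraph::graph_from_adjacency_matrix(net$A, mode = "undirected")
    d <- igraph::distances(g); inv <- 1 / d; inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    c(igraph::transitivity(g, type = "global"),
      sum(inv) / (10 * 9),
      withr::with_seed(42L, igraph::modularity(igraph::cluster_louvain(g))),
      igraph::assortativity_degree(g))
  }
  ga <- gl(a); gb <- gl(b)
  z <- function(v, i) (v[i] - mean(c(ga[i], gb[i]))) / sd(c(ga[i], gb[i]))
  dz <- vapply(1:4, function(i) {
    if (ga[i] == gb[i]) return(0)
    z(ga, i) - z(gb, i)
  }, numeric(1))
  expect_equal(got$TND, sqrt(sum(dz^2)), tolerance = 1e-12)
})

test_that("min-max rescaling makes max_RMSE affine-invariant", {
  # rescaled RMSE of affinely transformed vectors is unchanged
  rmse_scaled <- function(u, v) {
    lo <- min(c(u, v)); hi <- max(c(u, v))
    sqrt(mean(((u - lo) / (hi - lo) - (v - lo) / (hi - lo))^2))
  }
  set.seed(14)
  u <- rnorm(20); v <- rnorm(20)
  expect_equal(rmse_scaled(u, v), rmse_scaled(3 * u + 7, 3 * v + 7),
               tolerance = 1e-12)
})

test_that("distance-binned recovery flags empty bins and bins by hand", {
  coords <- cbind(c(0, 1, 2, 100), c(0, 0, 0, 0), 0)
  emb <- spatial_embedding(coords, neighbor_graph = {
    G <- matrix(1, 4, 4) - diag(4); G
  })
  # two short edges (1mm each), one long edge (98mm)
  tgt <- network_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4)), 4)
  mod <- network_from_edges(rbind(c(1, 2), c(2, 3), c(1, 4)), 4)
  out <- distance_binned_recovery(mod, tgt, emb, c(0, 30, 90, Inf))
  expect_equal(out$recovery[1], 1)          # both short edges recovered
  expect_false(out$applicable[2])           # no mid-range target edges
  expect_equal(out$recovery[3], 0)          # the long edge was missed
  ident <- distance_binned_recovery(tgt, tgt, emb)
  expect_true(all(ident$recovery[ident$applicable] == 1))
})
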