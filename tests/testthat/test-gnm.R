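test_that("wiring weights reduce to closed forms in degenerate settings", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  A <- matrix(0, 3, 3)

  # eta = 0, alpha = 0, additive: every absent pair weighs exactly 1
  w0 <- wiring_weights(D, NULL, A, gnm_params(0))
  expect_identical(w0$w, rep(1, 3))

  # multiplicative, gamma = 0: feature term is identically 1
  Fhalf <- matrix(0.5, 3, 3); diag(Fhalf) <- 1
  Fm <- similarity_matrix(Fhalf)
  wm <- wiring_weights(D, Fm, A, gnm_params(1, gamma = 0, form = "multiplicative"))
  ws <- wiring_weights(D, NULL, A, gnm_params(1))
  expect_equal(wm$w, ws$w)

  # hand evaluation of the spatial rule on the 3-node toy
  w1 <- wiring_weights(D, NULL, A, gnm_params(1))
  expect_equal(w1$w, c(1, exp(-1), exp(-2)), tolerance = 1e-14)
})

test_that("log-space wiring-rule evaluation matches naive direct evaluation", {
  for (case in 1:40) {
    set.seed(case)
    n <- 8
    D <- as.matrix(dist(matrix(runif(n * 3, 0, 50), n, 3)))
    Fm <- matrix(runif(n * n), n, n)
    Fm <- (Fm + t(Fm)) / 2
    diag(Fm) <- 0
    A <- random_graph(n, 0.3)
    if (all(A[upper.tri(A)] == 1)) next
    eta <- runif(1, 0, 2)
    gamma <- runif(1, -30, 30)
    alpha <- runif(1, 0, 10)
    form <- if (case %% 2) "additive" else "multiplicative"
    p <- gnm_params(eta, gamma, if (form == "additive") alpha else 0, form = form)
    w <- wiring_weights(D, Fm, A, p)$w
    w_naive <- naive_wiring_oracle(D, Fm, A, eta, gamma,
                                   if (form == "additive") alpha else 0,
                                   form, "exponential")
    expect_equal(w, w_naive, tolerance = 1e-9)
  }
})

test_that("power-law decay rejects zero distances and matches direct form", {
  D <- matrix(c(0, 2, 4, 2, 0, 8, 4, 8, 0), 3, 3)
  A <- matrix(0, 3, 3)
  w <- wiring_weights(D, NULL, A, gnm_params(1.5, decay = "powerlaw"))
  expect_equal(w$w, (c(2, 4, 8) / 2)^(-1.5), tolerance = 1e-12)
  D0 <- D; D0[1, 2] <- D0[2, 1] <- 0
  expect_error(wiring_weights(D0, NULL, A, gnm_params(1, decay = "powerlaw")),
               "positive distances")
})

test_that("multiplicative form refuses a non-default alpha", {
  expect_error(gnm_params(1, 2, alpha = 3, form = "multiplicative"), "alpha")
})

test_that("probabilities normalize over absent pairs", {
  pr <- connection_probabilities(list(pair_ids = 1:3, w = c(2, 1, 1)))
  expect_equal(pr$p, c(0.5, 0.25, 0.25))
  pr <- connection_probabilities(list(pair_ids = 1:4, w = rep(7, 4)))
  expect_equal(pr$p, rep(0.25, 4))
  set.seed(1)
  w <- runif(50)
  expect_lt(abs(sum(connection_probabilities(list(pair_ids = 1:50, w = w))$p) - 1),
            1e-12)
  expect_error(connection_probabilities(list(pair_ids = 1:2, w = c(0, 0))),
               "zero")
})

test_that("matching index agrees with hand evaluations and brute force", {
  expect_identical(matching_index(matrix(0, 4, 4)), matrix(0, 4, 4))

  K3 <- matrix(1, 3, 3) - diag(3)
  M <- matching_index(K3)
  expect_equal(M[upper.tri(M)], rep(1, 3))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  M <- matching_index(star)
  expect_equal(M[2, 3], 1)  # leaves share exactly the hub
  expect_equal(M[1, 2], 0)  # leaf has no neighbour besides the hub itself

  for (case in 1:30) {
    set.seed(case)
    A <- random_graph(sample(3:8, 1))
    expect_equal(matching_index(A), matching_oracle(A), tolerance = 1e-14)
  }
})

test_that("growth produces the requested density, symmetric and hollow", {
  emb <- toy_embedding(25, seed = 2)
  res <- grow_network(emb, model_spec(gnm_params(0.5)), 60, seed = 3)
  A <- res$network$A
  expect_identical(res$network$m, 60L)
  expect_identical(A, t(A))
  expect_identical(diag(A), rep(0, 25))
  expect_identical(nrow(res$trace$edge_order), 60L)

  empty <- grow_network(emb, model_spec(gnm_params(1)), 0, seed = 1)
  expect_identical(empty$network$m, 0L)
  expect_identical(nrow(empty$trace$edge_order), 0L)

  expect_error(grow_network(emb, model_spec(gnm_params(1)), 1000, seed = 1),
               "exceeds")
})

test_that("growth is deterministic in the seed", {
  emb <- toy_embedding(20, seed = 4)
  spec <- model_spec(gnm_params(1, 3, form = "multiplicative"),
                     feature = "matching")
  a <- grow_network(emb, spec, 40, seed = 5)
  b <- grow_network(emb, spec, 40, seed = 5)
  expect_identical(a$trace$edge_order, b$trace$edge_order)
  c <- grow_network(emb, spec, 40, seed = 6)
  expect_false(identical(a$trace$edge_order, c$trace$edge_order))
})

test_that("matching model's first step equals the spatial model's first step", {
  emb <- toy_embedding(15, seed = 7)
  spec_m <- model_spec(gnm_params(1, gamma = 2, form = "multiplicative"),
                       feature = "matching")
  spec_s <- model_spec(gnm_params(1, form = "multiplicative"))
  pm <- grow_network(emb, spec_m, 1, seed = 8, keep_log = TRUE)$trace$P_log[, 1]
  ps <- grow_network(emb, spec_s, 1, seed = 8, keep_log = TRUE)$trace$P_log[, 1]
  expect_lt(max(abs(pm - ps)), 1e-6)
})

test_that("incremental matching bookkeeping equals from-scratch recomputation", {
  emb <- toy_embedding(15, seed = 9)
  spec <- model_spec(gnm_params(1, gamma = 1.5, alpha = 2), feature = "matching")
  # debug mode asserts equality (and probability conservation) at every step
  expect_no_error(grow_network(emb, spec, 40, seed = 10, debug = TRUE))
})

test_that("a stronger distance penalty shortens generated edges", {
  emb <- make_embedding(100, "shell", scale = 100, seed = 11)
  mean_len <- function(eta, seeds) {
    mean(vapply(seeds, function(s) {
      net <- grow_network(emb, model_spec(gnm_params(eta)), 200, seed = s,
                          method = "successive")$network
      mean(emb$D[network_edges(net)])
    }, numeric(1)))
  }
  expect_lt(mean_len(2, 1:20), mean_len(0, 21:40))
})

test_that("mean connection probabilities match an external per-step average", {
  emb <- toy_embedding(20, seed = 12)
  spec <- model_spec(gnm_params(1, gamma = 2, alpha = 1), feature = "matching")
  res <- grow_network(emb, spec, 30, seed = 13, keep_log = TRUE)
  P_log <- res$trace$P_log
  lin <- which(upper.tri(diag(20)))
  mp <- res$trace$mean_P[lin]
  cnt <- res$trace$step_count_P[lin]
  # external accumulation: average each pair over steps where it was absent
  # at the step start, i.e. the steps with a recorded (possibly zero-valued)
  # probability before its addition step
  eo <- res$trace$edge_order
  added_step <- rep(Inf, length(lin))
  pt <- which(upper.tri(diag(20)), arr.ind = TRUE)
  for (s in seq_len(nrow(eo))) {
    id <- which(pt[, 1] == min(eo[s, ]) & pt[, 2] == max(eo[s, ]))
    added_step[id] <- s
  }
  for (id in seq_along(lin)) {
    steps <- seq_len(min(added_step[id], 30))
    expect_equal(mp[id], mean(P_log[id, steps]), tolerance = 1e-12)
    expect_identical(cnt[id], length(steps))
  }
  expect_true(all(mp >= 0 & mp <= 1))
  # a pair added at step 1 contributes its step-1 probability exactly
  first <- which(added_step == 1)
  expect_equal(mp[first], P_log[first, 1])

  expect_error(mean_connection_probability(list(a = 1)), "incomplete")
})
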