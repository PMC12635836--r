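make_line_embedding <- function(xs) {
  spatial_embedding(cbind(xs, 0, 0),
                    neighbor_graph = matrix(1, length(xs), length(xs)) -
                      diag(length(xs)))
}

test_that("thresholded degree hits its boundary contracts", {
  emb <- make_line_embedding(c(0, 1, 2, 50))
  net <- network_from_edges(rbind(c(1, 2), c(2, 3), c(1, 4)), 4)
  lens <- emb$D[network_edges(net)]   # 1, 1 (short), 50 (long)

  prof <- distance_threshold_degree(net, emb, c(0.5, 10, 100), "below")
  expect_false(prof$valid[1])                 # below the shortest edge: all-zero
  expect_true(is.na(prof$r[1]))
  expect_equal(prof$r[3], 1)                  # above the longest edge: identity

  # hand computation between the short and long edges
  k_thr <- c(1, 2, 1, 0)                      # edges shorter than 10
  k_full <- c(2, 2, 1, 1)
  expect_equal(prof$r[2], pearson_oracle(k_thr, k_full), tolerance = 1e-12)
})

test_that("below and above modes decompose the full degree exactly", {
  emb <- make_embedding(40, "shell", seed = 1)
  net <- plant_target(emb, m = 120, lambda = 0.05, seed = 2)$network
  full_k <- colSums(net$A)
  L <- net$A * emb$D
  for (thr in c(20, 50, 90, 150)) {
    k_below <- colSums(net$A == 1 & L < thr)
    k_above <- colSums(net$A == 1 & L >= thr)
    expect_identical(k_below + k_above, full_k)
  }
  below <- distance_threshold_degree(net, emb, c(20, 50, 90), "below")
  above <- distance_threshold_degree(net, emb, c(20, 50, 90), "above")
  expect_true(all(below$valid))
  expect_true(all(above$valid))
})

test_that("probability-distance tables enumerate all pairs with the right sign", {
  emb <- make_embedding(100, "shell", scale = 100, seed = 3)
  tgt <- plant_target(emb, m = 300, lambda = 0.1, seed = 4)$network
  spec <- model_spec(gnm_params(1))
  tr <- grow_network(emb, spec, 300, seed = 5)$trace
  pv <- probability_vs_distance(tr, tgt, emb)
  expect_identical(nrow(pv$table), as.integer(100 * 99 / 2))
  expect_lt(pv$spearman, 0)
  expect_identical(sum(pv$table$is_target_edge), 300L)

  # eta = 0: no distance dependence in the rule
  flat <- grow_network(emb, model_spec(gnm_params(0)), 300, seed = 6)$trace
  pv0 <- probability_vs_distance(flat, tgt, emb)
  expect_lt(abs(pv0$spearman), 0.1)

  expect_error(probability_vs_distance(matrix(0, 5, 5), tgt, emb), "shape")
})

test_that("sliding-window precision equals the null at top fraction 1", {
  emb <- make_embedding(60, "shell", scale = 100, seed = 7)
  tgt <- plant_target(emb, m = 150, lambda = 0.1, seed = 8)$network
  tr <- grow_network(emb, model_spec(gnm_params(1)), 150, seed = 9)$trace
  wc <- sliding_window_precision(tr, tgt, emb, top_fracs = 1.0,
                                 center_step = 5)
  valid <- wc[wc$valid, ]
  expect_gt(nrow(valid), 5)
  expect_equal(valid$precision, valid$null)
  expect_true(all(wc$n_pairs[!wc$valid] < 10))
})

test_that("a window of pure target edges is perfectly precise", {
  emb <- make_line_embedding(seq(0, 11))
  # connect every pair closer than 1.5: all distance-1 pairs are edges
  A <- (emb$D > 0 & emb$D < 1.5) * 1
  net <- binary_network(A)
  mp <- matrix(0, 12, 12)
  mp[upper.tri(mp)] <- runif(66)
  mp <- mp + t(mp)
  wc <- sliding_window_precision(mp, net, emb, half_width = 0.2,
                                 top_fracs = c(0.25, 1), center_step = 1,
                                 min_pairs = 5)
  at1 <- wc[wc$center == 1 & wc$valid, ]
  expect_true(all(at1$precision == 1))
  expect_true(all(at1$null == 1))
})

test_that("top-fraction selection matches a manual sort on a 12-pair window", {
  emb <- make_line_embedding(c(0, rep(10, 11)) + c(0, seq(0, 1, length.out = 11)))
  # pairs (1, j) for j >= 2 all lie ~10mm apart; others are close together
  net <- network_from_edges(rbind(c(1, 2), c(1, 3), c(1, 4)), 12)
  mp <- matrix(0, 12, 12)
  probs <- c(0.9, 0.8, 0.05, 0.6, 0.5, 0.4, 0.3, 0.2, 0.15, 0.1, 0.02)
  for (j in 2:12) mp[1, j] <- mp[j, 1] <- probs[j - 1]
  wc <- sliding_window_precision(mp, net, emb, half_width = 1.5,
                                 top_fracs = 0.25, center_step = 10,
                                 min_pairs = 5, seed = 1)
  win <- wc[which.min(abs(wc$center - 10)), ]
  # 11 pairs in the window; top ceiling(0.25 * 11) = 3 by probability are
  # (1,2), (1,3), (1,5); of these only (1,2) and (1,3) are edges
  expect_identical(win$n_pairs, 11L)
  expect_identical(win$n_selected, 3L)
  expect_equal(win$precision, 2 / 3)
  expect_equal(win$null, 3 / 11)
})

test_that("formed-edge FDR obeys exact per-bin counting", {
  emb <- make_line_embedding(c(0, 1, 2, 100, 101))
  tgt <- network_from_edges(rbind(c(1, 2), c(2, 3), c(4, 5)), 5)
  mod <- network_from_edges(rbind(c(1, 2), c(1, 3), c(1, 4)), 5)
  out <- formed_edge_fdr(mod, tgt, emb, c(0, 30, 90, Inf))
  expect_equal(out$fdr[1], 1 / 2)      # (1,2) hit, (1,3) false
  expect_false(out$applicable[2])
  expect_equal(out$fdr[3], 1)          # (1,4) is 100mm and false
  expect_identical(out$n_false, c(1L, 0L, 1L))
  # identity: fdr * bin count = false count, exactly
  expect_equal(out$fdr[out$applicable] * out$n_model[out$applicable],
               out$n_false[out$applicable])

  ident <- formed_edge_fdr(tgt, tgt, emb)
  expect_true(all(ident$fdr[ident$applicable] == 0))
  disj <- formed_edge_fdr(network_from_edges(rbind(c(1, 5), c(2, 5)), 5),
                          tgt, emb)
  expect_true(all(disj$fdr[disj$applicable] == 1))
})
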