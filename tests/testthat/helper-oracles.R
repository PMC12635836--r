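# Independent brute-force oracles, written from first principles and kept
# deliberately naive; they share no code with the package internals.

# two-sample KS: evaluate both ECDFs at every pooled point by counting
ks_oracle <- function(x, y) {
  ts <- c(x, y)
  max(vapply(ts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# local clustering: fraction of realized edges among a node's neighbours
clustering_oracle <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(A[cbind(pairs[1, ], pairs[2, ])])
  }, numeric(1))
}

# betweenness by exhaustive enumeration of all simple paths per pair
betweenness_oracle <- function(A) {
  n <- nrow(A)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nb in which(A[from, ] == 1)) {
      if (!(nb %in% visited)) {
        out <- c(out, all_paths(nb, to, c(visited, nb)))
      }
    }
    out
  }
  bt <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t, s)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        bt[interior] <- bt[interior] + 1 / length(shortest)
      }
    }
  }
  bt
}

# matching index by explicit set operations per pair
matching_oracle <- function(A) {
  n <- nrow(A)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      nb_i <- setdiff(which(A[i, ] == 1), c(i, j))
      nb_j <- setdiff(which(A[j, ] == 1), c(i, j))
      u <- union(nb_i, nb_j)
      M[i, j] <- if (length(u)) length(intersect(nb_i, nb_j)) / length(u) else 0
    }
  }
  M
}

# Pearson correlation from the textbook covariance/sd formula
pearson_oracle <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Spearman with explicit average-rank tie handling, then Pearson on ranks
spearman_oracle <- function(a, b) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  pearson_oracle(avg_rank(a), avg_rank(b))
}

# random connected-ish test graph on n nodes
random_graph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) A[i, j] <- A[j, i] <- 1
    }
  }
  A
}

# small shared fixtures
toy_embedding <- function(n = 10, seed = 11, geometry = "cloud") {
  make_embedding(n, geometry, scale = 50, seed = seed)
}

# direct (non-log-space) evaluation of the wiring rule, for equivalence tests
naive_wiring_oracle <- function(D, Fm, A, eta, gamma, alpha, form, decay) {
  n <- nrow(D)
  absent <- which(A == 0 & upper.tri(A))
  d <- D[absent]
  dist_term <- if (decay == "exponential") exp(-eta * d) else d^(-eta)
  dist_term <- dist_term / max(dist_term)
  if (is.null(Fm)) return(dist_term)
  f <- pmax(Fm[absent], 1e-6)
  feat <- f^gamma
  feat <- feat / max(feat)
  if (form == "additive") dist_term + alpha * feat else dist_term * feat
}
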