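#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist runif rnorm sd setNames quantile
#' @importFrom utils write.table read.table packageVersion
NULL

# Upper-triangle bookkeeping: node pairs (i < j) are addressed by a stable
# pair id given by column-major order of the strict upper triangle.

# (n_pairs x 2) matrix of node pairs in pair-id order
pair_table <- function(n) {
  which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
}

# linear indices into an n x n matrix for each pair id
pair_linear_index <- function(n) {
  which(upper.tri(matrix(0L, n, n)))
}

# pair id lookup for arbitrary (i, j), i != j
pair_id <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  # number of upper-tri cells in columns < hi, plus position within column
  (hi - 1L) * (hi - 2L) / 2L + lo
}

# deterministic child seeds below 2^31, derived from a master seed
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
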