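#' Distance-thresholded degree similarity profile
#'
#' For each distance threshold, recomputes nodal degree using only edges
#' shorter than the threshold (`mode = "below"`) or at least as long
#' (`mode = "above"`), and correlates (Pearson) the thresholded degree
#' vector with the full-network degree vector. The below/above modes are
#' exact complements: their thresholded degrees sum to the full degree at
#' every threshold. Thresholds at which the thresholded degree has zero
#' variance are flagged invalid rather than reported as 0.
#'
#' @param network a [binary_network()].
#' @param embedding the matching [spatial_embedding()].
#' @param thresholds ascending numeric grid of distance thresholds (mm).
#' @param mode `"below"` or `"above"`.
#' @return data.frame `threshold`, `r`, `valid` (class `threshold_profile`).
#' @export
distance_threshold_degree <- function(network, embedding, thresholds,
                                      mode = c("below", "above")) {
  mode <- match.arg(mode)
  if (!length(thresholds)) stop_input("threshold grid is empty")
  if (is.unsorted(thresholds)) stop_input("thresholds must be sorted ascending")
  L <- network$A * embedding$D
  full_k <- colSums(network$A)
  if (sd(full_k) == 0) stop_input("full degree vector has zero variance")
  out <- data.frame(threshold = thresholds, r = NA_real_, valid = FALSE)
  for (i in seq_along(thresholds)) {
    keep <- if (mode == "below") {
      network$A == 1 & L < thresholds[i]
    } else {
      network$A == 1 & L >= thresholds[i]
    }
    k <- colSums(keep)
    if (sd(k) > 0) {
      out$r[i] <- cor(k, full_k)
      out$valid[i] <- TRUE
    }
  }
  class(out) <- c("threshold_profile", class(out))
  out
}

#' Per-pair table of mean connection probability versus distance
#'
#' Tidy table of all node pairs with their separation, the mean connection
#' probability assigned across the growth run, and whether the pair is an
#' edge of the target network, plus the Spearman correlation between
#' distance and mean probability.
#'
#' @param mean_P mean-probability matrix from
#'   [mean_connection_probability()] (or a `growth_trace`).
#' @param target_net the target [binary_network()].
#' @param embedding the shared [spatial_embedding()].
#' @return List `table` (data.frame `i`, `j`, `distance`, `mean_p`,
#'   `is_target_edge`; one row per pair) and `spearman`.
#' @export
probability_vs_distance <- function(mean_P, target_net, embedding) {
  if (inherits(mean_P, "growth_trace")) mean_P <- mean_connection_probability(mean_P)
  n <- embedding$n
  if (nrow(mean_P) != n || ncol(mean_P) != n) stop_input("mean_P has wrong shape")
  pt <- pair_table(n)
  lin <- pair_linear_index(n)
  tab <- data.frame(i = pt[, 1], j = pt[, 2],
                    distance = embedding$D[lin],
                    mean_p = mean_P[lin],
                    is_target_edge = target_net$A[lin] == 1)
  list(table = tab,
       spearman = suppressWarnings(
         cor(tab$distance, tab$mean_p, method = "spearman")))
}

#' Sliding-window precision of high-probability connections
#'
#' At each distance-window centre, collects all node pairs within
#' `half_width` mm, ranks them by mean connection probability, and reports
#' the fraction of the top `f`-quantile (count `ceiling(f * n_window)`,
#' probability ties broken at random) that are target edges. The null is
#' the target-edge base rate among all windowed pairs — the precision
#' expected if all pairs in the window were equally probable. Windows with
#' fewer than `min_pairs` pairs are flagged invalid, not reported as 0.
#'
#' @param mean_P mean-probability matrix (or `growth_trace`).
#' @param target_net the target [binary_network()].
#' @param embedding the shared [spatial_embedding()].
#' @param half_width window half-width, mm (default 5).
#' @param top_fracs fractions of most-probable pairs to score.
#' @param center_step spacing of window centres, mm (default 1).
#' @param min_pairs minimum pairs for a reportable window.
#' @param seed seed for probability-tie randomization.
#' @return data.frame (class `window_curve`): `center`, `top_frac`,
#'   `n_pairs`, `n_selected`, `precision`, `null`, `valid`.
#' @export
sliding_window_precision <- function(mean_P, target_net, embedding,
                                     half_width = 5,
                                     top_fracs = c(0.05, 0.10, 0.25),
                                     center_step = 1, min_pairs = 10,
                                     seed = 1) {
  if (inherits(mean_P, "growth_trace")) mean_P <- mean_connection_probability(mean_P)
  n <- embedding$n
  lin <- pair_linear_index(n)
  d <- embedding$D[lin]
  p <- mean_P[lin]
  is_edge <- target_net$A[lin] == 1
  centers <- seq(min(d), max(d), by = center_step)
  rows <- vector("list", length(centers) * length(top_fracs))
  k <- 0L
  withr::with_seed(as.integer(seed), {
    tie_break <- runif(length(d))
    for (ct in centers) {
      inw <- which(abs(d - ct) <= half_width)
      nw <- length(inw)
      null_rate <- if (nw > 0) mean(is_edge[inw]) else NA_real_
      ord <- inw[order(-p[inw], tie_break[inw])]
      for (f in top_fracs) {
        k <- k + 1L
        if (nw < min_pairs) {
          rows[[k]] <- data.frame(center = ct, top_frac = f, n_pairs = nw,
                                  n_selected = 0L, precision = NA_real_,
                                  null = null_rate, valid = FALSE)
        } else {
          n_sel <- as.integer(ceiling(f * nw))
          sel <- ord[seq_len(n_sel)]
          rows[[k]] <- data.frame(center = ct, top_frac = f, n_pairs = nw,
                                  n_selected = n_sel,
                                  precision = mean(is_edge[sel]),
                                  null = null_rate, valid = TRUE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_curve", class(out))
  out
}

#' Distance-binned false discovery rate of formed edges
#'
#' For each half-open distance bin, the fraction of MODEL edges in the bin
#' that are absent from the target network. Bins containing no model edges
#' are flagged not-applicable.
#'
#' @param model_net,target_net [binary_network()] objects.
#' @param embedding the shared [spatial_embedding()].
#' @param bin_edges ascending bin boundaries, mm.
#' @return data.frame `lo`, `hi`, `n_model`, `n_false`, `fdr`, `applicable`.
#' @export
formed_edge_fdr <- function(model_net, target_net, embedding,
                            bin_edges = c(0, 30, 90, Inf)) {
  em <- edge_pair_ids(model_net)
  if (!length(em)) stop_input("model network has no edges")
  et <- edge_pair_ids(target_net)
  dvec <- embedding$D[pair_linear_index(embedding$n)]
  bin <- findInterval(dvec[em], bin_edges)
  k <- length(bin_edges) - 1
  out <- data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
                    n_model = 0L, n_false = 0L, fdr = NA_real_,
                    applicable = FALSE)
  for (b in seq_len(k)) {
    ids <- em[bin == b]
    out$n_model[b] <- length(ids)
    if (length(ids)) {
      out$n_false[b] <- length(setdiff(ids, et))
      out$fdr[b] <- out$n_false[b] / length(ids)
      out$applicable[b] <- TRUE
    }
  }
  out
}
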