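# File conventions: all tables are tab-separated; node indices are 0-based
# in files (and converted to R's 1-based indexing on read); edge lists are
# canonicalized i < j on write; distances are always mm.

#' Read a binary network from TSV
#'
#' Accepts either a dense n x n 0/1 matrix (no header) or a two-column
#' edge list with a header row; node indices in files are 0-based.
#' Dense input is symmetrized by max (with a warning if asymmetric) and a
#' nonzero diagonal is cleared with a warning. Duplicate edge-list rows
#' collapse to one edge with a message.
#'
#' @param path file path.
#' @param n_nodes node count (required to size edge-list input and to
#'   validate dense input).
#' @return A [binary_network()].
#' @export
read_network <- function(path, n_nodes) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  numeric_first <- !anyNA(suppressWarnings(as.numeric(first)))
  if (numeric_first && length(first) == n_nodes) {
    A <- as.matrix(read.table(path, sep = "\t", header = FALSE))
    dimnames(A) <- NULL
    if (nrow(A) != ncol(A)) stop_input("dense matrix is not square")
    if (!all(A %in% c(0, 1))) stop_input("dense matrix entries must be 0 or 1")
    if (any(diag(A) != 0)) {
      warning("nonzero diagonal cleared on read")
      diag(A) <- 0
    }
    if (!identical(A, t(A))) {
      warning("asymmetric 0/1 matrix symmetrized by max")
      A <- pmax(A, t(A))
    }
    return(binary_network(A))
  }
  if (length(first) != 2) {
    stop_input("unrecognized network format: expected dense ", n_nodes,
               "-column matrix or 2-column edge list")
  }
  el <- read.table(path, sep = "\t", header = TRUE)
  if (nrow(el)) {
    bad <- which(el[, 1] >= n_nodes | el[, 2] >= n_nodes | el[, 1] < 0 | el[, 2] < 0)
    if (length(bad)) {
      stop_input("edge on line ", bad[1] + 1L,
                 " references a node outside 0..", n_nodes - 1L)
    }
    self <- el[, 1] == el[, 2]
    if (any(self)) {
      warning(sum(self), " self-loop(s) dropped on read")
      el <- el[!self, , drop = FALSE]
    }
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    if (anyDuplicated(key)) {
      message(sum(duplicated(key)), " duplicate edge(s) collapsed on read")
      el <- el[!duplicated(key), , drop = FALSE]
    }
  }
  network_from_edges(as.matrix(el) + 1L, n_nodes)
}

#' Write a binary network to TSV
#'
#' @param net a [binary_network()].
#' @param path output path.
#' @param format `"edgelist"` (two 0-based columns `i`, `j`, i < j, header)
#'   or `"dense"` (n x n 0/1 matrix, no header).
#' @param order optional integer vector (one per edge, matching
#'   [network_edges()] order) written as an extra `order` column recording
#'   the growth step at which each edge formed.
#' @export
write_network <- function(net, path, format = c("edgelist", "dense"),
                          order = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    write.table(net$A, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    e <- network_edges(net) - 1L
    df <- data.frame(i = e[, 1], j = e[, 2])
    if (!is.null(order)) df$order <- order
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a grown network with its edge-addition order
#'
#' @param growth result of [grow_network()] (sequential method).
#' @param path output path.
#' @export
write_growth <- function(growth, path) {
  eo <- growth$trace$edge_order
  ids_grown <- pair_id(eo[, 1], eo[, 2], growth$network$n)
  e <- network_edges(growth$network)
  ids_sorted <- pair_id(e[, 1], e[, 2], growth$network$n)
  write_network(growth$network, path, order = match(ids_sorted, ids_grown))
}

#' Write / read a spatial embedding as TSV
#'
#' Columns `node_id`, `x`, `y`, `z` (mm), with a header row.
#'
#' @param embedding a [spatial_embedding()].
#' @param path file path.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(node_id = embedding$node_ids, embedding$coords)
  colnames(df) <- c("node_id", "x", "y", "z")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @param k neighbours for the rebuilt surface-adjacency graph.
#' @export
read_embedding <- function(path, k = 6) {
  df <- read.table(path, sep = "\t", header = TRUE)
  spatial_embedding(as.matrix(df[, c("x", "y", "z")]),
                    node_ids = as.character(df$node_id), k = k)
}

#' Write a feature table as TSV
#'
#' @param features a `feature_table`.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features$values)
  colnames(df) <- paste0("f", seq_len(ncol(df)) - 1L)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a model specification
#'
#' Writes the wiring-rule parameters, feature source, and label as YAML.
#' Static similarity matrices do not travel in the YAML; supply the matrix
#' when restoring.
#'
#' @param spec a [model_spec()].
#' @param path YAML path.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(list(
    label = spec$label,
    feature_source = spec$feature_source,
    params = spec$params[c("eta", "gamma", "alpha", "form", "decay")]
  ), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @param feature a [similarity_matrix()] when the stored source is
#'   `"static"`.
#' @export
read_model_spec <- function(path, feature = NULL) {
  y <- yaml::read_yaml(path)
  p <- y$params
  params <- gnm_params(p$eta, p$gamma, p$alpha, form = p$form, decay = p$decay)
  feat <- switch(y$feature_source,
                 spatial = NULL,
                 matching = "matching",
                 static = feature %||%
                   stop_input("stored spec uses a static feature; supply `feature`"))
  model_spec(params, feature = feat, label = y$label)
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  unname(tools::md5sum(paths))
}

write_manifest <- function(dir, stage, config, seed, outputs) {
  man <- list(package_version = as.character(utils::packageVersion("connectogen")),
              stage = stage,
              config_digest = digest_of(config),
              seed = seed,
              outputs = as.list(setNames(file_digest(outputs), basename(outputs))),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

digest_of <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

stage_fresh <- function(dir, config) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp)
  if (!identical(man$config_digest, as.character(digest_of(config)))) return(FALSE)
  outs <- file.path(dir, names(man$outputs))
  length(outs) > 0 && all(file.exists(outs)) &&
    identical(unname(unlist(man$outputs)), unname(file_digest(outs)))
}

validate_config <- function(config) {
  req <- function(x, key, where) {
    if (is.null(x)) stop_input("config error at ", where, ": missing `", key, "`")
    x
  }
  req(config$seed, "seed", "$seed")
  sy <- req(config$synth, "synth", "$synth")
  req(sy$n, "n", "$synth$n")
  req(sy$m, "m", "$synth$m")
  req(sy$lambda, "lambda", "$synth$lambda")
  models <- req(config$models, "models", "$models")
  for (i in seq_along(models)) {
    req(models[[i]]$name, "name", paste0("$models[[", i, "]]$name"))
    req(models[[i]]$eta, "eta", paste0("$models[[", i, "]]$eta"))
  }
  invisible(config)
}

build_model_spec <- function(mc, similarity) {
  params <- gnm_params(mc$eta, mc$gamma %||% 0, mc$alpha %||% 0,
                       form = mc$form %||% "additive",
                       decay = mc$decay %||% "exponential")
  feature <- switch(mc$feature %||% "spatial",
                    spatial = NULL,
                    random_similarity = similarity,
                    matching = "matching",
                    stop_input("config error: unknown model feature `",
                               mc$feature, "`"))
  model_spec(params, feature = feature, label = mc$name)
}

#' Run a declared end-to-end experiment
#'
#' Executes the stage graph synth -> grow/fit -> rewire/analyses, writing
#' per-stage TSV/CSV outputs and JSON manifests under `out_dir`. The master
#' seed deterministically derives all stage seeds, so identical configs
#' produce byte-identical result tables. A stage whose recorded config
#' digest and output digests are intact is skipped on rerun; deleting its
#' outputs regenerates it.
#'
#' @param config configuration list, or path to a YAML file holding one.
#'   Required keys: `seed`; `synth` (`n`, `m`, `lambda`, optional
#'   `geometry`, `scale`, `k`, `hub`, `features`); `models` (list of
#'   `name`, `eta`, optional `gamma`, `alpha`, `form`, `decay`,
#'   `feature` in `spatial|random_similarity|matching`, `fit`, `budget`).
#'   Optional: `rewire` (`ordering`, `target_rule`, `n_runs`,
#'   `checkpoint_step`), `analyses` (`bin_edges`, `thresholds`).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4 + length(config$models))

  # --- synth stage ---------------------------------------------------------
  sy <- config$synth
  synth_dir <- file.path(out_dir, "synth")
  synth_cfg <- list(synth = sy, seed = seeds[1])
  emb <- NULL; target <- NULL; sim <- NULL
  build_synth <- function() {
    emb <<- make_embedding(sy$n, sy$geometry %||% "shell",
                           scale = sy$scale %||% 100, k = sy$k %||% 6,
                           seed = seeds[1])
    tgt <- plant_target(emb, m = sy$m, lambda = sy$lambda,
                        hub_spec = sy$hub, seed = seeds[2])
    target <<- tgt$network
    fc <- sy$features %||% list()
    feats <- smooth_random_features(emb, n_features = fc$n_features %||% 20,
                                    n_smooth = fc$n_smooth %||% 5,
                                    seed = seeds[3])
    sim <<- feature_similarity(feats, orientation = fc$orientation %||% "similarity")
    list(feats = feats)
  }
  if (!stage_fresh(synth_dir, synth_cfg)) {
    dir.create(synth_dir, showWarnings = FALSE)
    st <- build_synth()
    write_embedding(emb, file.path(synth_dir, "coords.tsv"))
    write_network(target, file.path(synth_dir, "target.tsv"))
    write_features(st$feats, file.path(synth_dir, "features.tsv"))
    write_manifest(synth_dir, "synth", synth_cfg, seeds[1],
                   file.path(synth_dir, c("coords.tsv", "target.tsv", "features.tsv")))
  } else {
    build_synth()   # objects rebuilt in memory; outputs untouched
  }

  # --- model stages --------------------------------------------------------
  bins <- config$analyses$bin_edges %||% c(0, 30, 90, Inf)
  for (i in seq_along(config$models)) {
    mc <- config$models[[i]]
    mdir <- file.path(out_dir, "models", mc$name)
    mcfg <- list(model = mc, synth = synth_cfg, bins = bins)
    if (stage_fresh(mdir, mcfg)) next
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
    spec <- build_model_spec(mc, sim)
    mseed <- seeds[4 + i - 1L]
    if (isTRUE(mc$fit)) {
      fit <- optimize_gnm(spec, target, emb,
                          budget = budget_preset(mc$budget %||% "tiny"),
                          seed = mseed)
      net <- fit$best_network
      utils::write.csv(fit$evaluations, file.path(mdir, "evaluations.csv"),
                       row.names = FALSE)
    } else {
      net <- grow_network(emb, spec, m_target = target$m, seed = mseed)$network
    }
    write_network(net, file.path(mdir, "network.tsv"))
    utils::write.csv(fit_result(net, target, emb, include_alt = TRUE),
                     file.path(mdir, "fit.csv"), row.names = FALSE)
    utils::write.csv(distance_binned_recovery(net, target, emb, bins),
                     file.path(mdir, "binned_recovery.csv"), row.names = FALSE)
    outs <- file.path(mdir, c("network.tsv", "fit.csv", "binned_recovery.csv",
                              if (isTRUE(mc$fit)) "evaluations.csv"))
    write_manifest(mdir, paste0("model:", mc$name), mcfg, mseed, outs)
  }

  # --- rewiring stage ------------------------------------------------------
  if (!is.null(config$rewire)) {
    rc <- config$rewire
    rdir <- file.path(out_dir, "rewire")
    rcfg <- list(rewire = rc, synth = synth_cfg)
    if (!stage_fresh(rdir, rcfg)) {
      dir.create(rdir, showWarnings = FALSE)
      cfg <- rewiring_config(rc$ordering %||% "random",
                             rc$target_rule %||% "similar",
                             n_runs = rc$n_runs %||% 5,
                             checkpoint_step = rc$checkpoint_step)
      trajs <- rewire_ensemble(target, emb, cfg, seed = seeds[4])
      utils::write.csv(rewiring_curves(trajs, "maxKS"),
                       file.path(rdir, "curve_maxKS.csv"), row.names = FALSE)
      write_manifest(rdir, "rewire", rcfg, seeds[4],
                     file.path(rdir, "curve_maxKS.csv"))
    }
  }

  # --- analyses stage ------------------------------------------------------
  an <- config$analyses %||% list()
  adir <- file.path(out_dir, "analyses")
  acfg <- list(analyses = an, synth = synth_cfg)
  if (!stage_fresh(adir, acfg)) {
    dir.create(adir, showWarnings = FALSE)
    thresholds <- an$thresholds %||%
      seq(10, ceiling(max(emb$D)) + 10, by = 10)
    utils::write.csv(distance_threshold_degree(target, emb, thresholds, "below"),
                     file.path(adir, "threshold_degree.csv"), row.names = FALSE)
    write_manifest(adir, "analyses", acfg, seeds[1],
                   file.path(adir, "threshold_degree.csv"))
  }

  invisible(out_dir)
}
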