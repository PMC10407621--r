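# End-to-end orchestration: descriptors -> selection -> ANN training ->
# evaluation -> applicability domain, with a written run directory and
# manifest.

#' Run configuration for the end-to-end study pipeline
#'
#' @param data `"fixture"` (the packaged 72-compound dataset),
#'   the path of a dataset CSV (see [read_dataset_csv()]), an
#'   `ro_qsar_dataset`, or an `ro_synth_spec`.
#' @param out_dir output directory (created if absent).
#' @param split_mode `"fixed"` (use the labels carried by the data) or
#'   `"random"` (reassign by seeded permutation with the study's
#'   69.44/15.27/15.27 fractions).
#' @param seed seed for random splitting and training initialization.
#' @param k number of descriptors to select (cascade skipped when the data
#'   already has exactly `k` columns).
#' @param corr_threshold correlation-pruning threshold.
#' @param train_config an `ro_train_config`; its seed is overridden by
#'   `seed`.
#' @return an `ro_run_config` list.
#' @export
run_config <- function(data = "fixture", out_dir = tempfile("roqsar_run_"),
                       split_mode = c("fixed", "random"), seed = 1L, k = 4L,
                       corr_threshold = 0.90,
                       train_config = ann_config()) {
  structure(list(data = data, out_dir = out_dir,
                 split_mode = match.arg(split_mode), seed = as.integer(seed),
                 k = as.integer(k), corr_threshold = corr_threshold,
                 train_config = train_config),
            class = "ro_run_config")
}

.ro_resolve_dataset <- function(config) {
  d <- config$data
  if (inherits(d, "ro_qsar_dataset")) return(d)
  if (inherits(d, "ro_synth_spec")) return(synth_generate(d)$dataset)
  if (identical(d, "fixture")) {
    rec <- load_fixture()
    mols <- lapply(seq_len(nrow(rec)), function(i) {
      parse_smiles(rec$smiles[i], name = rec$name[i], abbrev = rec$abbrev[i])
    })
    desc <- suppressWarnings(descriptor_table(mols, embed_missing = TRUE))
    return(assemble(rec, desc, response = "experimental"))
  }
  if (is.character(d) && file.exists(d)) return(read_dataset_csv(d))
  stop("cannot resolve data source: supply 'fixture', a dataset CSV path, ",
       "an ro_qsar_dataset, or an ro_synth_spec")
}

#' Run the full study pipeline
#'
#' Resolves the data source, optionally reassigns splits, runs the
#' descriptor filtering cascade (when there are more columns than `k`),
#' trains the network, computes fit statistics per split plus an MLR
#' baseline, derives the applicability-domain report, and writes every
#' artifact (descriptor CSV, selection report JSON, weights JSON, metrics
#' CSV, Williams TSV, manifest JSON) into `config$out_dir`.
#'
#' @param config an `ro_run_config`.
#' @return invisibly, a list with `dataset`, `selection`, `ann`, `mlr`,
#'   `metrics`, `ad`, `out_dir`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "ro_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- .ro_resolve_dataset(config)

  if (config$split_mode == "random") {
    set.seed(config$seed)
    sizes <- .ro_split_sizes(nrow(dataset$X), c(0.6944, 0.1527, 0.1527))
    dataset$splits <- factor(rep(c("training", "test", "validation"), times = sizes),
                             levels = c("training", "test", "validation"))[sample.int(nrow(dataset$X))]
  }

  write_dataset_csv(dataset, file.path(config$out_dir, "dataset.csv"))

  selection <- NULL
  X <- dataset$X
  if (ncol(X) > config$k) {
    selection <- select_descriptors(X, dataset$y, k = config$k,
                                    corr_threshold = config$corr_threshold)
    X <- X[, selection$selected, drop = FALSE]
    jsonlite::write_json(list(
      n_input = selection$n_input,
      n_zero_variance_removed = selection$n_zero_variance_removed,
      n_correlation_removed = selection$n_correlation_removed,
      stepwise_ranking = selection$stepwise_ranking,
      selected = selection$selected
    ), file.path(config$out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  }
  model_data <- dataset; model_data$X <- X

  tc <- config$train_config
  tc$topology[1] <- ncol(X)
  tc$seed <- config$seed
  ann <- ann_train(model_data, tc)
  pred_ann <- predict(ann, X)

  tr <- dataset$splits == "training"
  mlr <- fit_mlr(X[tr, , drop = FALSE], dataset$y[tr])
  pred_mlr <- predict(mlr, X)

  metrics <- list()
  for (sc in c("total", "training", "test", "validation")) {
    keep <- if (sc == "total") rep(TRUE, nrow(X)) else dataset$splits == sc
    if (sum(keep) >= 2L) {
      metrics[[paste0("ann_", sc)]] <- fit_metrics(dataset$y[keep], pred_ann[keep], scope = sc)
      metrics[[paste0("mlr_", sc)]] <- fit_metrics(dataset$y[keep], pred_mlr[keep], scope = sc)
    }
  }
  mdf <- do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(model = sub("_.*", "", nm), scope = m$scope, n = m$n,
               r2 = m$r2, mse = m$mse, rmse = m$rmse, mpe = m$mpe)
  }))
  utils::write.csv(mdf, file.path(config$out_dir, "metrics.csv"), row.names = FALSE)

  ad <- williams_report(dataset$y, pred_ann, X, dataset$splits)
  write_williams_tsv(ad, file.path(config$out_dir, "williams.tsv"))

  w <- ann$weights
  jsonlite::write_json(list(
    topology = tc$topology, W = w$W, b_hidden = w$b_hidden, v = w$v,
    b_out = w$b_out, descriptor_names = colnames(X),
    stop_reason = ann$stop_reason, epochs_run = ann$epochs_run,
    garson_importance = as.list(garson_importance(ann))
  ), file.path(config$out_dir, "ann_model.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("roqsar")),
    seed = config$seed, split_mode = config$split_mode,
    n_compounds = nrow(dataset$X),
    data_checksum = .ro_checksum(dataset),
    stop_reason = ann$stop_reason,
    artifacts = c("dataset.csv", if (!is.null(selection)) "selection.json",
                  "metrics.csv", "williams.tsv", "ann_model.json")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = dataset, selection = selection, ann = ann,
                 mlr = mlr, metrics = metrics, ad = ad,
                 out_dir = config$out_dir))
}

# order-stable numeric checksum of the dataset (no digest dependency)
.ro_checksum <- function(dataset) {
  v <- c(as.numeric(dataset$X), dataset$y, as.integer(dataset$splits))
  sprintf("%.8e", sum(v * seq_along(v)) %% 1e9)
}

#' Hidden-node sweep
#'
#' Trains one network per hidden-node count over `node_range` (same data,
#' same seed) and reports the test-split MSE, marking the minimum. The
#' test-set MSE is the model-selection criterion for network size.
#'
#' @param dataset an `ro_qsar_dataset` whose columns are the model inputs.
#' @param node_range integer vector of hidden-node counts (default 1:7).
#' @param config an `ro_train_config` template.
#' @return data frame `hidden_nodes`, `mse_test`, `r2_test`, `selected`,
#'   sorted by node count.
#' @export
hidden_node_sweep <- function(dataset, node_range = 1:7, config = ann_config()) {
  stopifnot(inherits(dataset, "ro_qsar_dataset"))
  te <- dataset$splits == "test"
  if (sum(te) < 2L) stop("test split too small for a hidden-node sweep")
  node_range <- sort(unique(as.integer(node_range)))
  rows <- lapply(node_range, function(nh) {
    tc <- config
    tc$topology <- c(ncol(dataset$X), nh, 1L)
    fit <- ann_train(dataset, tc)
    pred <- predict(fit, dataset$X)
    m <- fit_metrics(dataset$y[te], pred[te], scope = "test")
    data.frame(hidden_nodes = nh, mse_test = m$mse, r2_test = m$r2)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$mse_test == min(out$mse_test)
  out
}
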