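# Cross-validated evaluation: per-fold metric rows, mean +/- SD aggregation,
# cold-start subsetting, and the three-variant ablation comparison.

#' Metrics of one trained fold
#'
#' Chooses the decision threshold on the validation split by Youden's J,
#' then reports accuracy, sensitivity, specificity, precision, MCC, ROC AUC
#' and PR AUC on the fold's test pairs, plus AUC/AUPR on the cold-start test
#' subset when it contains both classes.
#'
#' @param model A trained `mvgat_model`.
#' @param graph The fold's multi-view graph.
#' @param interactions The fold's [build_interaction_set()].
#' @return One-row data.frame of fold metrics.
#' @export
evaluate_fold <- function(model, graph, interactions) {
  val <- interactions[interactions$split == "val", , drop = FALSE]
  test <- interactions[interactions$split == "test", , drop = FALSE]
  val_scores <- predict_interactions(model, graph, val)
  test_scores <- predict_interactions(model, graph, test)
  thr <- youden_threshold(val$label, val_scores)
  cm <- confusion_metrics(test$label, test_scores, thr)
  cold <- interactions$cold_start[interactions$split == "test"]
  cold_auc <- cold_aupr <- NA_real_
  if (sum(cold & test$label == 1) >= 1 && sum(cold & test$label == 0) >= 1) {
    cold_auc <- roc_auc(test$label[cold], test_scores[cold])
    cold_aupr <- pr_auc(test$label[cold], test_scores[cold])
  }
  data.frame(
    n_test = nrow(test), threshold = thr,
    acc = cm[["acc"]], sen = cm[["sen"]], spec = cm[["spec"]],
    pre = cm[["pre"]], mcc = cm[["mcc"]],
    auc = roc_auc(test$label, test_scores),
    aupr = pr_auc(test$label, test_scores),
    n_cold = sum(cold), cold_auc = cold_auc, cold_aupr = cold_aupr
  )
}

metric_cols <- c("acc", "sen", "spec", "pre", "mcc", "auc", "aupr")

#' Aggregate per-fold models into a cross-validation report
#'
#' @param models List of trained `mvgat_model`s, one per fold.
#' @param graphs List of the matching per-fold graphs.
#' @param interaction_sets List of the matching [build_interaction_set()]s.
#' @return An `eval_report`: `per_fold` (one row per fold), `summary`
#'   (mean and SD of each metric), and `table` (the k + 1 row report with
#'   the Average row, as written by the CLI).
#' @export
evaluate_cv <- function(models, graphs, interaction_sets) {
  k <- length(models)
  if (k == 0L || length(graphs) != k || length(interaction_sets) != k) {
    stop_input("need one model, graph and interaction set per fold")
  }
  rows <- lapply(seq_len(k), function(f) {
    cbind(fold = f,
          evaluate_fold(models[[f]], graphs[[f]], interaction_sets[[f]]))
  })
  aggregate_report(do.call(rbind, rows))
}

aggregate_report <- function(per_fold) {
  mean_row <- vapply(per_fold[metric_cols], mean, numeric(1))
  sd_row <- vapply(per_fold[metric_cols], sd, numeric(1))
  if (nrow(per_fold) == 1L) sd_row[] <- 0
  summary <- data.frame(stat = c("mean", "sd"),
                        rbind(mean_row, sd_row), row.names = NULL)
  tab <- per_fold[, c("fold", metric_cols)]
  tab$fold <- as.character(tab$fold)
  tab <- rbind(tab, data.frame(fold = "Average",
                               as.list(mean_row)))
  structure(list(per_fold = per_fold, summary = summary, table = tab),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  tab <- x$table
  tab[metric_cols] <- lapply(tab[metric_cols], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the full cross-validation pipeline
#'
#' Builds the rotating folds, and for each fold: samples fresh negatives,
#' restricts the known-interaction view to the fold's training positives,
#' trains a model and scores the held-out pairs.
#'
#' @param graph A [assemble_multiview_graph()]; its drug-protein view is
#'   replaced per fold.
#' @param positives Data.frame of known interactions (`drug_id`,
#'   `protein_id`).
#' @param config A [train_config()].
#' @param k Number of folds.
#' @param folds_to_run Optional subset of fold indices (default all).
#' @param keep_models Keep the trained models in the result.
#' @return List with `report` (an `eval_report`), `folds`, and optionally
#'   `models`, `graphs`, `interaction_sets`.
#' @export
run_cv <- function(graph, positives, config = train_config(), k = 5,
                   folds_to_run = seq_len(k), keep_models = FALSE) {
  stopifnot(inherits(graph, "multiview_graph"))
  tab <- graph$entities$table
  drug_ids <- tab$id[tab$kind == "drug"]
  protein_ids <- tab$id[tab$kind == "protein"]
  folds <- make_folds(positives, k, seed = child_seed(config$seed, 50))
  rows <- list()
  models <- graphs <- isets <- list()
  for (f in folds_to_run) {
    iset <- build_interaction_set(folds, f, drug_ids, protein_ids,
                                  ratio = config$negative_ratio,
                                  seed = config$seed)
    train_pos <- folds$positives[folds$roles[, f] == "train", , drop = FALSE]
    graph_f <- set_interaction_view(graph, train_pos)
    model <- train_model(graph_f, iset, config)
    rows[[length(rows) + 1L]] <- cbind(fold = f,
                                       evaluate_fold(model, graph_f, iset))
    if (keep_models) {
      models[[as.character(f)]] <- model
      graphs[[as.character(f)]] <- graph_f
      isets[[as.character(f)]] <- iset
    }
  }
  out <- list(report = aggregate_report(do.call(rbind, rows)), folds = folds)
  if (keep_models) {
    out$models <- models
    out$graphs <- graphs
    out$interaction_sets <- isets
  }
  out
}

#' Ablation comparison on one fold
#'
#' Trains and evaluates the full model, the no-attention (uniform-weight
#' GCN) variant and the no-attributes variant under identical folds, seeds
#' and negative samples, reporting overall and cold-start AUC/AUPR per
#' variant.
#'
#' @param graph The fold's multi-view graph (training-positives interaction
#'   view).
#' @param interactions The fold's [build_interaction_set()].
#' @param config Base [train_config()] (attention and attributes enabled).
#' @return Data.frame with one row per variant (`full`, `no_attention`,
#'   `no_attributes`).
#' @export
run_ablations <- function(graph, interactions, config = train_config()) {
  variants <- list(
    full = config,
    no_attention = modifyList(config, list(use_attention = FALSE)),
    no_attributes = modifyList(config, list(use_attributes = FALSE))
  )
  rows <- lapply(names(variants), function(nm) {
    cfg <- structure(variants[[nm]], class = "train_config")
    model <- train_model(graph, interactions, cfg)
    ev <- evaluate_fold(model, graph, interactions)
    cbind(variant = nm, ev)
  })
  do.call(rbind, rows)
}
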