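test_that("fold splits follow the rotating 80/10/10 protocol", {
  pos <- data.frame(drug_id = sprintf("d%04d", 1:1000),
                    protein_id = sprintf("p%04d", 1:1000))
  folds <- make_folds(pos, k = 5, seed = 3)
  for (f in 1:5) {
    expect_equal(as.integer(table(factor(folds$roles[, f],
                                         c("train", "val", "test")))),
                 c(800L, 100L, 100L))
  }
  # held-out blocks partition the positives; test blocks pairwise disjoint
  held <- lapply(1:5, function(f) which(folds$roles[, f] != "train"))
  expect_equal(sort(unlist(held)), 1:1000)
  tests <- lapply(1:5, function(f) which(folds$roles[, f] == "test"))
  expect_equal(anyDuplicated(unlist(tests)), 0L)
  # determinism
  expect_identical(make_folds(pos, 5, seed = 3)$roles, folds$roles)
  expect_error(make_folds(pos[1:3, ], k = 5), class = "mvgat_config_error")
})

test_that("negative sampling avoids the positive set exactly", {
  drugs <- sprintf("d%02d", 1:10)
  prots <- sprintf("p%02d", 1:10)
  set.seed(2)
  pos <- unique(data.frame(drug_id = sample(drugs, 50, replace = TRUE),
                           protein_id = sample(prots, 50, replace = TRUE)))
  neg <- sample_negatives(pos, drugs, prots, ratio = 1, seed = 5)
  expect_equal(nrow(neg), nrow(pos))
  expect_length(intersect(paste(neg$drug_id, neg$protein_id),
                          paste(pos$drug_id, pos$protein_id)), 0)
  expect_identical(sample_negatives(pos, drugs, prots, ratio = 1, seed = 5),
                   neg)
  # complete bipartite positive set: no complement left
  full <- expand.grid(drug_id = drugs, protein_id = prots,
                      stringsAsFactors = FALSE)
  expect_error(sample_negatives(full, drugs, prots, ratio = 1, seed = 1),
               class = "mvgat_train_error")
})

test_that("cold-start flags depend on training-fold coverage", {
  pos <- data.frame(
    drug_id = c("d1", "d2", "d2", "d2", "d2", "d2", "d3", "d4", "d5", "d6"),
    protein_id = c("p1", "p1", "p2", "p3", "p4", "p5", "p2", "p3", "p4",
                   "p5"))
  folds <- structure(list(positives = pos, k = 2, seed = 1,
                          roles = matrix("train", 10, 2)),
                     class = "fold_assignment")
  # fold 1: d1's only pair held out -> cold; one of d2's five -> warm
  folds$roles[1, 1] <- "test"
  folds$roles[3, 1] <- "test"
  flags <- flag_cold_start(folds, 1)
  expect_identical(flags, c(TRUE, FALSE))
  # all entities covered in training -> empty cold-start set
  folds$roles[, 2] <- "train"
  expect_length(flag_cold_start(folds, 2), 0)
})

test_that("interaction sets are duplicate-free and split-consistent", {
  w <- tiny_world(seed = 3)
  tab <- w$entities$table
  folds <- make_folds(w$positives, 3, seed = 4)
  iset <- build_interaction_set(folds, 2, tab$id[tab$kind == "drug"],
                                tab$id[tab$kind == "protein"], seed = 4)
  key <- paste(iset$drug_id, iset$protein_id)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(iset$split %in% c("train", "val", "test")))
  expect_true(all(iset$label[iset$cold_start] %in% 0:1))
  neg <- iset[iset$label == 0, ]
  expect_length(intersect(paste(neg$drug_id, neg$protein_id),
                          paste(w$positives$drug_id,
                                w$positives$protein_id)), 0)
  # negatives per split match the configured 1:1 ratio
  for (s in c("train", "val", "test")) {
    expect_equal(sum(iset$split == s & iset$label == 0),
                 sum(iset$split == s & iset$label == 1))
  }
})

test_that("training logs finite losses and stops on the leakage guard", {
  w <- tiny_world(seed = 5)
  graph <- assemble_multiview_graph(w$entities, w$views, kmer_k = 1)
  tab <- graph$entities$table
  folds <- make_folds(w$positives, 2, seed = 5)
  iset <- build_interaction_set(folds, 1, tab$id[tab$kind == "drug"],
                                tab$id[tab$kind == "protein"], seed = 5)
  train_pos <- folds$positives[folds$roles[, 1] == "train", ]
  gf <- set_interaction_view(graph, train_pos)
  model <- train_model(gf, iset, fast_train_config(max_epochs = 6))
  expect_true(all(is.finite(model$log$loss)))
  expect_true(all(model$log$val_auc >= 0 & model$log$val_auc <= 1))

  # a graph whose interaction view still contains held-out positives
  expect_error(train_model(graph, iset, fast_train_config()),
               class = "mvgat_train_error")
})

test_that("training is deterministic given config and seed", {
  w <- tiny_world(seed = 6)
  graph <- assemble_multiview_graph(w$entities, w$views, kmer_k = 1)
  tab <- graph$entities$table
  folds <- make_folds(w$positives, 2, seed = 6)
  iset <- build_interaction_set(folds, 1, tab$id[tab$kind == "drug"],
                                tab$id[tab$kind == "protein"], seed = 6)
  gf <- set_interaction_view(graph,
                             folds$positives[folds$roles[, 1] == "train", ])
  m1 <- train_model(gf, iset, fast_train_config(max_epochs = 5))
  m2 <- train_model(gf, iset, fast_train_config(max_epochs = 5))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
})

test_that("cross-validation reports aggregate correctly", {
  per_fold <- data.frame(fold = 1:3, n_test = 10, threshold = 0.5,
                         acc = c(0.8, 0.9, 1.0), sen = 0.9, spec = 0.8,
                         pre = 0.85, mcc = c(0.5, 0.6, 0.7),
                         auc = c(0.90, 0.92, 0.94),
                         aupr = c(0.88, 0.90, 0.92), n_cold = 0,
                         cold_auc = NA_real_, cold_aupr = NA_real_)
  rep3 <- mvgat:::aggregate_report(per_fold)
  expect_equal(nrow(rep3$table), 4)  # k folds + Average
  expect_equal(rep3$table$auc[4], 0.92)
  expect_equal(rep3$summary$acc[1], 0.9)
  expect_equal(rep3$summary$acc[2], sd(c(0.8, 0.9, 1.0)))
  # identical per-fold metrics -> zero SD
  same <- per_fold
  same[mvgat:::metric_cols] <- lapply(same[mvgat:::metric_cols],
                                      function(x) rep(x[1], 3))
  expect_true(all(mvgat:::aggregate_report(same)$summary[2,
                    mvgat:::metric_cols] == 0))
})

test_that("evaluate_cv scores one model per fold and aggregates", {
  w <- tiny_world(seed = 8)
  graph <- assemble_multiview_graph(w$entities, w$views, kmer_k = 1)
  tab <- graph$entities$table
  folds <- make_folds(w$positives, 2, seed = 8)
  models <- graphs <- isets <- list()
  for (f in 1:2) {
    isets[[f]] <- build_interaction_set(folds, f, tab$id[tab$kind == "drug"],
                                        tab$id[tab$kind == "protein"],
                                        seed = 8)
    graphs[[f]] <- set_interaction_view(
      graph, folds$positives[folds$roles[, f] == "train", ])
    models[[f]] <- train_model(graphs[[f]], isets[[f]],
                               fast_train_config(max_epochs = 4))
  }
  rep2 <- evaluate_cv(models, graphs, isets)
  expect_s3_class(rep2, "eval_report")
  expect_equal(nrow(rep2$table), 3)
  expect_equal(rep2$table$auc[3], mean(rep2$per_fold$auc))
  expect_error(evaluate_cv(models, graphs[1], isets),
               class = "mvgat_input_error")
})

test_that("the ablation runner compares three variants on shared folds", {
  w <- tiny_world(seed = 7)
  graph <- assemble_multiview_graph(w$entities, w$views, kmer_k = 1)
  tab <- graph$entities$table
  folds <- make_folds(w$positives, 2, seed = 7)
  iset <- build_interaction_set(folds, 1, tab$id[tab$kind == "drug"],
                                tab$id[tab$kind == "protein"], seed = 7)
  gf <- set_interaction_view(graph,
                             folds$positives[folds$roles[, 1] == "train", ])
  abl <- run_ablations(gf, iset, fast_train_config(max_epochs = 4))
  expect_equal(abl$variant, c("full", "no_attention", "no_attributes"))
  expect_true(all(abl$auc >= 0 & abl$auc <= 1))
  expect_true(all(abl$n_test == abl$n_test[1]))
})
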