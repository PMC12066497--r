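# Protocol plumbing and the optimization loop: rotating 80/10/10 fold
# construction over the known positives, per-fold negative resampling from
# the complement of the full positive set, cold-start flagging, and
# full-batch Adam on binary cross-entropy with early stopping on validation
# AUC.

#' Training and model hyperparameter configuration
#'
#' @param embedding_dim Working embedding dimension of the encoder (the
#'   node-embedding size; default 32 for desk-scale runs, configurable up to
#'   the hundreds).
#' @param attention_dim Dimension of the query/key projections.
#' @param n_layers Message-passing layers per view.
#' @param mlp_layers Fully connected layers in the pair scorer (1-4).
#' @param mlp_hidden Width of the hidden MLP layers.
#' @param use_attention `FALSE` switches every layer to the uniform-weight
#'   GCN ablation variant.
#' @param use_attributes `FALSE` zeroes the pair-level prior block and the
#'   attribute-derived initial node features (shapes unchanged) — the
#'   attribute-ablation variant.
#' @param scale_attention Divide attention logits by `sqrt(attention_dim)`.
#' @param standardize_features Column-standardize the attribute feature
#'   blocks before they enter the model (label-free, recomputed
#'   deterministically from the graph; keeps the 0/1 fingerprint block and
#'   the small-valued k-mer block on comparable scales).
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled L2 penalty applied at each step (0 = off).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs without validation-AUC
#'   improvement.
#' @param ema_decay Exponential-moving-average decay for Polyak parameter
#'   averaging (0 disables).  Validation AUC and the returned model use the
#'   averaged parameters, which smooths the epoch-to-epoch noise of
#'   full-batch training.
#' @param mlp_refine Extra MLP-only optimization steps per epoch, taken on
#'   the epoch's (fixed) encoder output.  The pair scorer has to learn a
#'   multiplicative interaction from concatenated inputs, which needs many
#'   more gradient steps than the encoder; refining the head against the
#'   current embeddings buys those steps at a fraction of a full joint step.
#' @param negative_ratio Negatives per positive (default 1: balanced).
#' @param batch_size Pairs per gradient step; 0 (default) trains full-batch,
#'   which is deterministic and lets one encoder pass serve all pairs.
#' @param kmer_k Protein k-mer size used when the pipeline assembles
#'   features.
#' @param seed Seed for parameter initialisation and any sampling.
#' @param verbose Print per-epoch loss and validation AUC.
#' @return An object of class `train_config`.
#' @export
train_config <- function(embedding_dim = 32, attention_dim = 16,
                         n_layers = 2, mlp_layers = 2, mlp_hidden = 128,
                         use_attention = TRUE, use_attributes = TRUE,
                         scale_attention = FALSE, standardize_features = TRUE,
                         learning_rate = 0.01, weight_decay = 0,
                         max_epochs = 300, patience = 40, ema_decay = 0,
                         mlp_refine = 0,
                         negative_ratio = 1, batch_size = 0, kmer_k = 2,
                         seed = 1, verbose = FALSE) {
  mlp_layers <- check_count(mlp_layers, "mlp_layers")
  if (mlp_layers > 4) stop_config("mlp_layers must be between 1 and 4")
  structure(list(
    embedding_dim = check_count(embedding_dim, "embedding_dim"),
    attention_dim = check_count(attention_dim, "attention_dim"),
    n_layers = check_count(n_layers, "n_layers"),
    mlp_layers = mlp_layers,
    mlp_hidden = check_count(mlp_hidden, "mlp_hidden"),
    use_attention = isTRUE(use_attention),
    use_attributes = isTRUE(use_attributes),
    scale_attention = isTRUE(scale_attention),
    standardize_features = isTRUE(standardize_features),
    learning_rate = check_real(learning_rate, "learning_rate", lower = 1e-8),
    weight_decay = check_real(weight_decay, "weight_decay", lower = 0),
    max_epochs = check_count(max_epochs, "max_epochs"),
    patience = check_count(patience, "patience"),
    ema_decay = check_real(ema_decay, "ema_decay", 0, 0.9999),
    mlp_refine = check_count(mlp_refine, "mlp_refine", min = 0L),
    negative_ratio = check_real(negative_ratio, "negative_ratio",
                                lower = 1e-8),
    batch_size = check_count(batch_size, "batch_size", min = 0L),
    kmer_k = check_count(kmer_k, "kmer_k"),
    seed = check_count(seed, "seed", min = 0L),
    verbose = isTRUE(verbose)
  ), class = "train_config")
}

pair_key <- function(drug_id, protein_id) paste(drug_id, protein_id,
                                                sep = "\r")

#' Sample negative drug-protein pairs
#'
#' Uniform sample without replacement from the complement of the positive
#' set over all drug x protein cells; size is `floor(ratio * n_positives)`.
#' Deterministic given the seed.
#'
#' @param positives Data.frame with `drug_id`, `protein_id`.
#' @param drug_ids,protein_ids The full entity id vectors spanning the pair
#'   universe.
#' @param ratio Negatives per positive.
#' @param seed Integer seed.
#' @param exclude Optional additional pairs to exclude (defaults to
#'   `positives` only).
#' @param count Exact number of negatives to draw; overrides `ratio`.
#' @return Data.frame of negative pairs with a `label = 0` column.
#' @export
sample_negatives <- function(positives, drug_ids, protein_ids, ratio = 1,
                             seed = 1, exclude = positives, count = NULL) {
  nd <- length(drug_ids)
  np <- length(protein_ids)
  m <- if (is.null(count)) floor(ratio * nrow(positives)) else count
  ex_d <- match(exclude$drug_id, drug_ids)
  ex_p <- match(exclude$protein_id, protein_ids)
  if (anyNA(ex_d) || anyNA(ex_p)) {
    stop_input("excluded pairs reference unknown entity ids")
  }
  ex_lin <- unique((ex_p - 1L) * nd + ex_d)
  complement <- setdiff(seq_len(nd * np), ex_lin)
  if (m > length(complement)) {
    stop_train(sprintf(
      "requested %d negatives but only %d non-positive pairs exist",
      m, length(complement)))
  }
  set.seed(seed)
  pick <- sort(sample(complement, m))
  data.frame(
    drug_id = drug_ids[(pick - 1L) %% nd + 1L],
    protein_id = protein_ids[(pick - 1L) %/% nd + 1L],
    label = 0L, stringsAsFactors = FALSE)
}

#' Rotating train/validation/test fold assignment
#'
#' The positives are shuffled once (seeded) and split into `k` equal
#' held-out blocks.  In fold `f`, block `f` is split half-and-half into
#' validation and test; the remaining blocks are training — at `k = 5` this
#' yields the 80/10/10 split.  Test blocks across folds are pairwise
#' disjoint and the held-out blocks partition all positives.
#'
#' @param positives Data.frame with `drug_id`, `protein_id`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the single shuffle.
#' @return An object of class `fold_assignment` with a `roles` character
#'   matrix (`n_positives x k`, entries `"train"`, `"val"`, `"test"`).
#' @export
make_folds <- function(positives, k = 5, seed = 1) {
  n <- nrow(positives)
  k <- check_count(k, "k", min = 2L)
  if (k > n) stop_config("k exceeds the number of positives")
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  roles <- matrix("train", n, k)
  for (f in seq_len(k)) {
    block <- perm[starts[f]:stops[f]]
    nval <- floor(length(block) / 2)
    if (nval > 0) roles[block[seq_len(nval)], f] <- "val"
    roles[block[(nval + 1):length(block)], f] <- "test"
  }
  structure(list(positives = positives, k = k, seed = seed, roles = roles),
            class = "fold_assignment")
}

#' Flag cold-start test pairs of a fold
#'
#' A test pair is cold-start iff its drug has zero positive training pairs
#' in that fold or its protein has zero positive training pairs in that
#' fold.
#'
#' @param folds A [make_folds()] assignment.
#' @param fold Fold index.
#' @return Logical vector over the positives of that fold's test block,
#'   aligned with `subset(folds$positives, roles[, fold] == "test")`; also
#'   usable through [build_interaction_set()], which applies the same rule
#'   to sampled test negatives.
#' @export
flag_cold_start <- function(folds, fold) {
  stopifnot(inherits(folds, "fold_assignment"))
  role <- folds$roles[, fold]
  train_pos <- folds$positives[role == "train", , drop = FALSE]
  test_pos <- folds$positives[role == "test", , drop = FALSE]
  cold_pair(test_pos, train_pos)
}

cold_pair <- function(pairs, train_pos) {
  !(pairs$drug_id %in% train_pos$drug_id) |
    !(pairs$protein_id %in% train_pos$protein_id)
}

#' Build the labeled interaction set of one fold
#'
#' Combines the fold's positives with freshly sampled negatives (drawn from
#' the complement of the full positive set, per split at the configured
#' ratio) and annotates cold-start status relative to the fold's training
#' positives.
#'
#' @param folds A [make_folds()] assignment.
#' @param fold Fold index.
#' @param drug_ids,protein_ids Full entity id vectors.
#' @param ratio Negatives per positive.
#' @param seed Seed for the fold's negative draw.
#' @return Data.frame with `drug_id`, `protein_id`, `label`, `split`,
#'   `cold_start`; class `interaction_set`.
#' @export
build_interaction_set <- function(folds, fold, drug_ids, protein_ids,
                                  ratio = 1, seed = 1) {
  stopifnot(inherits(folds, "fold_assignment"))
  role <- folds$roles[, fold]
  pos <- folds$positives
  pos$label <- 1L
  pos$split <- role
  counts <- table(factor(role, levels = c("train", "val", "test")))
  need <- floor(ratio * as.numeric(counts))
  negs <- sample_negatives(pos, drug_ids, protein_ids,
                           seed = child_seed(seed, 200 + fold),
                           count = sum(need))
  # Shuffle the draw (it is returned sorted) before carving into splits so
  # each split's negatives are themselves a uniform sample.
  set.seed(child_seed(seed, 300 + fold))
  negs <- negs[sample.int(nrow(negs)), , drop = FALSE]
  negs$split <- rep(c("train", "val", "test"), need)[seq_len(nrow(negs))]
  out <- rbind(pos[, c("drug_id", "protein_id", "label", "split")],
               negs[, c("drug_id", "protein_id", "label", "split")])
  train_pos <- pos[pos$split == "train", , drop = FALSE]
  out$cold_start <- cold_pair(out, train_pos) & out$split == "test"
  rownames(out) <- NULL
  structure(out, class = c("interaction_set", "data.frame"), fold = fold)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0) upd <- upd + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# ---- training -------------------------------------------------------------

interaction_indices <- function(interactions, fb, split) {
  sel <- interactions$split == split
  di <- unname(fb$id_index[interactions$drug_id[sel]])
  pi <- unname(fb$id_index[interactions$protein_id[sel]])
  if (anyNA(di) || anyNA(pi)) {
    stop_input("interaction pairs reference entities absent from the graph")
  }
  list(di = di, pi = pi, y = as.numeric(interactions$label[sel]),
       cold = interactions$cold_start[sel])
}

pair_prior_matrix <- function(fb, di, pi, use_attributes) {
  if (!use_attributes) {
    return(matrix(0, length(di), fb$prior_dim))
  }
  cbind(fb$Fchem[match(di, fb$drug_rows), , drop = FALSE],
        fb$Fseq[match(pi, fb$prot_rows), , drop = FALSE])
}

#' Train the multi-view attention model on one fold
#'
#' Minimizes binary cross-entropy on the training pairs with Adam, early
#' stops on validation AUC (restoring the best parameters), and hard-errors
#' if the graph's known-interaction view contains any validation/test
#' positive (the leakage guard).
#'
#' @param graph A [assemble_multiview_graph()] whose drug-protein view holds
#'   only the fold's training positives (see [set_interaction_view()]).
#' @param interactions An [build_interaction_set()] for the fold.
#' @param config A [train_config()].
#' @return An object of class `mvgat_model` with the learned parameters, the
#'   config snapshot, and a per-epoch training log (`loss`, `val_auc`).
#' @export
train_model <- function(graph, interactions, config = train_config()) {
  stopifnot(inherits(graph, "multiview_graph"),
            inherits(interactions, "interaction_set"))
  dti <- Filter(function(v) v$relation == "drug_protein", graph$views)
  if (length(dti) == 1L) {
    held <- interactions$label == 1L & interactions$split != "train"
    held_keys <- pair_key(interactions$drug_id[held],
                          interactions$protein_id[held])
    view_keys <- c(pair_key(dti[[1]]$edges$src, dti[[1]]$edges$dst),
                   pair_key(dti[[1]]$edges$dst, dti[[1]]$edges$src))
    leaked <- intersect(held_keys, view_keys)
    if (length(leaked)) {
      stop_train(sprintf(
        "leakage guard: %d held-out positive pair(s) present in the known-interaction view",
        length(leaked)))
    }
  }

  cfg <- config
  fb <- build_model_data(graph, cfg)
  if (!cfg$use_attributes) {
    # Attribute ablation: node features and the pair prior carry no
    # information, but shapes are unchanged.
    fb$Xd <- fb$Xd * 0
    fb$Xp <- fb$Xp * 0
  }
  tr <- interaction_indices(interactions, fb, "train")
  va <- interaction_indices(interactions, fb, "val")
  P_tr <- pair_prior_matrix(fb, tr$di, tr$pi, cfg$use_attributes)
  P_va <- pair_prior_matrix(fb, va$di, va$pi, cfg$use_attributes)

  params <- init_params(fb, cfg)
  state <- adam_init(params)
  n_tr <- length(tr$y)
  batches <- if (cfg$batch_size == 0L || cfg$batch_size >= n_tr) {
    list(seq_len(n_tr))
  } else {
    split(seq_len(n_tr), ceiling(seq_len(n_tr) / cfg$batch_size))
  }

  state_mlp <- adam_init(params[grepl("^mlp", names(params))])
  ema <- if (cfg$ema_decay > 0) params
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_auc = numeric(0))
  best <- list(auc = -Inf, params = params, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    epoch_loss <- 0
    for (b in batches) {
      fbk <- forward_backward(params, fb, cfg, tr$di[b], tr$pi[b],
                              P_tr[b, , drop = FALSE], tr$y[b])
      if (!is.finite(fbk$loss)) {
        stop_train(sprintf("non-finite training loss at epoch %d", epoch))
      }
      st <- adam_step(params, fbk$grads, state, cfg$learning_rate,
                      weight_decay = cfg$weight_decay %||% 0)
      params <- st$params
      state <- st$state
      epoch_loss <- epoch_loss + fbk$loss * length(b) / n_tr
    }
    if (cfg$mlp_refine > 0) {
      enc <- encode_forward(params, fb, cfg, keep_caches = FALSE)
      X_tr <- pair_design(enc$z, tr$di, tr$pi, P_tr)
      for (r in seq_len(cfg$mlp_refine)) {
        layers <- mlp_layer_list(params, cfg)
        mf <- mlp_forward(X_tr, layers)
        p_hat <- plogis(mf$out)
        mb <- mlp_backward((p_hat - tr$y) / n_tr, layers, mf$caches)
        g <- list()
        for (l in seq_along(layers)) {
          g[[sprintf("mlp%d_W", l)]] <- mb$grads[[l]]$W
          g[[sprintf("mlp%d_b", l)]] <- mb$grads[[l]]$b
        }
        st <- adam_step(params, g, state_mlp, cfg$learning_rate,
                        weight_decay = cfg$weight_decay %||% 0)
        params <- st$params
        state_mlp <- st$state
      }
    }
    if (!is.null(ema)) {
      dc <- cfg$ema_decay
      for (nm in names(params)) {
        ema[[nm]] <- dc * ema[[nm]] + (1 - dc) * params[[nm]]
      }
    }
    eval_params <- ema %||% params
    val_scores <- score_pairs(eval_params, fb, cfg, va$di, va$pi, P_va)
    val_auc <- roc_auc(va$y, val_scores)
    log <- rbind(log, data.frame(epoch = epoch, loss = epoch_loss,
                                 val_auc = val_auc))
    if (cfg$verbose) {
      message(sprintf("epoch %3d  loss %.4f  val AUC %.4f", epoch,
                      epoch_loss, val_auc))
    }
    if (val_auc > best$auc + 1e-6) {
      best <- list(auc = val_auc, params = eval_params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }

  structure(list(params = best$params, config = cfg,
                 view_names = fb$view_names,
                 entity_table = graph$entities$table,
                 log = log, best_epoch = best$epoch,
                 best_val_auc = best$auc, seed = cfg$seed),
            class = "mvgat_model")
}

#' @export
print.mvgat_model <- function(x, ...) {
  cat(sprintf(
    "mvgat_model: %d views, %d layers, dim %d | best epoch %d (val AUC %.4f)\n",
    length(x$view_names), x$config$n_layers, x$config$embedding_dim,
    x$best_epoch, x$best_val_auc))
  invisible(x)
}

#' Score drug-protein pairs with a trained model
#'
#' @param model A trained `mvgat_model`.
#' @param graph The multi-view graph to encode (normally the training
#'   fold's graph).
#' @param pairs Data.frame with `drug_id`, `protein_id`.
#' @return Numeric vector of interaction scores in (0, 1).
#' @export
predict_interactions <- function(model, graph, pairs) {
  stopifnot(inherits(model, "mvgat_model"))
  cfg <- model$config
  fb <- build_model_data(graph, cfg)
  if (!cfg$use_attributes) {
    fb$Xd <- fb$Xd * 0
    fb$Xp <- fb$Xp * 0
  }
  di <- unname(fb$id_index[pairs$drug_id])
  pi <- unname(fb$id_index[pairs$protein_id])
  if (anyNA(di) || anyNA(pi)) {
    bad <- unique(c(pairs$drug_id[is.na(di)], pairs$protein_id[is.na(pi)]))
    stop_input("unknown entity id(s): ", paste(bad, collapse = ", "))
  }
  P <- pair_prior_matrix(fb, di, pi, cfg$use_attributes)
  score_pairs(model$params, fb, cfg, di, pi, P)
}
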