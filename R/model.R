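# The multi-view attention network.  Per view: a stack of dot-product
# attention message-passing layers, a_ij = softmax_j(Q_i . K_j) over the
# in-neighbourhood (self always included),
# h_i' = ReLU(sum_j a_ij W h_j); per-view embeddings are fused by a learned
# softmax convex combination z = sum_v alpha_v h_v; pair scores are
# sigmoid(MLP([z_drug ; z_target ; f_prior])).  Forward and backward passes
# are written against the edge kernels in src/kernels.cpp; gradients are
# hand-derived and verified against finite differences in the test suite.

#' Attention weights of one node over its neighbours
#'
#' `softmax_j(Q_i . K_j)`: positive weights that sum to 1 over the
#' neighbourhood.
#'
#' @param query Query vector `Q_i`.
#' @param keys Matrix of key vectors `K_j`, one row per neighbour.
#' @param scale Optional logical: divide logits by `sqrt(length(query))`
#'   (transformer-style scaling, off by default).
#' @return Numeric vector of weights, one per row of `keys`.
#' @export
attention_scores <- function(query, keys, scale = FALSE) {
  keys <- rbind(keys)
  if (ncol(keys) != length(query)) stop_input("query/key dimension mismatch")
  logit <- as.numeric(keys %*% query)
  if (scale) logit <- logit / sqrt(length(query))
  .group_softmax(logit, rep(0L, length(logit)), 1L)
}

# ---- single-layer kernels -------------------------------------------------

# Node feature matrices are n x d on the R side; the C++ kernels take them
# transposed (d x n, one contiguous column per node).
edge_dot_nodes <- function(X, Y, ix, iy) .edge_dot_cols(t(X), t(Y), ix, iy)
scatter_nodes <- function(w, X, from, to, nout) {
  t(.scatter_scale_cols(w, t(X), from, to, nout))
}

# edges: list(ei, ej) of 0-based receiver/sender node indices.
layer_forward <- function(H, W, Wq, Wk, edges, use_attention = TRUE,
                          scale = FALSE) {
  n <- nrow(H)
  M <- H %*% W
  if (use_attention) {
    Q <- H %*% Wq
    K <- H %*% Wk
    logit <- edge_dot_nodes(Q, K, edges$ei, edges$ej)
    if (scale) logit <- logit / sqrt(ncol(Q))
  } else {
    Q <- K <- NULL
    logit <- numeric(length(edges$ei))
  }
  a <- .group_softmax(logit, edges$ei, n)
  Z <- scatter_nodes(a, M, edges$ej, edges$ei, n)
  Hout <- Z * (Z > 0)
  list(Hout = Hout, cache = list(H = H, M = M, Q = Q, K = K, a = a, Z = Z))
}

layer_backward <- function(dHout, params, edges, cache, use_attention = TRUE,
                           scale = FALSE) {
  n <- nrow(dHout)
  dZ <- dHout * (cache$Z > 0)
  dM <- scatter_nodes(cache$a, dZ, edges$ei, edges$ej, n)
  dH <- dM %*% t(params$W)
  grads <- list(W = crossprod(cache$H, dM))
  if (use_attention) {
    da <- edge_dot_nodes(dZ, cache$M, edges$ei, edges$ej)
    dlogit <- .group_softmax_backward(cache$a, da, edges$ei, n)
    if (scale) dlogit <- dlogit / sqrt(ncol(cache$Q))
    dQ <- scatter_nodes(dlogit, cache$K, edges$ej, edges$ei, n)
    dK <- scatter_nodes(dlogit, cache$Q, edges$ei, edges$ej, n)
    grads$Wq <- crossprod(cache$H, dQ)
    grads$Wk <- crossprod(cache$H, dK)
    dH <- dH + dQ %*% t(params$Wq) + dK %*% t(params$Wk)
  }
  list(dH = dH, grads = grads)
}

as_edge_list <- function(edges, n, add_self_loops = FALSE) {
  if (is.list(edges) && !is.null(edges$ei)) return(edges)
  edges <- rbind(edges)
  ei <- as.integer(edges[, 1]) - 1L
  ej <- as.integer(edges[, 2]) - 1L
  if (add_self_loops) {
    ei <- c(ei, seq_len(n) - 1L)
    ej <- c(ej, seq_len(n) - 1L)
  }
  o <- order(ei, ej)
  list(ei = ei[o], ej = ej[o])
}

#' One attention message-passing layer
#'
#' `h_i' = ReLU(sum_{j in N(i)} a_ij W h_j)` with
#' `a_ij = softmax_j(Q_i . K_j)`, `Q = h W_q`, `K = h W_k`.  The
#' neighbourhood is exactly the supplied edge set; callers that want the
#' self-inclusion rule (as [encode_views()] uses) set
#' `add_self_loops = TRUE`.
#'
#' @param h Feature matrix, one row per node.
#' @param edges Two-column matrix of (receiver, sender) 1-based node indices.
#' @param W Layer transform matrix.
#' @param Wq,Wk Query/key projection matrices.
#' @param add_self_loops Append an `(i, i)` edge for every node.
#' @param scale Divide attention logits by `sqrt(ncol(Wq))`.
#' @return Updated feature matrix (non-negative entries).
#' @export
message_pass <- function(h, edges, W, Wq, Wk, add_self_loops = FALSE,
                         scale = FALSE) {
  h <- as.matrix(h)
  el <- as_edge_list(edges, nrow(h), add_self_loops)
  layer_forward(h, W, Wq, Wk, el, use_attention = TRUE, scale = scale)$Hout
}

#' One uniform-weight (GCN) message-passing layer
#'
#' Identical to [message_pass()] but with every attention weight fixed to
#' `1/|N(i)|` — the no-attention ablation.  Implemented as the same softmax
#' aggregation path with all logits forced to zero, so forcing equal logits
#' in the attention layer reproduces this variant bit-for-bit.
#'
#' @inheritParams message_pass
#' @return Updated feature matrix.
#' @export
gcn_message_pass <- function(h, edges, W, add_self_loops = FALSE) {
  h <- as.matrix(h)
  el <- as_edge_list(edges, nrow(h), add_self_loops)
  layer_forward(h, W, NULL, NULL, el, use_attention = FALSE)$Hout
}

#' Fuse per-view embeddings with learned softmax weights
#'
#' `z = sum_v alpha_v h_v` with `alpha = softmax(logits)`: a convex
#' combination, so `alpha_v > 0` and `sum alpha = 1` always hold.
#'
#' @param embeddings List of equal-shaped embedding matrices, one per view.
#' @param logits Numeric vector of unconstrained fusion logits (one per
#'   view).
#' @return List with `z` (fused matrix) and `alpha` (the weights).
#' @export
fuse_views <- function(embeddings, logits) {
  stopifnot(length(embeddings) >= 1L, length(logits) == length(embeddings))
  dims <- vapply(embeddings, function(m) paste(dim(m), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1L) {
    stop_input("all views must share the embedding dimension")
  }
  alpha <- as.numeric(.group_softmax(as.numeric(logits),
                                     rep(0L, length(logits)), 1L))
  z <- alpha[1] * embeddings[[1]]
  for (v in seq_along(embeddings)[-1]) z <- z + alpha[v] * embeddings[[v]]
  list(z = z, alpha = alpha)
}

# ---- MLP head -------------------------------------------------------------

mlp_forward <- function(X, layers) {
  caches <- vector("list", length(layers))
  A <- X
  for (m in seq_along(layers)) {
    Zm <- sweep(A %*% layers[[m]]$W, 2, layers[[m]]$b, "+")
    if (m < length(layers)) {
      caches[[m]] <- list(A = A, Z = Zm)
      A <- Zm * (Zm > 0)
    } else {
      caches[[m]] <- list(A = A, Z = Zm)
      A <- Zm
    }
  }
  list(out = as.numeric(A), caches = caches)
}

mlp_backward <- function(dout, layers, caches) {
  grads <- vector("list", length(layers))
  dA <- matrix(dout, ncol = 1)
  for (m in rev(seq_along(layers))) {
    dZ <- if (m < length(layers)) dA * (caches[[m]]$Z > 0) else dA
    grads[[m]] <- list(W = crossprod(caches[[m]]$A, dZ), b = colSums(dZ))
    dA <- dZ %*% t(layers[[m]]$W)
  }
  list(dX = dA, grads = grads)
}

#' Score one drug-target pair
#'
#' `sigmoid(MLP([h_drug ; h_target ; f_prior]))`: a score strictly in
#' (0, 1).
#'
#' @param h_drug,h_target Embedding vectors of the pair.
#' @param prior Pair-level prior vector (may be a zero vector in the
#'   attribute-ablation mode; use `numeric(0)` for a model trained without a
#'   prior block).
#' @param mlp List of layers, each `list(W, b)`; hidden layers use ReLU, the
#'   last layer has a single output unit.
#' @return A number in (0, 1).
#' @export
predict_pair <- function(h_drug, h_target, prior, mlp) {
  x <- matrix(c(h_drug, h_target, prior), nrow = 1)
  if (nrow(mlp[[1]]$W) != ncol(x)) {
    stop_input(sprintf("MLP expects input of dimension %d, got %d",
                       nrow(mlp[[1]]$W), ncol(x)))
  }
  plogis(mlp_forward(x, mlp)$out)
}

# ---- parameter initialisation --------------------------------------------

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -r, r), nin, nout)
}

init_params <- function(fb, cfg) {
  set.seed(child_seed(cfg$seed, 100))
  d <- cfg$embedding_dim
  da <- cfg$attention_dim
  p <- list(
    proj_drug_W = glorot(ncol(fb$Xd), d), proj_drug_b = numeric(d),
    proj_prot_W = glorot(ncol(fb$Xp), d), proj_prot_b = numeric(d),
    # Free identity embeddings for every node (id-keyed, so a relabeled
    # graph still maps each entity to its own row); the attribute
    # projections are added on top.  These let the encoder learn
    # collaborative structure from the interaction/association views (and
    # are all the attribute-ablated variant has to work with), while
    # cold-start signal flows through the attribute projections.
    emb_node = matrix(rnorm(fb$n * d, sd = 0.1), fb$n, d,
                      dimnames = list(fb$ids, NULL))
  )
  for (v in seq_along(fb$views)) {
    for (l in seq_len(cfg$n_layers)) {
      p[[sprintf("v%02d_l%d_W", v, l)]] <- glorot(d, d)
      p[[sprintf("v%02d_l%d_Wq", v, l)]] <- glorot(d, da)
      p[[sprintf("v%02d_l%d_Wk", v, l)]] <- glorot(d, da)
    }
  }
  p$fusion_logits <- numeric(length(fb$views))
  in_dim <- 2 * d + fb$prior_dim
  dims <- c(in_dim, rep(cfg$mlp_hidden, cfg$mlp_layers - 1), 1L)
  for (m in seq_len(cfg$mlp_layers)) {
    p[[sprintf("mlp%d_W", m)]] <- glorot(dims[m], dims[m + 1])
    p[[sprintf("mlp%d_b", m)]] <- numeric(dims[m + 1])
  }
  p
}

mlp_layer_list <- function(params, cfg) {
  lapply(seq_len(cfg$mlp_layers), function(m) {
    list(W = params[[sprintf("mlp%d_W", m)]],
         b = params[[sprintf("mlp%d_b", m)]])
  })
}

# ---- model data (graph compiled for the numeric passes) -------------------

standardize_cols <- function(m) {
  mu <- colMeans(m)
  s <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
  s[s < 1e-12] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

build_model_data <- function(graph, cfg) {
  stopifnot(inherits(graph, "multiview_graph"))
  tab <- graph$entities$table
  n <- nrow(tab)
  drug_rows <- which(tab$kind == "drug")
  prot_rows <- which(tab$kind == "protein")
  dis_rows <- which(tab$kind == "disease")
  idx <- seq_len(n)
  names(idx) <- tab$id

  views <- lapply(graph$views, function(v) {
    ei <- idx[v$edges$src]
    ej <- idx[v$edges$dst]
    # receiver = src row, sender = dst row; storage is symmetric so both
    # directions are present.  Self-loops for every node keep isolated nodes
    # defined and the softmax non-degenerate.
    as_edge_list(cbind(unname(ei), unname(ej)), n, add_self_loops = TRUE)
  })

  Fchem <- graph$features$f_chem[tab$id[drug_rows], , drop = FALSE]
  Fseq <- graph$features$f_seq[tab$id[prot_rows], , drop = FALSE]
  if (isTRUE(cfg$standardize_features %||% TRUE)) {
    # Column standardization keeps the 0/1 fingerprint block and the
    # small-valued k-mer frequency block on comparable scales; it is a
    # label-free transform recomputed deterministically from the graph.
    Fchem <- standardize_cols(Fchem)
    Fseq <- standardize_cols(Fseq)
  }
  list(
    n = n, n_dis = length(dis_rows), ids = tab$id,
    drug_rows = drug_rows, prot_rows = prot_rows, dis_rows = dis_rows,
    id_index = idx, view_names = names(graph$views), views = views,
    Xd = Fchem, Xp = Fseq, Fchem = Fchem, Fseq = Fseq,
    prior_dim = ncol(Fchem) + ncol(Fseq)
  )
}

# ---- full forward / backward ---------------------------------------------

encode_forward <- function(params, fb, cfg, keep_caches = TRUE) {
  n <- fb$n
  d <- cfg$embedding_dim
  H0 <- params$emb_node
  if (!is.null(rownames(H0))) H0 <- unname(H0[fb$ids, , drop = FALSE])
  H0[fb$drug_rows, ] <- H0[fb$drug_rows, ] +
    sweep(fb$Xd %*% params$proj_drug_W, 2, params$proj_drug_b, "+")
  H0[fb$prot_rows, ] <- H0[fb$prot_rows, ] +
    sweep(fb$Xp %*% params$proj_prot_W, 2, params$proj_prot_b, "+")

  hv <- vector("list", length(fb$views))
  caches <- if (keep_caches) vector("list", length(fb$views))
  for (v in seq_along(fb$views)) {
    H <- H0
    vc <- if (keep_caches) vector("list", cfg$n_layers)
    for (l in seq_len(cfg$n_layers)) {
      lf <- layer_forward(H,
                          params[[sprintf("v%02d_l%d_W", v, l)]],
                          params[[sprintf("v%02d_l%d_Wq", v, l)]],
                          params[[sprintf("v%02d_l%d_Wk", v, l)]],
                          fb$views[[v]],
                          use_attention = cfg$use_attention,
                          scale = cfg$scale_attention)
      if (keep_caches) vc[[l]] <- lf$cache
      H <- lf$Hout
    }
    hv[[v]] <- H
    if (keep_caches) caches[[v]] <- vc
  }
  fz <- fuse_views(hv, params$fusion_logits)
  list(H0 = H0, hv = hv, caches = caches, z = fz$z, alpha = fz$alpha)
}

encode_backward <- function(dZfused, dalpha_extra = NULL, enc, params, fb,
                            cfg) {
  grads <- list()
  V <- length(fb$views)
  # fusion backward
  dalpha <- vapply(seq_len(V), function(v) sum(dZfused * enc$hv[[v]]),
                   numeric(1))
  a <- enc$alpha
  grads$fusion_logits <- a * (dalpha - sum(a * dalpha))
  dH0 <- matrix(0, fb$n, cfg$embedding_dim)
  for (v in seq_len(V)) {
    dH <- a[v] * dZfused
    for (l in rev(seq_len(cfg$n_layers))) {
      nm <- sprintf("v%02d_l%d_", v, l)
      lb <- layer_backward(
        dH,
        list(W = params[[paste0(nm, "W")]],
             Wq = params[[paste0(nm, "Wq")]],
             Wk = params[[paste0(nm, "Wk")]]),
        fb$views[[v]], enc$caches[[v]][[l]],
        use_attention = cfg$use_attention, scale = cfg$scale_attention)
      grads[[paste0(nm, "W")]] <- lb$grads$W
      if (cfg$use_attention) {
        grads[[paste0(nm, "Wq")]] <- lb$grads$Wq
        grads[[paste0(nm, "Wk")]] <- lb$grads$Wk
      }
      dH <- lb$dH
    }
    dH0 <- dH0 + dH
  }
  grads$proj_drug_W <- crossprod(fb$Xd, dH0[fb$drug_rows, , drop = FALSE])
  grads$proj_drug_b <- colSums(dH0[fb$drug_rows, , drop = FALSE])
  grads$proj_prot_W <- crossprod(fb$Xp, dH0[fb$prot_rows, , drop = FALSE])
  grads$proj_prot_b <- colSums(dH0[fb$prot_rows, , drop = FALSE])
  grads$emb_node <- dH0
  grads
}

pair_design <- function(z, di, pi, prior) {
  cbind(z[di, , drop = FALSE], z[pi, , drop = FALSE], prior)
}

# Loss + gradients for one set of labeled pairs (full batch).
forward_backward <- function(params, fb, cfg, di, pi, prior, y) {
  enc <- encode_forward(params, fb, cfg, keep_caches = TRUE)
  X <- pair_design(enc$z, di, pi, prior)
  layers <- mlp_layer_list(params, cfg)
  mf <- mlp_forward(X, layers)
  p <- plogis(mf$out)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))

  m <- length(y)
  dout <- (p - y) / m                       # d loss / d logit (sigmoid+BCE)
  mb <- mlp_backward(dout, layers, mf$caches)
  grads <- list()
  for (l in seq_along(layers)) {
    grads[[sprintf("mlp%d_W", l)]] <- mb$grads[[l]]$W
    grads[[sprintf("mlp%d_b", l)]] <- mb$grads[[l]]$b
  }
  d <- cfg$embedding_dim
  ones <- rep(1, m)
  dZf <- scatter_nodes(ones, mb$dX[, 1:d, drop = FALSE],
                       seq_len(m) - 1L, di - 1L, fb$n) +
    scatter_nodes(ones, mb$dX[, (d + 1):(2 * d), drop = FALSE],
                  seq_len(m) - 1L, pi - 1L, fb$n)
  grads <- c(grads, encode_backward(dZf, NULL, enc, params, fb, cfg))
  list(loss = loss, grads = grads, scores = p)
}

score_pairs <- function(params, fb, cfg, di, pi, prior, enc = NULL) {
  if (is.null(enc)) enc <- encode_forward(params, fb, cfg,
                                          keep_caches = FALSE)
  X <- pair_design(enc$z, di, pi, prior)
  plogis(mlp_forward(X, mlp_layer_list(params, cfg))$out)
}

#' Per-view node embeddings of a trained model
#'
#' Runs the configured number of attention layers on every view with that
#' view's parameters and returns one embedding matrix per view (rows named
#' by entity id), plus the fused embedding and the learned view weights.
#'
#' @param graph The [assemble_multiview_graph()] the model was trained on
#'   (or a compatible one).
#' @param model A trained `mvgat_model`.
#' @return List with `per_view` (list of matrices), `fused`, `alpha`.
#' @export
encode_views <- function(graph, model) {
  stopifnot(inherits(model, "mvgat_model"))
  fb <- build_model_data(graph, model$config)
  if (length(fb$views) != length(model$params$fusion_logits)) {
    stop_config("view count does not match the trained model")
  }
  enc <- encode_forward(model$params, fb, model$config, keep_caches = FALSE)
  ids <- graph$entities$table$id
  per_view <- lapply(enc$hv, function(h) { rownames(h) <- ids; h })
  names(per_view) <- fb$view_names
  fused <- enc$z
  rownames(fused) <- ids
  list(per_view = per_view, fused = fused, alpha = enc$alpha)
}
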