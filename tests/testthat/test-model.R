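test_that("attention weights are a softmax over neighbour logits", {
  expect_equal(attention_scores(1, matrix(1, 1, 1)), 1.0)
  expect_equal(attention_scores(c(1, 1), matrix(1, 4, 2) / 2),
               rep(0.25, 4))
  # logits (0, ln 3) -> (0.25, 0.75)
  expect_equal(attention_scores(1, matrix(c(0, log(3)), 2, 1)),
               c(0.25, 0.75))
  expect_error(attention_scores(c(1, 2), matrix(1, 2, 3)),
               class = "mvgat_input_error")
})

test_that("message passing reproduces hand-computed updates", {
  # all-zero features stay zero
  W <- diag(3)
  Wq <- Wk <- matrix(0.5, 3, 2)
  edges <- rbind(c(1, 2), c(2, 1))
  expect_equal(message_pass(matrix(0, 2, 3), edges, W, Wq, Wk),
               matrix(0, 2, 3))

  # single neighbour, attention weight 1, identity W: output = h_j
  h <- rbind(c(0, 0), c(2, 3))
  out <- message_pass(h, rbind(c(1, 2)), diag(2), matrix(0, 2, 1),
                      matrix(0, 2, 1))
  expect_equal(out[1, ], c(2, 3))

  # engineered logits (0, ln 3) over neighbours (4,0) and (0,4):
  # 0.25*(4,0) + 0.75*(0,4) = (1,3)
  H <- rbind(c(1, 1), c(4, 0), c(0, 4))
  Wq2 <- matrix(c(1, 0), 2, 1)
  Wk2 <- matrix(c(0, log(3) / 4), 2, 1)
  out2 <- message_pass(H, rbind(c(1, 2), c(1, 3)), diag(2), Wq2, Wk2)
  expect_equal(out2[1, ], c(1, 3))

  # ReLU clips negative pre-activations
  out3 <- message_pass(rbind(c(0, 0), c(-5, 2)), rbind(c(1, 2)), diag(2),
                       matrix(0, 2, 1), matrix(0, 2, 1))
  expect_equal(out3[1, ], c(0, 2))
})

test_that("uniform-weight GCN layer equals mean aggregation", {
  # single neighbour: identical to the attention layer
  h <- rbind(c(1, 2), c(3, 4))
  e <- rbind(c(1, 2))
  expect_identical(gcn_message_pass(h, e, diag(2)),
                   message_pass(h, e, diag(2), matrix(0, 2, 1),
                                matrix(0, 2, 1)))

  # 4-neighbour toy node with identity W: ReLU of the neighbour mean
  h4 <- rbind(c(0, 0), c(4, 0), c(0, 4), c(2, 2), c(-2, 6))
  e4 <- cbind(1, 2:5)
  out <- gcn_message_pass(h4, e4, diag(2))
  expect_equal(out[1, ], pmax(colMeans(h4[2:5, ]), 0))
})

random_graph <- function(n, d, n_edges, seed) {
  set.seed(seed)
  edges <- unique(cbind(sample(n, n_edges, replace = TRUE),
                        sample(n, n_edges, replace = TRUE)))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- rbind(edges, cbind(1:n, 1:n))  # self-loops keep groups non-empty
  list(h = matrix(rnorm(n * d), n), edges = edges)
}

test_that("zero attention logits reproduce the GCN bit-for-bit", {
  for (seed in 1:5) {
    g <- random_graph(20, 6, 60, seed)
    W <- matrix(rnorm(36), 6)
    # forcing all logits equal by zeroing the query projection
    att <- message_pass(g$h, g$edges, W, matrix(0, 6, 3),
                        matrix(rnorm(18), 6))
    gcn <- gcn_message_pass(g$h, g$edges, W)
    expect_identical(att, gcn)
  }
})

test_that("attention rows are normalized and embeddings non-negative", {
  w <- tiny_world(seed = 4)
  graph <- assemble_multiview_graph(w$entities, w$views, kmer_k = 1)
  cfg <- fast_train_config()
  fb <- mvgat:::build_model_data(graph, cfg)
  params <- mvgat:::init_params(fb, cfg)
  enc <- mvgat:::encode_forward(params, fb, cfg, keep_caches = TRUE)
  for (v in seq_along(fb$views)) {
    for (l in seq_len(cfg$n_layers)) {
      a <- enc$caches[[v]][[l]]$a
      sums <- tapply(a, fb$views[[v]]$ei, sum)
      expect_equal(as.numeric(sums), rep(1, length(sums)),
                   tolerance = 1e-12)
    }
    expect_true(all(enc$hv[[v]] >= 0))
  }
  expect_equal(sum(enc$alpha), 1)
})

test_that("view fusion is a convex combination", {
  h1 <- matrix(c(2, 0), 1)
  h2 <- matrix(c(0, 2), 1)
  # one view: z = h regardless of logit
  expect_equal(fuse_views(list(h1), logits = 5)$z, h1)
  # identical embeddings: fused equals them for any logits
  fz <- fuse_views(list(h1, h1, h1), logits = c(-3, 0, 7))
  expect_equal(fz$z, h1)
  expect_equal(sum(fz$alpha), 1)
  # equal logits: z = (1, 1)
  expect_equal(fuse_views(list(h1, h2), logits = c(0.4, 0.4))$z,
               matrix(c(1, 1), 1))
  expect_error(fuse_views(list(h1, matrix(0, 2, 2)), c(0, 0)),
               class = "mvgat_input_error")
})

test_that("pair scores are sigmoid MLP outputs", {
  mlp <- list(list(W = matrix(0, 6, 4), b = numeric(4)),
              list(W = matrix(0, 4, 1), b = 0))
  expect_equal(predict_pair(c(1, 2), c(3, 4), c(1, 0), mlp), 0.5)
  set.seed(1)
  mlp2 <- list(list(W = matrix(rnorm(24), 6), b = rnorm(4)),
               list(W = matrix(rnorm(4)), b = rnorm(1)))
  s <- predict_pair(c(1, 2), c(3, 4), c(1, 0), mlp2)
  expect_gt(s, 0)
  expect_lt(s, 1)
  expect_identical(s, predict_pair(c(1, 2), c(3, 4), c(1, 0), mlp2))
  expect_error(predict_pair(c(1, 2), c(3, 4), c(1, 0, 0), mlp2),
               class = "mvgat_input_error")
})

test_that("analytic gradients match finite differences", {
  cfg <- train_config(embedding_dim = 5, attention_dim = 3, n_layers = 2,
                      mlp_layers = 2, mlp_hidden = 4, seed = 3)
  w <- tiny_world(seed = 2, n_drugs = 8, n_proteins = 7, n_diseases = 3,
                  fingerprint_bits = 10)
  graph <- assemble_multiview_graph(w$entities, w$views, kmer_k = 1)
  fb <- mvgat:::build_model_data(graph, cfg)
  params <- mvgat:::init_params(fb, cfg)
  set.seed(9)
  di <- sample(fb$drug_rows, 12, replace = TRUE)
  pi <- sample(fb$prot_rows, 12, replace = TRUE)
  P <- mvgat:::pair_prior_matrix(fb, di, pi, TRUE)
  y <- rbinom(12, 1, 0.5)
  fbk <- mvgat:::forward_backward(params, fb, cfg, di, pi, P, y)
  lossfn <- function(p) mvgat:::forward_backward(p, fb, cfg, di, pi, P,
                                                 y)$loss
  eps <- 1e-6
  for (nm in names(fbk$grads)) {
    g <- fbk$grads[[nm]]
    for (i in sample(length(g), min(3, length(g)))) {
      p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      num <- (lossfn(p_hi) - lossfn(p_lo)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4, info = nm)
    }
  }
})

test_that("pair scores are invariant to consistent node relabeling", {
  w <- tiny_world(seed = 6, n_drugs = 5, n_proteins = 4, n_diseases = 1,
                  n_views = 3)
  graph <- assemble_multiview_graph(w$entities, w$views, kmer_k = 1)
  cfg <- fast_train_config(max_epochs = 4)
  tab <- graph$entities$table
  folds <- make_folds(w$positives, 2, seed = 1)
  iset <- build_interaction_set(folds, 1, tab$id[tab$kind == "drug"],
                                tab$id[tab$kind == "protein"], seed = 1)
  gf <- set_interaction_view(graph,
                             folds$positives[folds$roles[, 1] == "train", ])
  model <- train_model(gf, iset, cfg)
  pairs <- iset[iset$split == "test", c("drug_id", "protein_id")]
  base <- predict_interactions(model, gf, pairs)

  # permute the entity table (and nothing else: edges/features are id-keyed)
  set.seed(8)
  perm <- sample(nrow(tab))
  ent2 <- entity_set(tab$id[perm], tab$kind[perm],
                     fingerprints = gf$entities$fingerprints,
                     sequences = gf$entities$sequences)
  gf2 <- assemble_multiview_graph(ent2, gf$views, kmer_k = 1)
  permuted <- predict_interactions(model, gf2, pairs)
  expect_equal(permuted, base, tolerance = 1e-9)
})

test_that("models reproduce scores after a serialization round trip", {
  w <- tiny_world(seed = 7)
  graph <- assemble_multiview_graph(w$entities, w$views, kmer_k = 1)
  tab <- graph$entities$table
  folds <- make_folds(w$positives, 2, seed = 2)
  iset <- build_interaction_set(folds, 1, tab$id[tab$kind == "drug"],
                                tab$id[tab$kind == "protein"], seed = 2)
  gf <- set_interaction_view(graph,
                             folds$positives[folds$roles[, 1] == "train", ])
  model <- train_model(gf, iset, fast_train_config(max_epochs = 5))
  pairs <- iset[iset$split == "test", ]
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, path)
  expect_identical(predict_interactions(readRDS(path), gf, pairs),
                   predict_interactions(model, gf, pairs))
})
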