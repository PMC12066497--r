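# Shared fixtures (all generated in code) and independent oracles.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_drugs = 15, n_proteins = 12, n_diseases = 5, n_views = 5,
               latent_dim = 4, interaction_bias = -1, fingerprint_bits = 16,
               sequence_length = 30, similarity_k = 3, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

tiny_world <- function(seed = 1, ...) generate_world(tiny_config(seed, ...))

fast_train_config <- function(seed = 1, ...) {
  args <- list(embedding_dim = 8, attention_dim = 4, mlp_hidden = 8,
               max_epochs = 8, patience = 8, seed = seed)
  do.call(train_config, utils::modifyList(args, list(...)))
}

# Brute-force Mann-Whitney AUC: enumerate all positive-negative pairs,
# counting ties as 1/2.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold-sweep PR AUC with step-wise precision.
pr_oracle <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  recall_prev <- 0
  area <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    recall <- tp / n_pos
    precision <- tp / (tp + fp)
    area <- area + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  area
}

# Full dynamic-programming Smith-Waterman with affine gaps, matching the
# convention that a gap of length L costs gap_opening + L * gap_extension.
sw_oracle <- function(a, b, submat, gap_opening = 10, gap_extension = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  open_cost <- gap_opening + gap_extension
  M <- Ix <- Iy <- matrix(0, n + 1, m + 1)
  Ix[] <- Iy[] <- -Inf
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open_cost,
                              Ix[i, j + 1] - gap_extension)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open_cost,
                              Iy[i + 1, j] - gap_extension)
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) +
                                  submat[av[i], bv[j]])
      best <- max(best, M[i + 1, j + 1], Ix[i + 1, j + 1], Iy[i + 1, j + 1])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

sw_similarity_oracle <- function(a, b) {
  s_ab <- sw_oracle(a, b, blosum62)
  s_ab / sqrt(sw_oracle(a, a, blosum62) * sw_oracle(b, b, blosum62))
}

random_labeled_scores <- function(n, tie_prob = 0.3) {
  labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
  scores <- if (runif(1) < tie_prob) {
    sample(seq(0, 1, by = 0.25), n, replace = TRUE)
  } else {
    runif(n)
  }
  list(labels = labels, scores = scores)
}
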