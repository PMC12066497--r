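# Synthetic multi-relational drug-gene-disease worlds with planted
# latent-factor interactions.  Every entity carries a latent vector; the true
# interaction probability of a (drug, protein) pair is
# plogis(u_d . v_p + interaction_bias), and all similarity views, attributes
# and sequences are noisy functions of the same latents, so downstream stages
# have a recoverable signal whose strength is controlled by the config.

#' Configuration for the synthetic network generator
#'
#' Defaults describe the study conditions used throughout the package: a
#' sparse interaction matrix (unit-normal latent factors, `interaction_bias`
#' of -5 gives roughly 6\% positive density), 15 relation views, mildly noisy
#' similarity graphs, and drug/protein attributes that are strongly but not
#' perfectly coupled to the latent factors.
#'
#' @param n_drugs,n_proteins,n_diseases Entity counts (all >= 1).
#' @param latent_dim Dimension of the planted latent factors.
#' @param n_views Total number of relation views to emit (default 15,
#'   partitioned across drug-drug, protein-protein, drug-disease,
#'   protein-disease similarity/association views plus one known-interaction
#'   view; see [generate_views()]).
#' @param interaction_bias Additive bias on the pair logit; more negative
#'   means sparser positives.
#' @param view_noise_sd Standard deviation of the Gaussian noise added to
#'   similarity weights (>= 0).
#' @param attribute_informativeness In \[0, 1\]: 0 makes fingerprints and
#'   sequences independent of the latents, 1 makes them deterministic
#'   functions of the latents.
#' @param fingerprint_bits Length of the binary drug fingerprints.
#' @param sequence_length Length of the sampled protein sequences.
#' @param noise_views Number of drug-drug similarity views generated from
#'   fresh random latents (pure noise); used by the ablation analyses.
#' @param edge_noise_frac Fraction of spurious edges injected into every
#'   similarity view: for a view with `m` true edges,
#'   `round(edge_noise_frac * m)` uniformly random extra pairs are added
#'   with weights resampled from the view's own weight distribution.
#'   Emulates the unreliable connections of curated interaction databases;
#'   used by the attention-vs-uniform ablation.
#' @param orthogonal_latents If `TRUE`, drug and protein latents live in
#'   disjoint coordinate blocks so every pair logit is exactly
#'   `interaction_bias` (a null world with no pair-level signal).
#' @param association_bias Bias of the drug-disease / protein-disease
#'   association logits.
#' @param similarity_k Neighbourhood size for mutual top-k sparsification of
#'   similarity views.
#' @param seed Integer master seed; all sub-generators derive child seeds
#'   from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 100, n_proteins = 100, n_diseases = 30,
                             latent_dim = 8, n_views = 15,
                             interaction_bias = -5, view_noise_sd = 0.1,
                             attribute_informativeness = 0.8,
                             fingerprint_bits = 64, sequence_length = 150,
                             noise_views = 0, edge_noise_frac = 0,
                             orthogonal_latents = FALSE,
                             association_bias = -2.5, similarity_k = 10,
                             seed = 1) {
  cfg <- list(
    n_drugs = check_count(n_drugs, "n_drugs"),
    n_proteins = check_count(n_proteins, "n_proteins"),
    n_diseases = check_count(n_diseases, "n_diseases", min = 0L),
    latent_dim = check_count(latent_dim, "latent_dim"),
    n_views = check_count(n_views, "n_views"),
    interaction_bias = check_real(interaction_bias, "interaction_bias"),
    view_noise_sd = check_real(view_noise_sd, "view_noise_sd", lower = 0),
    attribute_informativeness = check_real(attribute_informativeness,
                                           "attribute_informativeness", 0, 1),
    fingerprint_bits = check_count(fingerprint_bits, "fingerprint_bits"),
    sequence_length = check_count(sequence_length, "sequence_length"),
    noise_views = check_count(noise_views, "noise_views", min = 0L),
    edge_noise_frac = check_real(edge_noise_frac, "edge_noise_frac", 0, 10),
    orthogonal_latents = isTRUE(orthogonal_latents),
    association_bias = check_real(association_bias, "association_bias"),
    similarity_k = check_count(similarity_k, "similarity_k"),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "synthetic_config")
}

entity_ids <- function(prefix, n) {
  sprintf("%s_%0*d", prefix, max(3L, nchar(n)), seq_len(n))
}

latent_matrix <- function(n, dim, ids) {
  m <- matrix(rnorm(n * dim), nrow = n, ncol = dim)
  rownames(m) <- ids
  m
}

#' Generate entities, latent factors and attributes
#'
#' Drugs receive a binary fingerprint obtained by thresholding at zero a fixed
#' random projection of `a * latent + (1 - a) * independent noise` where `a`
#' is `attribute_informativeness`; proteins receive a residue sequence sampled
#' from latent-biased residue frequencies (softmax over per-residue loadings
#' of the same blend); diseases carry latents only.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_world` list with `config`, `entities` (an
#'   [entity_set()]), and `latents` (matrices `drug`, `protein`, `disease`).
#' @export
generate_entities <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- config$latent_dim
  a <- config$attribute_informativeness
  d_ids <- entity_ids("drug", config$n_drugs)
  p_ids <- entity_ids("protein", config$n_proteins)
  s_ids <- if (config$n_diseases > 0) entity_ids("disease", config$n_diseases)

  set.seed(child_seed(config$seed, 1))
  U <- latent_matrix(config$n_drugs, L, d_ids)
  V <- latent_matrix(config$n_proteins, L, p_ids)
  C <- if (config$n_diseases > 0) {
    latent_matrix(config$n_diseases, L, s_ids)
  } else {
    matrix(0, 0, L)
  }
  if (config$orthogonal_latents) {
    # Drugs occupy the first block of coordinates, proteins the second, so
    # u . v = 0 exactly for every pair: no planted pair-level signal.
    half <- ceiling(L / 2)
    if (half >= L) stop_config("orthogonal_latents requires latent_dim >= 2")
    U[, (half + 1):L] <- 0
    V[, 1:half] <- 0
  }

  set.seed(child_seed(config$seed, 2))
  proj <- matrix(rnorm(L * config$fingerprint_bits), L)
  eps <- matrix(rnorm(config$n_drugs * L), config$n_drugs)
  blend <- a * U + (1 - a) * eps
  fingerprints <- (blend %*% proj > 0) + 0L
  rownames(fingerprints) <- d_ids

  set.seed(child_seed(config$seed, 3))
  loadings <- matrix(rnorm(L * 20), L, 20)
  eta <- matrix(rnorm(config$n_proteins * L), config$n_proteins)
  res_logit <- (a * V + (1 - a) * eta) %*% loadings
  res_prob <- exp(res_logit - apply(res_logit, 1, max))
  res_prob <- res_prob / rowSums(res_prob)
  alphabet <- aa_alphabet()
  sequences <- vapply(seq_len(config$n_proteins), function(i) {
    paste(sample(alphabet, config$sequence_length, replace = TRUE,
                 prob = res_prob[i, ]), collapse = "")
  }, character(1))
  names(sequences) <- p_ids

  entities <- entity_set(
    ids = c(d_ids, p_ids, s_ids),
    kinds = c(rep("drug", config$n_drugs),
              rep("protein", config$n_proteins),
              rep("disease", config$n_diseases)),
    fingerprints = fingerprints,
    sequences = sequences
  )
  structure(list(config = config, entities = entities,
                 latents = list(drug = U, protein = V, disease = C)),
            class = "synthetic_world")
}

#' Sample the positive drug-protein interaction set
#'
#' Pair `(d, p)` is positive with probability
#' `plogis(u_d . v_p + interaction_bias)`.  The true probability matrix is
#' recorded on the world for calibration analyses.
#'
#' @param world A `synthetic_world` from [generate_entities()].
#' @param config The same [synthetic_config()] (defaults to `world$config`).
#' @return The world, with `positives` (a data.frame of `drug_id`,
#'   `protein_id`) and `true_prob` added.
#' @export
generate_interactions <- function(world, config = world$config) {
  stopifnot(inherits(world, "synthetic_world"))
  U <- world$latents$drug
  V <- world$latents$protein
  prob <- plogis(U %*% t(V) + config$interaction_bias)
  set.seed(child_seed(config$seed, 4))
  hit <- matrix(runif(length(prob)), nrow = nrow(prob)) < prob
  idx <- which(hit, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  world$positives <- data.frame(
    drug_id = rownames(U)[idx[, 1]],
    protein_id = rownames(V)[idx[, 2]],
    stringsAsFactors = FALSE
  )
  world$true_prob <- prob
  world
}

# Largest-remainder split of the non-interaction views across the four
# similarity/association kinds in the documented 4:4:3:3 default ratio; the
# known-interaction view always takes one slot.
view_partition <- function(n_views) {
  if (n_views < 3) {
    stop_config("n_views must be at least 3 ",
                "(drug-drug, protein-protein and interaction views)")
  }
  rest <- n_views - 1L
  w <- c(dd = 4, pp = 4, ddis = 3, pdis = 3) / 14
  raw <- w * rest
  base <- floor(raw)
  rem <- rest - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  # Guarantee at least one drug-drug and one protein-protein view.
  for (need in c("dd", "pp")) {
    if (base[need] == 0) {
      donor <- names(which.max(base[setdiff(names(base), need)]))
      base[donor] <- base[donor] - 1L
      base[need] <- 1L
    }
  }
  c(as.list(base), list(dti = 1L))
}

cosine_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  s <- (m / nrm) %*% t(m / nrm)
  diag(s) <- 1
  s
}

symmetric_noise <- function(n, sd) {
  if (sd == 0) return(matrix(0, n, n))
  e <- matrix(rnorm(n * n, sd = sd), n, n)
  e[lower.tri(e)] <- t(e)[lower.tri(e)]
  diag(e) <- 0
  e
}

similarity_view_from_latents <- function(lat, ids, noise_sd, k, name,
                                         relation, edge_noise_frac = 0) {
  s <- cosine_rows(lat) + symmetric_noise(nrow(lat), noise_sd)
  rownames(s) <- colnames(s) <- ids
  view <- build_similarity_view_matrix(s, k = min(k, length(ids) - 1L),
                                       name = name, relation = relation)
  if (edge_noise_frac > 0 && nrow(view$edges) > 0) {
    m <- round(edge_noise_frac * nrow(view$edges) / 2)
    i <- sample(length(ids), m, replace = TRUE)
    j <- sample(length(ids), m, replace = TRUE)
    keep <- i != j
    spurious <- data.frame(
      src = ids[i[keep]], dst = ids[j[keep]],
      weight = sample(view$edges$weight, sum(keep), replace = TRUE),
      stringsAsFactors = FALSE)
    all_edges <- rbind(view$edges[view$edges$src < view$edges$dst,
                                  c("src", "dst", "weight")], spurious)
    view <- view_graph(name = name, relation = relation, edges = all_edges)
  }
  view
}

association_view <- function(lat_a, lat_b, ids_a, ids_b, bias, name,
                             relation) {
  prob <- plogis(lat_a %*% t(lat_b) + bias)
  hit <- matrix(runif(length(prob)), nrow = nrow(prob)) < prob
  idx <- which(hit, arr.ind = TRUE)
  edges <- data.frame(src = ids_a[idx[, 1]], dst = ids_b[idx[, 2]],
                      weight = 1, stringsAsFactors = FALSE)
  view_graph(name = name, relation = relation, edges = edges)
}

#' Generate the relation views of a synthetic world
#'
#' Emits `n_views` views partitioned across drug-drug similarity,
#' protein-protein similarity, drug-disease association, protein-disease
#' association, and one drug-protein known-interaction view.  Similarity
#' weights are the cosine of the entity latents plus Gaussian noise,
#' sparsified by mutual top-k.  The interaction view is built from
#' `train_pairs` when supplied (never from held-out pairs); by default it
#' uses all positives, which is only appropriate before any fold has been
#' designated.
#'
#' @param world A `synthetic_world` with positives generated.
#' @param config The [synthetic_config()] (defaults to `world$config`).
#' @param train_pairs Optional data.frame (`drug_id`, `protein_id`) of
#'   training positives for the interaction view.
#' @return Named list of [view_graph()] objects, in recorded view order.
#' @export
generate_views <- function(world, config = world$config, train_pairs = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  if (is.null(world$positives)) {
    stop_config("generate_interactions() must be run before generate_views()")
  }
  part <- view_partition(config$n_views)
  if (config$n_diseases == 0 && (part$ddis > 0 || part$pdis > 0)) {
    part$dd <- part$dd + part$ddis
    part$pp <- part$pp + part$pdis
    part$ddis <- part$pdis <- 0L
  }
  if (config$noise_views > part$dd) {
    stop_config(sprintf(
      "noise_views (%d) exceeds the number of drug-drug views (%d)",
      config$noise_views, part$dd))
  }
  ent <- world$entities$table
  d_ids <- ent$id[ent$kind == "drug"]
  p_ids <- ent$id[ent$kind == "protein"]
  s_ids <- ent$id[ent$kind == "disease"]
  views <- list()
  vi <- 0L

  for (i in seq_len(part$dd)) {
    vi <- vi + 1L
    set.seed(child_seed(config$seed, 10 + vi))
    lat <- if (i <= config$noise_views) {
      matrix(rnorm(length(d_ids) * config$latent_dim), length(d_ids))
    } else {
      world$latents$drug
    }
    nm <- sprintf("%02d_drug_sim_%d%s", vi, i,
                  if (i <= config$noise_views) "_noise" else "")
    views[[nm]] <- similarity_view_from_latents(
      lat, d_ids, config$view_noise_sd, config$similarity_k, nm, "drug_drug",
      edge_noise_frac = config$edge_noise_frac)
  }
  for (i in seq_len(part$pp)) {
    vi <- vi + 1L
    set.seed(child_seed(config$seed, 10 + vi))
    nm <- sprintf("%02d_protein_sim_%d", vi, i)
    views[[nm]] <- similarity_view_from_latents(
      world$latents$protein, p_ids, config$view_noise_sd,
      config$similarity_k, nm, "protein_protein",
      edge_noise_frac = config$edge_noise_frac)
  }
  for (i in seq_len(part$ddis)) {
    vi <- vi + 1L
    set.seed(child_seed(config$seed, 10 + vi))
    nm <- sprintf("%02d_drug_disease_%d", vi, i)
    views[[nm]] <- association_view(world$latents$drug, world$latents$disease,
                                    d_ids, s_ids, config$association_bias,
                                    nm, "drug_disease")
  }
  for (i in seq_len(part$pdis)) {
    vi <- vi + 1L
    set.seed(child_seed(config$seed, 10 + vi))
    nm <- sprintf("%02d_protein_disease_%d", vi, i)
    views[[nm]] <- association_view(world$latents$protein,
                                    world$latents$disease, p_ids, s_ids,
                                    config$association_bias, nm,
                                    "protein_disease")
  }
  vi <- vi + 1L
  pairs <- train_pairs %||% world$positives
  nm <- sprintf("%02d_dti_known", vi)
  views[[nm]] <- view_graph(
    name = nm, relation = "drug_protein",
    edges = data.frame(src = pairs$drug_id, dst = pairs$protein_id,
                       weight = 1, stringsAsFactors = FALSE))
  views
}

#' Generate a complete synthetic world in one call
#'
#' Runs [generate_entities()], [generate_interactions()] and
#' [generate_views()] under a single seed.
#'
#' @inheritParams generate_entities
#' @return A `synthetic_world` with `views` attached.
#' @export
generate_world <- function(config = synthetic_config()) {
  world <- generate_entities(config)
  world <- generate_interactions(world)
  world$views <- generate_views(world)
  world
}

#' Write a synthetic world as plain-text fixtures
#'
#' Emits `entities.tsv`, one `edges_<view>.tsv` per view, `proteins.fasta`,
#' `fingerprints.tsv` and `positives.tsv` (TSV with header, UTF-8, LF).
#'
#' @param world A `synthetic_world` with views.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixtures <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ent <- world$entities
  paths <- character(0)

  p <- file.path(dir, "entities.tsv")
  write_tsv(data.frame(id = ent$table$id, type = ent$table$kind,
                       name = gsub("_", " ", ent$table$id)), p)
  paths <- c(paths, p)

  for (nm in names(world$views)) {
    p <- file.path(dir, sprintf("edges_%s.tsv", nm))
    write_view(world$views[[nm]], p)
    paths <- c(paths, p)
  }

  p <- file.path(dir, "proteins.fasta")
  write_fasta(ent$sequences, p)
  paths <- c(paths, p)

  p <- file.path(dir, "fingerprints.tsv")
  write_tsv(data.frame(id = rownames(ent$fingerprints),
                       bitstring = apply(ent$fingerprints, 1, paste,
                                         collapse = "")), p)
  paths <- c(paths, p)

  p <- file.path(dir, "positives.tsv")
  write_tsv(world$positives, p)
  paths <- c(paths, p)
  invisible(paths)
}
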