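# Containers for the heterogeneous multi-view graph: typed entities, one
# weighted edge set per relation view, and the per-node prior feature
# matrices.  All persisted artifacts store string ids; integer indices are
# assigned deterministically from entity-table order only at assembly time.

#' Construct a typed entity set
#'
#' @param ids Character vector of unique entity ids.
#' @param kinds Character vector (same length) with values `"drug"`,
#'   `"protein"` or `"disease"`.
#' @param fingerprints Optional 0/1 matrix with rownames covering the drug
#'   ids.
#' @param sequences Optional named character vector of residue sequences
#'   covering the protein ids.
#' @return An object of class `entity_set`.
#' @export
entity_set <- function(ids, kinds, fingerprints = NULL, sequences = NULL) {
  ids <- as.character(ids)
  kinds <- as.character(kinds)
  if (length(ids) != length(kinds)) {
    stop_input("ids and kinds must have equal length")
  }
  if (anyDuplicated(ids)) {
    stop_input("duplicate entity id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- setdiff(unique(kinds), c("drug", "protein", "disease"))
  if (length(bad)) stop_input("unknown entity kind(s): ",
                              paste(bad, collapse = ", "))
  tab <- data.frame(id = ids, kind = kinds, index = seq_along(ids),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fingerprints = fingerprints,
                 sequences = sequences),
            class = "entity_set")
}

#' @export
print.entity_set <- function(x, ...) {
  counts <- table(x$table$kind)
  cat("entity_set:", nrow(x$table), "entities (",
      paste(sprintf("%s %s", counts, names(counts)), collapse = ", "), ")\n")
  invisible(x)
}

#' Construct one relation view
#'
#' Undirected views (the default; similarity and association views) are
#' stored symmetrized: edge `(i, j, w)` is present iff `(j, i, w)` is.
#' Self-edges are dropped at storage time (the model re-introduces self-loops
#' during message passing), duplicate rows are collapsed, and weights must be
#' finite.
#'
#' @param name View name (string; fusion weights are positional, so view
#'   order is recorded by the enclosing multi-view graph).
#' @param relation Relation label, e.g. `"drug_drug"` or `"drug_protein"`.
#' @param edges Data.frame with columns `src`, `dst`, `weight`.
#' @param directed Currently only undirected storage is supported.
#' @return An object of class `view_graph`.
#' @export
view_graph <- function(name, relation, edges, directed = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  edges <- data.frame(src = as.character(edges$src),
                      dst = as.character(edges$dst),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (nrow(edges) && any(!is.finite(edges$weight))) {
    stop_input(sprintf("view '%s' has non-finite edge weights", name))
  }
  edges <- edges[edges$src != edges$dst, , drop = FALSE]
  if (!directed && nrow(edges)) {
    edges <- rbind(edges,
                   data.frame(src = edges$dst, dst = edges$src,
                              weight = edges$weight,
                              stringsAsFactors = FALSE))
  }
  if (nrow(edges)) {
    edges <- edges[!duplicated(edges[, c("src", "dst")]), , drop = FALSE]
    edges <- edges[order(edges$src, edges$dst), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(name = name, relation = relation, edges = edges,
                 directed = directed),
            class = "view_graph")
}

#' @export
print.view_graph <- function(x, ...) {
  cat(sprintf("view_graph '%s' (%s): %d directed edge rows\n",
              x$name, x$relation, nrow(x$edges)))
  invisible(x)
}

#' Assemble the multi-view heterogeneous graph
#'
#' Resolves every edge endpoint against the entity table (deterministic
#' indexing by file/entity order), records the view order, and attaches the
#' initial per-node feature matrices (fingerprint bits for drugs, k-mer
#' composition for proteins; diseases receive a learned embedding inside the
#' model).
#'
#' @param entities An [entity_set()], or a fixture directory path produced by
#'   [write_fixtures()]/[cmd_simulate()].
#' @param views Named list of [view_graph()]s (ignored when `entities` is a
#'   directory).
#' @param kmer_k k-mer size for the protein sequence features (1-3).
#' @return An object of class `multiview_graph`.
#' @export
assemble_multiview_graph <- function(entities, views = NULL, kmer_k = 2) {
  if (is.character(entities) && length(entities) == 1L) {
    raw <- read_world_dir(entities)
    entities <- entity_set(raw$entities$id, raw$entities$kind,
                           fingerprints = raw$fingerprints,
                           sequences = raw$sequences)
    views <- raw$views
  }
  stopifnot(inherits(entities, "entity_set"))
  if (is.null(views) || !length(views)) stop_input("no views supplied")
  if (is.null(names(views)) || any(names(views) == "")) {
    names(views) <- vapply(views, function(v) v$name, character(1))
  }

  id_to_index <- seq_len(nrow(entities$table))
  names(id_to_index) <- entities$table$id
  for (v in views) {
    ids <- unique(c(v$edges$src, v$edges$dst))
    missing <- setdiff(ids, entities$table$id)
    if (length(missing)) {
      bad_row <- which(v$edges$src %in% missing | v$edges$dst %in% missing)[1]
      stop_input(sprintf(
        "view '%s' row %d references unknown entity id '%s'",
        v$name, bad_row, missing[1]))
    }
  }

  features <- prior_feature_matrices(entities, kmer_k = kmer_k)
  structure(list(entities = entities, views = views, features = features,
                 kmer_k = kmer_k),
            class = "multiview_graph")
}

#' @export
print.multiview_graph <- function(x, ...) {
  cat(sprintf("multiview_graph: %d entities, %d views\n",
              nrow(x$entities$table), length(x$views)))
  invisible(x)
}

#' Replace the known-interaction view of a multi-view graph
#'
#' Used by the fold loop to restrict the drug-protein view to the training
#' positives of the current fold (the leakage guard in [train_model()]
#' asserts this).
#'
#' @param graph A [assemble_multiview_graph()] result.
#' @param pairs Data.frame with `drug_id`, `protein_id`.
#' @param relation Relation label of the view to replace.
#' @return The graph with the interaction view rebuilt from `pairs`.
#' @export
set_interaction_view <- function(graph, pairs, relation = "drug_protein") {
  stopifnot(inherits(graph, "multiview_graph"))
  hit <- which(vapply(graph$views, function(v) v$relation == relation,
                      logical(1)))
  if (length(hit) != 1L) {
    stop_config(sprintf("expected exactly one '%s' view, found %d",
                        relation, length(hit)))
  }
  old <- graph$views[[hit]]
  graph$views[[hit]] <- view_graph(
    name = old$name, relation = relation,
    edges = data.frame(src = pairs$drug_id, dst = pairs$protein_id,
                       weight = 1, stringsAsFactors = FALSE))
  graph
}
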