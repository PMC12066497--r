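# Pairwise similarity scorers for the attribute-derived views, and the
# mutual top-k sparsification rule that turns a dense similarity matrix into
# a view graph.

#' Tanimoto similarity of two fingerprint bit-vectors
#'
#' `|A intersect B| / |A union B|` over the set bits.  Returns 0 when both
#' vectors are all-zero (documented convention for featureless molecules).
#'
#' @param fp_a,fp_b Equal-length 0/1 vectors (logical or numeric).
#' @return A number in \[0, 1\].
#' @export
tanimoto_similarity <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stop_input("fingerprints must have equal length")
  }
  a <- as.logical(fp_a)
  b <- as.logical(fp_b)
  if (anyNA(a) || anyNA(b)) stop_input("fingerprints must be 0/1 vectors")
  union <- sum(a | b)
  if (union == 0L) return(0)
  sum(a & b) / union
}

assert_residues <- function(seq, arg) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop_input(sprintf("'%s' must be a non-empty residue string", arg))
  }
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), aa_alphabet())
  if (length(bad)) {
    stop_input(sprintf("'%s' contains illegal residue(s): %s", arg,
                       paste(bad, collapse = ", ")))
  }
  seq
}

local_align_score <- function(a, b, submat, gap_opening, gap_extension) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = submat, gapOpening = gap_opening,
    gapExtension = gap_extension, scoreOnly = TRUE)
}

#' Normalized local-alignment similarity of two protein sequences
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps: opening 10,
#' extension 1 by default) normalized as
#' `score(a, b) / sqrt(score(a, a) * score(b, b))`, a self-contained stand-in
#' for BLAST bit-score similarity.  Symmetric, 1 for identical sequences.
#'
#' @param seq_a,seq_b Non-empty strings over the 20-letter amino-acid
#'   alphabet (case-insensitive).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings, or a numeric matrix.
#' @return A number in \[0, 1\].
#' @export
sequence_similarity <- function(seq_a, seq_b, gap_opening = 10,
                                gap_extension = 1,
                                substitution_matrix = "BLOSUM62") {
  seq_a <- assert_residues(seq_a, "seq_a")
  seq_b <- assert_residues(seq_b, "seq_b")
  submat <- if (is.matrix(substitution_matrix)) {
    substitution_matrix
  } else {
    get(utils::data(list = substitution_matrix,
                    package = "Biostrings",
                    envir = environment()))
  }
  s_ab <- local_align_score(seq_a, seq_b, submat, gap_opening, gap_extension)
  s_aa <- local_align_score(seq_a, seq_a, submat, gap_opening, gap_extension)
  s_bb <- local_align_score(seq_b, seq_b, submat, gap_opening, gap_extension)
  min(1, max(0, s_ab / sqrt(s_aa * s_bb)))
}

#' Build a similarity view by mutual top-k sparsification
#'
#' Scores all pairs of entities of one kind, then keeps edge `(i, j)` if `j`
#' is among `i`'s top-k most similar entities or `i` is among `j`'s;
#' symmetrizes; edge weights are the raw similarity scores.  Edges with
#' non-positive weight are dropped when `drop_zero` is on (the default), so
#' an all-zero similarity table yields an empty view.
#'
#' @param entities An [entity_set()].
#' @param kind Entity kind to score (`"drug"` or `"protein"`).
#' @param scorer Function of two attribute payloads returning a similarity in
#'   \[0, 1\] (e.g. [tanimoto_similarity()] on fingerprints or
#'   [sequence_similarity()] on sequences); alternatively supply a
#'   precomputed matrix via [build_similarity_view_matrix()].
#' @param k Neighbourhood size, `1 <= k <` number of entities of that kind.
#' @param name View name.
#' @param relation Relation label (default `<kind>_<kind>`).
#' @param drop_zero Drop edges with weight `<= 0`.
#' @return A [view_graph()].
#' @export
build_similarity_view <- function(entities, kind, scorer, k, name,
                                  relation = paste0(kind, "_", kind),
                                  drop_zero = TRUE) {
  stopifnot(inherits(entities, "entity_set"))
  ids <- entities$table$id[entities$table$kind == kind]
  payload <- switch(kind,
    drug = lapply(ids, function(i) entities$fingerprints[i, ]),
    protein = lapply(ids, function(i) entities$sequences[[i]]),
    stop_input("no attribute payload defined for kind: ", kind))
  n <- length(ids)
  s <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      s[i, j] <- s[j, i] <- scorer(payload[[i]], payload[[j]])
    }
  }
  build_similarity_view_matrix(s, k, name, relation, drop_zero)
}

#' Mutual top-k sparsification of a precomputed similarity matrix
#'
#' @param s Symmetric similarity matrix with entity ids as dimnames.
#' @inheritParams build_similarity_view
#' @return A [view_graph()].
#' @export
build_similarity_view_matrix <- function(s, k, name, relation,
                                         drop_zero = TRUE) {
  n <- nrow(s)
  if (is.null(rownames(s))) stop_input("similarity matrix needs id dimnames")
  k <- check_count(k, "k")
  if (k >= n) {
    stop_config(sprintf("k (%d) must be smaller than the number of entities (%d)",
                        k, n))
  }
  diag(s) <- -Inf
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    top <- order(s[i, ], decreasing = TRUE)[seq_len(k)]
    keep[i, top] <- TRUE
  }
  keep <- keep | t(keep)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  w <- s[idx]
  if (drop_zero) {
    sel <- w > 0
    idx <- idx[sel, , drop = FALSE]
    w <- w[sel]
  }
  view_graph(name = name, relation = relation,
             edges = data.frame(src = rownames(s)[idx[, 1]],
                                dst = rownames(s)[idx[, 2]],
                                weight = w, stringsAsFactors = FALSE))
}
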