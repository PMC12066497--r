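# Prior attribute features: fingerprint bits for drugs, k-mer composition
# for proteins, and their pair-level concatenation
# f_prior = [f_chem ; f_seq].  These enter the model twice: as initial node
# features (after a learned projection) and as a pair-level block appended to
# the fused embeddings at the MLP input; each use is independently
# switchable for the attribute-ablation variant.

#' Chemical descriptor features of a drug
#'
#' Casts the fingerprint bits to reals, optionally L2-normalized.
#'
#' @param fingerprint Non-empty 0/1 vector.
#' @param l2_normalize Divide by the Euclidean norm (all-zero vectors are
#'   left unchanged).  Default off.
#' @return Numeric vector of the same length.
#' @export
drug_chem_features <- function(fingerprint, l2_normalize = FALSE) {
  if (length(fingerprint) == 0L) stop_input("empty fingerprint")
  v <- as.numeric(fingerprint)
  if (anyNA(v) || any(v < 0 | v > 1)) stop_input("fingerprint must be 0/1")
  if (l2_normalize) {
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  v
}

kmer_alphabet <- function(k) {
  v <- ""
  for (i in seq_len(k)) {
    v <- as.vector(vapply(v, function(p) paste0(p, aa_alphabet()),
                          character(20)))
  }
  v
}

#' k-mer composition features of a protein sequence
#'
#' Normalized frequency vector of the overlapping k-mers over the `20^k`
#' k-mer alphabet in fixed lexicographic order; entries are non-negative and
#' sum to 1.  Case-insensitive.
#'
#' @param sequence Residue string of length `>= k`.
#' @param k k-mer size in `{1, 2, 3}` (default 3).
#' @return Named numeric vector of length `20^k`.
#' @export
protein_seq_features <- function(sequence, k = 3) {
  k <- check_count(k, "k")
  if (!k %in% 1:3) stop_config("k must be 1, 2 or 3")
  sequence <- assert_residues(sequence, "sequence")
  n <- nchar(sequence)
  if (n < k) stop_input("sequence shorter than k")
  kmers <- substring(sequence, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  counts <- table(factor(kmers, levels = kmer_alphabet(k)))
  out <- as.numeric(counts) / length(kmers)
  names(out) <- kmer_alphabet(k)
  out
}

# All drug/protein prior features of an entity set, as matrices in entity
# order.  The same matrices serve as initial node features and as the
# pair-level prior blocks.
prior_feature_matrices <- function(entities, kmer_k = 2) {
  tab <- entities$table
  d_ids <- tab$id[tab$kind == "drug"]
  p_ids <- tab$id[tab$kind == "protein"]
  if (is.null(entities$fingerprints) ||
      !all(d_ids %in% rownames(entities$fingerprints))) {
    stop_input("fingerprints missing for some drugs")
  }
  if (is.null(entities$sequences) ||
      !all(p_ids %in% names(entities$sequences))) {
    stop_input("sequences missing for some proteins")
  }
  f_chem <- t(vapply(d_ids,
                     function(i) drug_chem_features(entities$fingerprints[i, ]),
                     numeric(ncol(entities$fingerprints))))
  f_seq <- t(vapply(p_ids,
                    function(i) protein_seq_features(entities$sequences[[i]],
                                                     k = kmer_k),
                    numeric(20^kmer_k)))
  rownames(f_chem) <- d_ids
  rownames(f_seq) <- p_ids
  structure(list(f_chem = f_chem, f_seq = f_seq,
                 dim_chem = ncol(f_chem), dim_seq = ncol(f_seq)),
            class = "prior_features")
}

#' Pair-level prior vector of a drug-protein pair
#'
#' Concatenation of the drug's chemical features and the protein's sequence
#' features, in that order: `f_prior = [f_chem ; f_seq]`.
#'
#' @param drug_id,protein_id Entity ids.
#' @param features A `prior_features` object (from
#'   [assemble_multiview_graph()]'s `$features` or
#'   `mvgat:::prior_feature_matrices`).
#' @return Numeric vector of length `dim_chem + dim_seq`.
#' @export
pair_prior <- function(drug_id, protein_id, features) {
  stopifnot(inherits(features, "prior_features"))
  if (!drug_id %in% rownames(features$f_chem)) {
    stop_input("no chemical features for drug id: ", drug_id)
  }
  if (!protein_id %in% rownames(features$f_seq)) {
    stop_input("no sequence features for protein id: ", protein_id)
  }
  c(features$f_chem[drug_id, ], features$f_seq[protein_id, ])
}
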