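# Plain-text readers/writers for the fixture formats: header TSV, UTF-8, LF.

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, format_col), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_col <- function(x) {
  # %.17g guarantees that doubles survive the write/read round trip exactly.
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

read_tsv <- function(path, required = NULL, colClasses = NA) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "", comment.char = "",
                   colClasses = colClasses)
  if (!is.null(required) && !all(required %in% names(df))) {
    stop_input(sprintf("file %s is missing required columns: %s", path,
                       paste(setdiff(required, names(df)), collapse = ", ")))
  }
  df
}

#' Read an entity table
#'
#' @param path TSV with columns `id`, `type` (and optionally `name`).
#' @return A data.frame with columns `id` and `kind`.
#' @export
read_entities <- function(path) {
  df <- read_tsv(path, required = c("id", "type"))
  if (anyDuplicated(df$id)) {
    stop_input("duplicate entity id(s): ",
               paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  data.frame(id = as.character(df$id), kind = as.character(df$type),
             stringsAsFactors = FALSE)
}

#' Read one relation view from an edge-list TSV
#'
#' @param path TSV with columns `source_id`, `target_id`, `weight`,
#'   `relation`.
#' @param name View name; defaults to the file name stripped of the
#'   `edges_` prefix and extension.
#' @return A [view_graph()].
#' @export
read_view <- function(path, name = NULL) {
  df <- read_tsv(path, required = c("source_id", "target_id", "weight",
                                    "relation"))
  if (is.null(name)) {
    name <- sub("^edges_", "", sub("\\.tsv$", "", basename(path)))
  }
  relation <- if (nrow(df)) df$relation[1] else "unknown"
  view_graph(name = name, relation = relation,
             edges = data.frame(src = as.character(df$source_id),
                                dst = as.character(df$target_id),
                                weight = as.numeric(df$weight),
                                stringsAsFactors = FALSE))
}

#' Write a relation view as an edge-list TSV
#'
#' Undirected views are stored with one canonical row per edge
#' (`source_id < target_id`), sorted, so the on-disk form is unique and
#' re-serialization after reading is byte-identical.
#'
#' @param view A [view_graph()].
#' @param path Output path.
#' @export
write_view <- function(view, path) {
  stopifnot(inherits(view, "view_graph"))
  e <- view$edges
  keep <- e$src < e$dst | !(paste(e$dst, e$src) %in% paste(e$src, e$dst))
  e <- e[keep, , drop = FALSE]
  e <- e[order(e$src, e$dst), , drop = FALSE]
  write_tsv(data.frame(source_id = e$src, target_id = e$dst,
                       weight = e$weight, relation = view$relation), path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of residue sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read drug fingerprints
#'
#' @param path TSV with columns `id` and `bitstring` (e.g. `"0101..."`).
#' @return Integer 0/1 matrix, one row per drug, rownames = ids.
#' @export
read_fingerprints <- function(path) {
  # bitstrings must stay character: numeric conversion would drop leading 0s
  df <- read_tsv(path, required = c("id", "bitstring"),
                 colClasses = "character")
  bits <- strsplit(as.character(df$bitstring), "")
  len <- unique(lengths(bits))
  if (length(len) != 1L) stop_input("fingerprint bitstrings differ in length")
  m <- do.call(rbind, lapply(bits, function(b) {
    v <- suppressWarnings(as.integer(b))
    if (anyNA(v) || any(v > 1L)) stop_input("fingerprint bits must be 0/1")
    v
  }))
  rownames(m) <- as.character(df$id)
  m
}

#' Read labeled or unlabeled drug-protein pairs
#'
#' @param path TSV with columns `drug_id`, `protein_id` and optionally
#'   `label`.
#' @return A data.frame.
#' @export
read_pairs <- function(path) {
  df <- read_tsv(path, required = c("drug_id", "protein_id"))
  df$drug_id <- as.character(df$drug_id)
  df$protein_id <- as.character(df$protein_id)
  df
}

# Read a fixture directory written by write_fixtures()/cmd_simulate().
read_world_dir <- function(dir) {
  ent <- read_entities(file.path(dir, "entities.tsv"))
  view_files <- sort(list.files(dir, pattern = "^edges_.*\\.tsv$",
                                full.names = TRUE))
  views <- lapply(view_files, read_view)
  names(views) <- vapply(views, function(v) v$name, character(1))
  fp_path <- file.path(dir, "fingerprints.tsv")
  fa_path <- file.path(dir, "proteins.fasta")
  pos_path <- file.path(dir, "positives.tsv")
  list(
    entities = ent,
    views = views,
    fingerprints = if (file.exists(fp_path)) read_fingerprints(fp_path),
    sequences = if (file.exists(fa_path)) read_fasta(fa_path),
    positives = if (file.exists(pos_path)) read_pairs(pos_path)
  )
}
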