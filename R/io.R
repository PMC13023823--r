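# ---- standard input formats --------------------------------------------

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA file.
#' @return list with `name` and `sequence` (RNA alphabet, T read as U).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  list(name = names(set)[1],
       sequence = normalize_rna_sequence(as.character(set[[1]])))
}

#' Read a Vienna dot-bracket file
#'
#' Accepts the 2-line (sequence, structure) or 3-line (`>name`, sequence,
#' structure) layout. Bracket families `()`, `[]`, `{}`, `<>` are accepted;
#' only `()` contributes nested pairs.
#'
#' @param path dot-bracket file.
#' @return list with `name`, `sequence`, `db`, and the parsed `ss`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- NA_character_
  if (length(lines) > 0 && startsWith(lines[1], ">")) {
    name <- sub("^>", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 2)
    stop("dot-bracket file needs a sequence line and a structure line: ",
         path)
  ss <- parse_dot_bracket(lines[2], lines[1])
  list(name = name, sequence = ss$sequence, db = lines[2], ss = ss)
}

#' Export feature matrices of a chain for inspection
#'
#' Writes the tree node/edge feature matrices as CSV and the
#' nucleotide-to-tree membership map as JSON.
#'
#' @param features a `chain_features` from [featurize_chain()].
#' @param path_prefix output prefix; writes `<prefix>_tree_nodes.csv`,
#'   `<prefix>_tree_edges.csv`, `<prefix>_membership.json`.
#' @export
write_features <- function(features, path_prefix) {
  utils::write.csv(features$tree_node_features,
                   paste0(path_prefix, "_tree_nodes.csv"), row.names = FALSE)
  utils::write.csv(features$tree_edge_features,
                   paste0(path_prefix, "_tree_edges.csv"), row.names = FALSE)
  jsonlite::write_json(list(node_members = features$node_members,
                            edge_members = features$edge_members),
                       paste0(path_prefix, "_membership.json"))
  invisible(path_prefix)
}
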