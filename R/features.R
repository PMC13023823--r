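# ---- nucleotide graph ---------------------------------------------------

BASE_LEVELS  <- c("A", "U", "G", "C")
MOTIF_LEVELS <- c("S", "H", "B", "I", "M", "E", "X")
EDGE_LEVELS  <- c("backbone", "pair", "pseudoknot")

#' Build the fine-grained nucleotide graph
#'
#' One node per nucleotide with an 11-dimensional feature vector: 4-dim base
#' one-hot (A, U, G, C; all zeros for N) concatenated with a 7-dim motif
#' label one-hot (S, H, B, I, M, E, X). Undirected edges carry a 3-dim
#' one-hot type: backbone (i, i+1), nested base pair, or pseudoknot pair.
#'
#' @param ss a `secondary_structure`.
#' @param labels per-nucleotide motif labels from [classify_loops()].
#' @return a `nucleotide_graph`: list with `node_features` (n x 11),
#'   `edges` (m x 2 integer matrix), `edge_features` (m x 3).
#' @export
build_nucleotide_graph <- function(ss, labels) {
  n <- ss$length
  if (length(labels) != n) stop("labels length does not match sequence")
  bases <- strsplit(ss$sequence, "")[[1]]
  node_features <- matrix(0, n, 11,
                          dimnames = list(NULL, c(BASE_LEVELS, MOTIF_LEVELS)))
  bi <- match(bases, BASE_LEVELS)        # NA for N
  ok <- !is.na(bi)
  node_features[cbind(which(ok), bi[ok])] <- 1
  li <- match(labels, MOTIF_LEVELS)
  if (anyNA(li)) stop("unknown motif label")
  node_features[cbind(seq_len(n), 4L + li)] <- 1

  eb <- if (n > 1) cbind(seq_len(n - 1), 2:n) else empty_pairs()
  ep <- ss$nested_pairs
  ek <- ss$pseudoknot_pairs
  edges <- rbind(eb, ep, ek)
  type <- rep(1:3, times = c(nrow(eb), nrow(ep), nrow(ek)))
  edge_features <- matrix(0, nrow(edges), 3,
                          dimnames = list(NULL, EDGE_LEVELS))
  if (nrow(edges) > 0)
    edge_features[cbind(seq_len(nrow(edges)), type)] <- 1
  structure(list(node_features = node_features,
                 edges = unname(edges), edge_features = edge_features),
            class = "nucleotide_graph")
}

# ---- tree node features (loop descriptors) ------------------------------

TREE_FEATURE_GROUPS <- c("length", "pairwise_min", "sorted_length",
                         "pairwise_diff", "pairwise_ratio", "fraction",
                         "max_au_run", "max_a_run")

pad3 <- function(x) c(x, rep(0, 3 - length(x)))[1:3]

max_run <- function(chars, allowed) {
  if (length(chars) == 0) return(0L)
  hit <- chars %in% allowed
  if (!any(hit)) return(0L)
  r <- rle(hit)
  max(r$lengths[r$values])
}

#' Tree-node feature vector of a loop motif
#'
#' 24 values: the 8 loop-descriptor groups, each padded to length 3 with 0.
#' Groups, in fixed order: segment lengths 5' to 3'; pairwise minima;
#' lengths sorted ascending (real segments sorted, then padded); pairwise
#' absolute differences; pairwise ratios (zero-guarded denominator);
#' normalized length fractions; maximum consecutive A/U run per segment;
#' maximum consecutive A run per segment. Pairwise groups enumerate (1,2),
#' (1,3), (2,3).
#'
#' @param motif a `motif` with at most 3 segments.
#' @param seq the chain's sequence string.
#' @return named numeric vector of length 24.
#' @export
tree_node_features <- function(motif, seq) {
  M <- length(motif$segments)
  if (M > 3) stop("unsupported motif with ", M, " segments")
  bases <- strsplit(seq, "")[[1]]
  len <- vapply(motif$segments, length, integer(1))
  pair_idx <- list(c(1, 2), c(1, 3), c(2, 3))
  pairs_avail <- Filter(function(p) p[2] <= M, pair_idx)
  pw <- function(f) pad3(vapply(pairs_avail,
                                function(p) f(len[p[1]], len[p[2]]),
                                numeric(1)))
  total <- sum(len)
  segs_chars <- lapply(motif$segments, function(s) bases[s])
  v <- c(pad3(len),
         pw(function(a, b) min(a, b)),
         pad3(sort(len)),
         pw(function(a, b) abs(a - b)),
         pw(function(a, b) a / max(b, 1)),
         if (total > 0) pad3(len / total) else rep(0, 3),
         pad3(vapply(segs_chars, max_run, numeric(1), allowed = c("A", "U"))),
         pad3(vapply(segs_chars, max_run, numeric(1), allowed = "A")))
  names(v) <- paste0(rep(TREE_FEATURE_GROUPS, each = 3), "_", 1:3)
  v
}

# ---- stem edge features -------------------------------------------------

#' Stem (tree edge) feature vector
#'
#' `(Lstem, fGC, fAU, fGU)`: base-pair count and the fractions of G-C, A-U
#' and G-U pairs (both orientations counted), each normalized by `Lstem`.
#' Non-canonical pairs leave the fractions summing below 1.
#'
#' @param stem a `stem`.
#' @param seq the chain's sequence string.
#' @return named numeric vector of length 4.
#' @export
stem_edge_features <- function(stem, seq) {
  bases <- strsplit(seq, "")[[1]]
  bp <- paste0(bases[stem$pairs[, 1]], bases[stem$pairs[, 2]])
  L <- stem$length_bp
  c(Lstem = L,
    fGC = sum(bp %in% c("GC", "CG")) / L,
    fAU = sum(bp %in% c("AU", "UA")) / L,
    fGU = sum(bp %in% c("GU", "UG")) / L)
}

# ---- chain-level assembly ----------------------------------------------

#' Featurize a chain for the dual-resolution model
#'
#' Assembles the nucleotide graph, the tree node/edge feature matrices and
#' the nucleotide-to-tree membership map. Each loop nucleotide maps to its
#' tree node; each stem nucleotide maps to its tree edge. Rows are ordered
#' by node/edge id, deterministically.
#'
#' @param ss a `secondary_structure`.
#' @param tree optional pre-built `tree_graph` for the same structure.
#' @return a `chain_features` list: `nuc_graph`, `tree` (the tree graph),
#'   `tree_node_features` (T x 24), `tree_edge_features` ((T-1) x 4),
#'   `node_members` (list per tree node of nucleotide indices),
#'   `edge_members` (list per stem), `junctions`.
#' @export
featurize_chain <- function(ss, tree = NULL) {
  if (is.null(tree)) tree <- build_tree_graph(ss)
  if (tree$ss$length != ss$length ||
      nrow(tree$ss$nested_pairs) != nrow(ss$nested_pairs))
    stop("assembly error: tree graph does not match the structure")
  ng <- build_nucleotide_graph(ss, tree$labels)
  tnf <- t(vapply(tree$nodes, tree_node_features, numeric(24),
                  seq = ss$sequence))
  tef <- if (length(tree$stems) > 0) {
    t(vapply(tree$stems, stem_edge_features, numeric(4), seq = ss$sequence))
  } else matrix(0, 0, 4, dimnames = list(NULL, c("Lstem", "fGC", "fAU", "fGU")))
  node_members <- lapply(tree$nodes, function(m)
    as.integer(unlist(m$segments)))
  edge_members <- lapply(tree$stems, function(s)
    as.integer(c(s$pairs[, 1], s$pairs[, 2])))
  covered <- c(unlist(node_members), unlist(edge_members))
  if (length(covered) != ss$length || anyDuplicated(covered) ||
      !setequal(covered, seq_len(ss$length)))
    stop("assembly error: membership map is not a partition of the chain")
  structure(list(nuc_graph = ng, tree = tree,
                 tree_node_features = tnf, tree_edge_features = tef,
                 node_members = node_members, edge_members = edge_members,
                 junctions = find_three_way_junctions(tree)),
            class = "chain_features")
}
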