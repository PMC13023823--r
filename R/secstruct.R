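# ---- secondary structure -----------------------------------------------

BRACKET_OPEN  <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

normalize_rna_sequence <- function(seq) {
  s <- toupper(seq)
  s <- chartr("T", "U", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "U", "G", "C", "N"))
  if (length(bad) > 0)
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "))
  s
}

empty_pairs <- function() matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("i", "j")))

as_pair_matrix <- function(pairs) {
  if (length(pairs) == 0) return(empty_pairs())
  m <- do.call(rbind, pairs)
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("i", "j")
  m
}

#' Parse a dot-bracket secondary structure
#'
#' Matches brackets per family: round parentheses define the nested (planar)
#' pairing map; the families `[]`, `{}` and `<>` are recorded separately as
#' pseudoknot pairs, since crossing interactions cannot live in a planar tree
#' graph. Indices are 1-based.
#'
#' @param db dot-bracket string (characters `.()[]{}<>`).
#' @param seq RNA sequence of the same length (A/U/G/C/N; T is read as U).
#' @return A `secondary_structure` object: list with `sequence`,
#'   `nested_pairs` (m x 2 integer matrix, i < j), `pseudoknot_pairs`, `length`.
#' @export
#' @examples
#' ss <- parse_dot_bracket("((..))", "GGAACC")
#' ss$nested_pairs
parse_dot_bracket <- function(db, seq) {
  if (nchar(db) != nchar(seq))
    stop("structure and sequence lengths differ (", nchar(db), " vs ",
         nchar(seq), ")")
  seq <- normalize_rna_sequence(seq)
  chars <- strsplit(db, "")[[1]]
  n <- length(chars)
  stacks <- rep(list(integer(0)), length(BRACKET_OPEN))
  nested <- list()
  pk <- list()
  for (k in seq_len(n)) {
    ch <- chars[k]
    fo <- match(ch, BRACKET_OPEN)
    fc <- match(ch, BRACKET_CLOSE)
    if (!is.na(fo)) {
      stacks[[fo]] <- c(stacks[[fo]], k)
    } else if (!is.na(fc)) {
      if (length(stacks[[fc]]) == 0)
        stop("unbalanced '", ch, "' at position ", k)
      i <- stacks[[fc]][length(stacks[[fc]])]
      stacks[[fc]] <- stacks[[fc]][-length(stacks[[fc]])]
      if (fc == 1L) nested[[length(nested) + 1L]] <- c(i, k)
      else pk[[length(pk) + 1L]] <- c(i, k)
    } else if (ch != ".") {
      stop("invalid structure character '", ch, "' at position ", k)
    }
  }
  for (f in seq_along(stacks))
    if (length(stacks[[f]]) > 0)
      stop("unbalanced '", BRACKET_OPEN[f], "' at position ",
           stacks[[f]][length(stacks[[f]])])
  structure(list(sequence = seq,
                 nested_pairs = as_pair_matrix(nested),
                 pseudoknot_pairs = as_pair_matrix(pk),
                 length = n),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure:", x$length, "nt,",
      nrow(x$nested_pairs), "nested pairs,",
      nrow(x$pseudoknot_pairs), "pseudoknot pairs\n")
  invisible(x)
}

#' Render a secondary structure back to dot-bracket
#'
#' Inverse of [parse_dot_bracket()]: nested pairs become `()`; pseudoknot
#' pairs are assigned greedily to the `[]`, `{}`, `<>` families so that pairs
#' within one family never cross.
#'
#' @param ss a `secondary_structure`.
#' @return dot-bracket string.
#' @export
render_dot_bracket <- function(ss) {
  chars <- rep(".", ss$length)
  np <- ss$nested_pairs
  if (nrow(np) > 0) {
    chars[np[, 1]] <- "("
    chars[np[, 2]] <- ")"
  }
  fams <- rep(list(empty_pairs()), 3L)  # [], {}, <>
  pk <- ss$pseudoknot_pairs
  if (nrow(pk) > 0) {
    for (r in seq_len(nrow(pk))) {
      i <- pk[r, 1]; j <- pk[r, 2]
      placed <- FALSE
      for (f in 1:3) {
        m <- fams[[f]]
        crosses <- nrow(m) > 0 &&
          any((m[, 1] < i & i < m[, 2] & m[, 2] < j) |
              (i < m[, 1] & m[, 1] < j & j < m[, 2]))
        if (!crosses) {
          fams[[f]] <- rbind(m, c(i, j))
          chars[i] <- BRACKET_OPEN[f + 1L]
          chars[j] <- BRACKET_CLOSE[f + 1L]
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("pseudoknots need more than 3 bracket families")
    }
  }
  paste(chars, collapse = "")
}

# nested pairing vector: p[i] = j if (i,j) nested pair, else NA
pairing_vector <- function(ss) {
  p <- rep(NA_integer_, ss$length)
  np <- ss$nested_pairs
  if (nrow(np) > 0) {
    p[np[, 1]] <- np[, 2]
    p[np[, 2]] <- np[, 1]
  }
  p
}

# ---- stems --------------------------------------------------------------

#' Find helical stems
#'
#' Partitions the nested pairing map into maximal runs of strictly stacked
#' base pairs: consecutive pairs (i, j), (i+1, j-1). Any interruption — even a
#' single-nucleotide bulge — terminates a stem, so loops always sit between
#' stems as distinct tree nodes.
#'
#' @param ss a `secondary_structure`.
#' @return list of `stem` objects (fields `id`, `pairs` k x 2 matrix ordered
#'   outer to inner, `length_bp`), ordered by the stem's 5' start index.
#' @export
find_stems <- function(ss) {
  p <- pairing_vector(ss)
  np <- ss$nested_pairs
  stems <- list()
  if (nrow(np) > 0) {
    for (r in seq_len(nrow(np))) {
      i <- np[r, 1]; j <- np[r, 2]
      # stem start: no stacked pair just outside
      if (i > 1 && !is.na(p[i - 1]) && p[i - 1] == j + 1) next
      run <- list(c(i, j))
      while (i + 1L < j - 1L && !is.na(p[i + 1L]) && p[i + 1L] == j - 1L) {
        i <- i + 1L; j <- j - 1L
        run[[length(run) + 1L]] <- c(i, j)
      }
      m <- do.call(rbind, run)
      colnames(m) <- c("i", "j")
      stems[[length(stems) + 1L]] <-
        structure(list(id = NA_integer_, pairs = m, length_bp = nrow(m)),
                  class = "stem")
    }
  }
  ord <- order(vapply(stems, function(s) s$pairs[1, 1], integer(1)))
  stems <- stems[ord]
  for (k in seq_along(stems)) stems[[k]]$id <- k
  stems
}

# ---- loop classification ------------------------------------------------

new_motif <- function(id, kind, segments, incident_stems, parent_stem) {
  structure(list(id = id, kind = kind, segments = segments,
                 incident_stems = incident_stems, parent_stem = parent_stem),
            class = "motif")
}

# walk positions lo..hi at the current nesting level; returns unpaired runs
# (in 5'->3' order, including empty runs between stems) and child stem ids
walk_level <- function(lo, hi, p, pos2stem) {
  runs <- list()
  children <- integer(0)
  current <- integer(0)
  k <- lo
  while (k <= hi) {
    if (!is.na(p[k])) {
      runs[[length(runs) + 1L]] <- current
      current <- integer(0)
      children <- c(children, pos2stem[k])
      k <- p[k] + 1L
    } else {
      current <- c(current, k)
      k <- k + 1L
    }
  }
  runs[[length(runs) + 1L]] <- current
  list(runs = runs, children = children)
}

#' Classify loop motifs and label every nucleotide
#'
#' Decomposes a pseudoknot-free structure into loop motifs: hairpin (H),
#' bulge (B), internal (I), multibranch (M), external (E). Paired nucleotides
#' are labelled S; nucleotides paired only in pseudoknots are labelled X.
#' A bulge records only its non-empty strand; a three-way multibranch loop
#' records all three segments, empty ones included.
#'
#' @param ss a `secondary_structure`.
#' @param stems output of [find_stems()].
#' @return list with `motifs` (list of `motif`) and `labels` (character vector
#'   of per-nucleotide labels in S/H/B/I/M/E/X).
#' @export
classify_loops <- function(ss, stems) {
  n <- ss$length
  p <- pairing_vector(ss)
  pos2stem <- rep(NA_integer_, n)
  for (s in stems)
    for (r in seq_len(nrow(s$pairs))) {
      pos2stem[s$pairs[r, 1]] <- s$id
      pos2stem[s$pairs[r, 2]] <- s$id
    }
  motifs <- list()

  ext <- walk_level(1L, n, p, pos2stem)
  ext_segments <- Filter(function(r) length(r) > 0, ext$runs)
  motifs[[1L]] <- new_motif(1L, "E", ext_segments, ext$children,
                            NA_integer_)

  for (s in stems) {
    inner <- s$pairs[s$length_bp, ]
    lo <- inner[1] + 1L; hi <- inner[2] - 1L
    w <- walk_level(lo, hi, p, pos2stem)
    nchild <- length(w$children)
    id <- length(motifs) + 1L
    if (nchild == 0) {
      motifs[[id]] <- new_motif(id, "H", w$runs, s$id, s$id)
    } else if (nchild == 1) {
      r1 <- w$runs[[1]]; r2 <- w$runs[[2]]
      segs <- Filter(function(r) length(r) > 0, list(r1, r2))
      kind <- if (length(segs) >= 2) "I" else "B"
      if (length(segs) == 0)
        stop("internal consistency error: adjacent stems not merged")
      motifs[[id]] <- new_motif(id, kind, segs,
                                c(s$id, w$children), s$id)
    } else if (nchild == 2) {
      motifs[[id]] <- new_motif(id, "M", w$runs,
                                c(s$id, w$children), s$id)
    } else {
      stop("unsupported topology: junction with ", nchild + 1L,
           " branches (only three-way junctions are supported)")
    }
  }

  labels <- rep("X", n)
  labels[!is.na(p)] <- "S"
  for (m in motifs)
    for (seg in m$segments)
      if (length(seg) > 0) labels[seg] <- m$kind
  if (nrow(ss$pseudoknot_pairs) > 0) {
    pkpos <- unique(as.vector(ss$pseudoknot_pairs))
    pkpos <- pkpos[is.na(p[pkpos])]
    labels[pkpos] <- "X"
  }
  list(motifs = motifs, labels = labels)
}

# ---- tree graph ---------------------------------------------------------

#' Build the coarse-grained tree graph
#'
#' Loops become nodes and stems become edges connecting the loop outside a
#' stem to the loop it encloses. For pseudoknot-free input the result is a
#' tree: node count = stem count + 1. Pseudoknot pairs are excluded from the
#' construction (they cannot be represented in a planar tree).
#'
#' @param ss a `secondary_structure`.
#' @return a `tree_graph`: list with `nodes` (motifs), `stems`, `edges`
#'   (data.frame stem/from/to), `labels`, `ss`.
#' @export
build_tree_graph <- function(ss) {
  stems <- find_stems(ss)
  cl <- classify_loops(ss, stems)
  motifs <- cl$motifs
  # node enclosed by stem s (its inner loop)
  inner_of <- rep(NA_integer_, length(stems))
  for (m in motifs)
    if (!is.na(m$parent_stem)) inner_of[m$parent_stem] <- m$id
  # node on the outer side of stem s
  outer_of <- rep(NA_integer_, length(stems))
  for (m in motifs)
    for (s in m$incident_stems)
      if (is.na(m$parent_stem) || m$parent_stem != s) outer_of[s] <- m$id
  if (length(stems) > 0 && (anyNA(inner_of) || anyNA(outer_of)))
    stop("internal consistency error: stem with unresolved endpoint")
  edges <- data.frame(stem = vapply(stems, `[[`, integer(1), "id"),
                      from = outer_of, to = inner_of)
  tree <- structure(list(nodes = motifs, stems = stems, edges = edges,
                         labels = cl$labels, ss = ss),
                    class = "tree_graph")
  if (length(motifs) > 1) {
    g <- igraph::graph_from_edgelist(cbind(edges$from, edges$to),
                                     directed = FALSE)
    if (igraph::vcount(g) < length(motifs) || !igraph::is_connected(g))
      stop("internal consistency error: tree graph is disconnected")
  }
  if (nrow(edges) != length(motifs) - 1L)
    stop("internal consistency error: |edges| != |nodes| - 1")
  tree
}

#' @export
print.tree_graph <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, character(1), "kind")
  cat("Tree graph:", length(x$nodes), "nodes (",
      paste(kinds, collapse = ""), "),", nrow(x$edges), "stems\n")
  invisible(x)
}

tree_degree <- function(tree, node_id) {
  sum(tree$edges$from == node_id | tree$edges$to == node_id)
}

tree_neighbor_via <- function(tree, node_id, stem_id) {
  e <- tree$edges[tree$edges$stem == stem_id, ]
  if (nrow(e) != 1) stop("unknown stem id ", stem_id)
  if (e$from == node_id) e$to else e$from
}

#' Locate three-way junctions
#'
#' Returns every degree-3 multibranch node. Branches are ordered 1, 2, 3 by
#' the smallest nucleotide index at which each stem first appears along the
#' chain 5' to 3'; the closing pair of a branch is the base pair of that stem
#' nearest the junction loop.
#'
#' @param tree a `tree_graph`.
#' @return list of `three_way_junction` objects (fields `node_id`, `branches`,
#'   `closing_pairs` 3 x 2 matrix, `neighbor_nodes`). Empty list when the
#'   structure has no three-way junction.
#' @export
find_three_way_junctions <- function(tree) {
  out <- list()
  for (m in tree$nodes) {
    if (m$kind != "M") next
    if (length(m$incident_stems) != 3 || tree_degree(tree, m$id) != 3) next
    first_idx <- vapply(m$incident_stems, function(s)
      min(tree$stems[[s]]$pairs[, 1]), integer(1))
    branches <- m$incident_stems[order(first_idx)]
    closing <- t(vapply(branches, function(s) {
      st <- tree$stems[[s]]
      if (!is.na(m$parent_stem) && s == m$parent_stem)
        st$pairs[st$length_bp, ] else st$pairs[1, ]
    }, integer(2)))
    colnames(closing) <- c("i", "j")
    neighbors <- vapply(branches, function(s)
      tree_neighbor_via(tree, m$id, s), integer(1))
    out[[length(out) + 1L]] <-
      structure(list(node_id = m$id, branches = branches,
                     closing_pairs = closing, neighbor_nodes = neighbors),
                class = "three_way_junction")
  }
  out
}

#' Serialize a tree graph to JSON
#'
#' @param tree a `tree_graph`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(m) list(
    id = m$id, kind = m$kind,
    segments = lapply(m$segments, as.integer),
    incident_stems = as.integer(m$incident_stems)))
  edges <- lapply(seq_len(nrow(tree$edges)), function(r) {
    s <- tree$stems[[tree$edges$stem[r]]]
    list(stem = s$id, from = tree$edges$from[r], to = tree$edges$to[r],
         pairs = unname(apply(s$pairs, 1, as.integer, simplify = FALSE)))
  })
  js <- jsonlite::toJSON(list(nodes = nodes, edges = edges),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
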