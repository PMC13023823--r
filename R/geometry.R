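# ---- coordinate extraction ---------------------------------------------

#' Read C4' backbone coordinates from a structure file
#'
#' Extracts one C4' atom per residue of the selected chain from a PDB or
#' mmCIF file. C4' atoms are used as conformationally stable backbone
#' anchors; residues lacking a C4' atom are omitted with a warning.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param chain chain identifier (default `"A"`).
#' @return a `coord_map`: list with `xyz` (r x 3 matrix, rownames = 1-based
#'   residue rank within the chain) and `resno` (author residue numbers).
#' @export
read_structure <- function(path, chain = "A") {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found in ", path)
  resno_all <- unique(at$resno)
  c4 <- at[at$elety == "C4'", , drop = FALSE]
  if (nrow(c4) == 0) stop("no C4' atoms found for chain '", chain, "'")
  c4 <- c4[!duplicated(c4$resno), , drop = FALSE]
  missing <- setdiff(resno_all, c4$resno)
  if (length(missing) > 0)
    warning(length(missing), " residue(s) lack a C4' atom and were omitted")
  rank <- match(c4$resno, resno_all)
  xyz <- as.matrix(c4[, c("x", "y", "z")])
  ord <- order(rank)
  xyz <- xyz[ord, , drop = FALSE]
  rownames(xyz) <- rank[ord]
  if (any(!is.finite(xyz))) stop("non-finite coordinates in ", path)
  structure(list(xyz = xyz, resno = c4$resno[ord]), class = "coord_map")
}

coord_of <- function(coords, idx) {
  r <- match(as.character(idx), rownames(coords$xyz))
  found <- !is.na(r)
  out <- matrix(NA_real_, length(idx), 3)
  out[found, ] <- coords$xyz[r[found], , drop = FALSE]
  out
}

# ---- node coordinates ---------------------------------------------------

#' Coordinate of a non-junction loop node
#'
#' The geometric centroid of the C4' atoms of all nucleotides comprising the
#' loop. Unresolved members are dropped; a fully unresolved loop is an error.
#'
#' @param motif a `motif` (kind other than M).
#' @param coords a `coord_map`.
#' @return length-3 numeric vector (Angstrom).
#' @export
loop_node_coordinate <- function(motif, coords) {
  members <- unlist(motif$segments)
  if (length(members) == 0)
    stop("loop node ", motif$id, " has no member residues")
  xyz <- coord_of(coords, members)
  ok <- stats::complete.cases(xyz)
  if (!any(ok))
    stop("loop node ", motif$id, " has no resolved member residues")
  colMeans(xyz[ok, , drop = FALSE])
}

#' Anchor point of a junction branch
#'
#' Midpoint between the C4' atoms of a stem's closing base pair.
#'
#' @param closing_pair integer length-2 vector (i, j) of the closing pair.
#' @param coords a `coord_map`.
#' @return length-3 numeric vector.
#' @export
junction_anchor <- function(closing_pair, coords) {
  xyz <- coord_of(coords, closing_pair)
  if (any(!stats::complete.cases(xyz)))
    stop("closing pair (", closing_pair[1], ",", closing_pair[2],
         ") has unresolved C4' atom(s)")
  colMeans(xyz)
}

#' Incenter of a triangle in 3D
#'
#' `I = (a A + b B + c C) / (a + b + c)` with `a = |BC|`, `b = |CA|`,
#' `c = |AB|`. Degenerate (collinear or collapsed) triangles are an error.
#'
#' @param A,B,C length-3 numeric vectors.
#' @param tol degeneracy tolerance on the triangle area (Angstrom^2).
#' @return length-3 numeric vector.
#' @export
triangle_incenter <- function(A, B, C, tol = 1e-6) {
  a <- sqrt(sum((B - C)^2))
  b <- sqrt(sum((C - A)^2))
  cc <- sqrt(sum((A - B)^2))
  area <- 0.5 * sqrt(sum(cross3(B - A, C - A)^2))
  if (a + b + cc < tol || area < tol)
    stop("degenerate triangle (area ", signif(area, 3), " A^2)")
  (a * A + b * B + cc * C) / (a + b + cc)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Coordinate of a three-way junction node
#'
#' Incenter of the triangle formed by the three branch anchor points
#' (closing-pair midpoints). If the anchor triangle is degenerate the
#' centroid of the anchors is used instead, with a warning.
#'
#' @param junction a `three_way_junction`.
#' @param coords a `coord_map`.
#' @return length-3 numeric vector.
#' @export
junction_node_coordinate <- function(junction, coords) {
  anchors <- lapply(seq_len(3), function(k)
    junction_anchor(junction$closing_pairs[k, ], coords))
  tryCatch(
    triangle_incenter(anchors[[1]], anchors[[2]], anchors[[3]]),
    error = function(e) {
      warning("degenerate anchor triangle at junction node ",
              junction$node_id, "; falling back to anchor centroid")
      (anchors[[1]] + anchors[[2]] + anchors[[3]]) / 3
    })
}

#' Assign coordinates to every tree node
#'
#' Non-junction loops get the centroid of their member C4' atoms; three-way
#' junction nodes get the anchor-triangle incenter. Nodes that cannot be
#' resolved are skipped with a warning.
#'
#' @param tree a `tree_graph`.
#' @param coords a `coord_map`.
#' @return numeric matrix (nodes x 3) with NA rows for unresolved nodes.
#' @export
assign_node_coordinates <- function(tree, coords) {
  junctions <- find_three_way_junctions(tree)
  jids <- vapply(junctions, `[[`, integer(1), "node_id")
  out <- matrix(NA_real_, length(tree$nodes), 3)
  for (m in tree$nodes) {
    res <- tryCatch({
      if (m$id %in% jids)
        junction_node_coordinate(junctions[[match(m$id, jids)]], coords)
      else loop_node_coordinate(m, coords)
    }, error = function(e) {
      warning("node ", m$id, " unresolved: ", conditionMessage(e))
      rep(NA_real_, 3)
    })
    out[m$id, ] <- res
  }
  out
}

# ---- angles -------------------------------------------------------------

#' Angle between two vectors, in degrees
#'
#' `acos` of the clipped cosine; result in \[0, 180\].
#'
#' @param u,v non-zero length-3 numeric vectors.
#' @export
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) stop("zero-length vector in angle computation")
  cosv <- min(1, max(-1, sum(u * v) / (nu * nv)))
  acos(cosv) * 180 / pi
}

#' Inter-branch angles of a three-way junction
#'
#' Branch direction k is the vector from the junction coordinate to the
#' coordinate of the tree node reached via branch k (default), or to the
#' branch anchor midpoint when `endpoint = "anchor"`. Angles follow the
#' convention theta1 = (1,2), theta2 = (2,3), theta3 = (3,1), each in
#' (0, 180\].
#'
#' @param junction a `three_way_junction`.
#' @param tree the `tree_graph` containing it.
#' @param node_coords matrix from [assign_node_coordinates()].
#' @param coords `coord_map`; only required for `endpoint = "anchor"`.
#' @param endpoint `"node"` or `"anchor"`.
#' @return an `angle_set`: named numeric vector (theta1, theta2, theta3).
#' @export
compute_inter_branch_angles <- function(junction, tree, node_coords,
                                        coords = NULL,
                                        endpoint = c("node", "anchor")) {
  endpoint <- match.arg(endpoint)
  ctr <- node_coords[junction$node_id, ]
  if (any(is.na(ctr))) stop("junction node has no coordinate")
  dirs <- lapply(seq_len(3), function(k) {
    tip <- if (endpoint == "node") {
      node_coords[junction$neighbor_nodes[k], ]
    } else {
      if (is.null(coords)) stop("endpoint='anchor' requires coords")
      junction_anchor(junction$closing_pairs[k, ], coords)
    }
    if (any(is.na(tip))) stop("branch ", k, " endpoint has no coordinate")
    v <- tip - ctr
    if (sqrt(sum(v^2)) < 1e-9)
      stop("degenerate geometry: zero-length branch vector ", k)
    v
  })
  angle_set(angle_between(dirs[[1]], dirs[[2]]),
            angle_between(dirs[[2]], dirs[[3]]),
            angle_between(dirs[[3]], dirs[[1]]))
}

#' Construct an angle set
#' @param theta1,theta2,theta3 angles in degrees.
#' @export
angle_set <- function(theta1, theta2, theta3) {
  structure(stats::setNames(as.numeric(c(theta1, theta2, theta3)),
                            c("theta1", "theta2", "theta3")),
            class = "angle_set")
}

# ---- rigid-star skeletons ----------------------------------------------

unit_directions_from_angles <- function(angles) {
  t1 <- angles[[1]] * pi / 180
  if (sin(t1) < 1e-9) {
    warning("theta1 near 0/180 degrees; perturbing branch-2 direction")
    t1 <- min(max(t1, 1e-6), pi - 1e-6)
  }
  th1 <- t1 * 180 / pi
  th2 <- angles[[2]]; th3 <- angles[[3]]
  # feasible range of theta3 given theta1, theta2 (cone geometry)
  lo <- abs(th1 - th2)
  hi <- if (th1 + th2 <= 180) th1 + th2 else 360 - (th1 + th2)
  th3_eff <- min(max(th3, lo), hi)
  feasible <- abs(th3_eff - th3) < 1e-9
  u1 <- c(1, 0, 0)
  u2 <- c(cos(t1), sin(t1), 0)
  x <- cos(th3_eff * pi / 180)
  y <- (cos(th2 * pi / 180) - x * cos(t1)) / sin(t1)
  z2 <- 1 - x^2 - y^2
  u3 <- c(x, y, sqrt(max(0, z2)))
  u3 <- u3 / sqrt(sum(u3^2))
  list(u = rbind(u1, u2, u3), feasible = feasible)
}

#' Reconstruct a rigid-star skeleton from angles and branch lengths
#'
#' Places the junction center at the origin, branch 1 along +x, branch 2 in
#' the xy-plane at theta1 from branch 1, and branch 3 so that its angles to
#' branches 1 and 2 equal theta3 and theta2 (out-of-plane component +z).
#' Angle triples violating the spherical constraints are projected onto the
#' feasible boundary and flagged.
#'
#' @param angles an `angle_set` (degrees, each in (0, 180\]).
#' @param branch_lengths positive length-3 numeric (Angstrom).
#' @return a `skeleton_star`: list with `center`, `endpoints` (3 x 3 matrix),
#'   `branch_lengths`, `feasible`.
#' @export
reconstruct_skeleton <- function(angles, branch_lengths) {
  if (any(branch_lengths <= 0)) stop("branch lengths must be positive")
  ud <- unit_directions_from_angles(angles)
  endpoints <- ud$u * branch_lengths
  structure(list(center = c(0, 0, 0), endpoints = endpoints,
                 branch_lengths = branch_lengths, feasible = ud$feasible),
            class = "skeleton_star")
}

#' Build the native-abstracted star of a junction
#'
#' Center = junction node coordinate; endpoints = coordinates of the three
#' neighbor tree nodes (branch order 1..3).
#'
#' @param junction a `three_way_junction`.
#' @param node_coords matrix from [assign_node_coordinates()].
#' @return a `skeleton_star`.
#' @export
native_star <- function(junction, node_coords) {
  ctr <- node_coords[junction$node_id, ]
  ep <- node_coords[junction$neighbor_nodes, , drop = FALSE]
  if (any(is.na(ctr)) || any(is.na(ep)))
    stop("junction or neighbor node lacks a coordinate")
  structure(list(center = ctr, endpoints = ep,
                 branch_lengths = sqrt(rowSums((ep - rep(ctr, each = 3))^2)),
                 feasible = TRUE),
            class = "skeleton_star")
}

#' Recompute the pairwise angles realized by a skeleton star
#'
#' @param star a `skeleton_star`.
#' @return an `angle_set`.
#' @export
realized_angles <- function(star) {
  v <- sweep(star$endpoints, 2, star$center)
  angle_set(angle_between(v[1, ], v[2, ]),
            angle_between(v[2, ], v[3, ]),
            angle_between(v[3, ], v[1, ]))
}

star_points <- function(star) rbind(star$center, star$endpoints)

# Kabsch: optimal proper-rotation superposition RMSD of matched point sets
kabsch_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

#' Skeleton RMSD between two rigid stars
#'
#' Least-squares rigid superposition (Kabsch, proper rotations +
#' translation) over the four matched points (center + 3 endpoints).
#' Because a predicted angle triple does not determine handedness, both
#' mirror images of `pred` are evaluated and the minimum RMSD is reported.
#'
#' @param pred,native `skeleton_star` objects with matched branch indices.
#' @return RMSD in Angstrom.
#' @export
skeleton_rmsd <- function(pred, native) {
  P <- star_points(pred)
  Q <- star_points(native)
  Pm <- P %*% diag(c(1, 1, -1))
  min(kabsch_rmsd(P, Q), kabsch_rmsd(Pm, Q))
}

# ---- high-level extraction ---------------------------------------------

#' Extract ground-truth junction angles from a structure
#'
#' Runs the full geometric pipeline: tree graph, node coordinates, and
#' inter-branch angles for every three-way junction of the chain.
#'
#' @param ss a `secondary_structure`.
#' @param coords a `coord_map` for the same chain.
#' @param endpoint branch endpoint convention, see
#'   [compute_inter_branch_angles()].
#' @return data.frame with one row per junction: junction index, node id,
#'   theta1..theta3, branch lengths, closing pairs (1-based).
#' @export
extract_junction_angles <- function(ss, coords, endpoint = "node") {
  tree <- build_tree_graph(ss)
  junctions <- find_three_way_junctions(tree)
  if (length(junctions) == 0)
    return(data.frame(junction = integer(0), node_id = integer(0),
                      theta1 = numeric(0), theta2 = numeric(0),
                      theta3 = numeric(0)))
  node_coords <- assign_node_coordinates(tree, coords)
  rows <- lapply(seq_along(junctions), function(k) {
    j <- junctions[[k]]
    ang <- compute_inter_branch_angles(j, tree, node_coords,
                                       coords = coords, endpoint = endpoint)
    star <- native_star(j, node_coords)
    data.frame(junction = k, node_id = j$node_id,
               theta1 = ang[[1]], theta2 = ang[[2]], theta3 = ang[[3]],
               len1 = star$branch_lengths[1],
               len2 = star$branch_lengths[2],
               len3 = star$branch_lengths[3],
               close1_i = j$closing_pairs[1, 1], close1_j = j$closing_pairs[1, 2],
               close2_i = j$closing_pairs[2, 1], close2_j = j$closing_pairs[2, 2],
               close3_i = j$closing_pairs[3, 1], close3_j = j$closing_pairs[3, 2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a 4-point skeleton star as a minimal PDB file
#'
#' One C4'-only pseudo-residue per point (center first), for visualization.
#'
#' @param star a `skeleton_star`.
#' @param path output file.
#' @export
write_star_pdb <- function(star, path) {
  pts <- star_points(star)
  lines <- vapply(seq_len(nrow(pts)), function(r) {
    sprintf("ATOM  %5d  C4'   N A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            r, r, pts[r, 1], pts[r, 2], pts[r, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
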