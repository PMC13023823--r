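# Synthetic single-3WJ RNAs with planted, recoverable geometry.
#
# Layout (5'->3'):
#   ext5 - stem1 - segA - stem2 - hairpin2 - stem2' - segB - stem3 -
#   hairpin3 - stem3' - segC - stem1' - ext3
# The multibranch loop (segments A, B, C) is closed by stem1 and opens
# stems 2 and 3, so every generated chain carries exactly one three-way
# junction. Coordinates are emitted so that the geometric extraction
# (anchor midpoints -> incenter -> neighbor centroids) reproduces the
# planted angle triple exactly, up to floating point.

#' Synthetic dataset specification
#'
#' @param count number of chains.
#' @param stem_bp inclusive range of stem lengths (base pairs).
#' @param loop_nt inclusive range of junction loop-segment lengths (nt).
#' @param hairpin_nt inclusive range of hairpin loop lengths (nt).
#' @param ext_nt inclusive range of each external dangling end (nt).
#' @param gu_prob probability that a stem pair is a G-U wobble.
#' @param sigma angle noise s.d. (degrees) around the planted rule.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(count = 10L, stem_bp = c(2L, 8L),
                           loop_nt = c(0L, 8L), hairpin_nt = c(3L, 8L),
                           ext_nt = c(1L, 4L), gu_prob = 0.1,
                           sigma = 5, seed = 1L) {
  stopifnot(count >= 1, stem_bp[1] >= 1, stem_bp[1] <= stem_bp[2],
            loop_nt[1] >= 0, loop_nt[1] <= loop_nt[2],
            hairpin_nt[1] >= 1, ext_nt[1] >= 1, gu_prob >= 0,
            gu_prob <= 1, sigma >= 0)
  structure(list(count = as.integer(count), stem_bp = as.integer(stem_bp),
                 loop_nt = as.integer(loop_nt),
                 hairpin_nt = as.integer(hairpin_nt),
                 ext_nt = as.integer(ext_nt), gu_prob = gu_prob,
                 sigma = sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

rint <- function(range) sample(seq(range[1], range[2]), 1)

rand_bases <- function(n) if (n == 0) character(0) else
  sample(c("A", "U", "G", "C"), n, replace = TRUE)

# sample one stem as paired letter columns (5' strand, 3' partner)
rand_stem <- function(bp, gu_prob) {
  wc <- c("AU", "UA", "GC", "CG")
  gu <- c("GU", "UG")
  picks <- ifelse(stats::runif(bp) < gu_prob, sample(gu, bp, replace = TRUE),
                  sample(wc, bp, replace = TRUE))
  list(p5 = substr(picks, 1, 1), p3 = substr(picks, 2, 2))
}

#' Sample one single-3WJ sequence/structure pair
#'
#' @param spec a [synthetic_spec()]. Uses the current RNG state.
#' @return list with `sequence`, `db` (dot-bracket) and `layout` (segment
#'   and stem lengths, stem GC fractions).
#' @export
sample_structure <- function(spec) {
  s <- c(rint(spec$stem_bp), rint(spec$stem_bp), rint(spec$stem_bp))
  lseg <- c(rint(spec$loop_nt), rint(spec$loop_nt), rint(spec$loop_nt))
  hp <- c(rint(spec$hairpin_nt), rint(spec$hairpin_nt))
  ext <- c(rint(spec$ext_nt), rint(spec$ext_nt))
  st <- lapply(s, function(bp) rand_stem(bp, spec$gu_prob))
  seq_parts <- c(rand_bases(ext[1]),
                 st[[1]]$p5, rand_bases(lseg[1]),
                 st[[2]]$p5, rand_bases(hp[1]), rev(st[[2]]$p3),
                 rand_bases(lseg[2]),
                 st[[3]]$p5, rand_bases(hp[2]), rev(st[[3]]$p3),
                 rand_bases(lseg[3]),
                 rev(st[[1]]$p3), rand_bases(ext[2]))
  db_parts <- c(rep(".", ext[1]),
                rep("(", s[1]), rep(".", lseg[1]),
                rep("(", s[2]), rep(".", hp[1]), rep(")", s[2]),
                rep(".", lseg[2]),
                rep("(", s[3]), rep(".", hp[2]), rep(")", s[3]),
                rep(".", lseg[3]),
                rep(")", s[1]), rep(".", ext[2]))
  gc <- vapply(st, function(x)
    mean(paste0(x$p5, x$p3) %in% c("GC", "CG")), numeric(1))
  list(sequence = paste(seq_parts, collapse = ""),
       db = paste(db_parts, collapse = ""),
       layout = list(stem_bp = s, seg_nt = lseg, hairpin_nt = hp,
                     ext_nt = ext, gc_frac = gc))
}

# ---- planted angle rule -------------------------------------------------

#' Default planted angle rule
#'
#' A smooth bounded map from junction descriptors to an angle triple:
#' deviations from the symmetric 120/120/120 base are driven by pairwise
#' differences of the three loop-segment lengths (via tanh) and by pairwise
#' differences of the branch stems' GC fractions. The rule is fixed so that
#' parameter-recovery results are comparable across runs.
#'
#' @param seg_nt length-3 vector of junction loop-segment lengths.
#' @param gc_frac length-3 vector of branch-stem GC fractions.
#' @return length-3 numeric of noise-free angles (degrees).
#' @export
planted_angle_rule <- function(seg_nt, gc_frac) {
  d <- c(35 * tanh((seg_nt[1] - seg_nt[2]) / 4) +
           20 * (gc_frac[1] - gc_frac[2]),
         35 * tanh((seg_nt[2] - seg_nt[3]) / 4) +
           20 * (gc_frac[2] - gc_frac[3]),
         35 * tanh((seg_nt[3] - seg_nt[1]) / 4) +
           20 * (gc_frac[3] - gc_frac[1]))
  120 + d
}

angles_feasible <- function(theta) {
  r <- theta * pi / 180
  G <- diag(3)
  G[1, 2] <- G[2, 1] <- cos(r[1])
  G[2, 3] <- G[3, 2] <- cos(r[2])
  G[1, 3] <- G[3, 1] <- cos(r[3])
  min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) >= -1e-9
}

#' Project an angle triple onto the feasible set
#'
#' Clips each angle into \[5, 175\] degrees and, if the triple is not
#' realizable by three unit vectors (Gram matrix not PSD), shrinks it by
#' bisection toward the orthogonal triple (90, 90, 90) — a strictly
#' interior point of the feasible set — until it is realizable.
#'
#' @param theta length-3 numeric (degrees).
#' @return feasible length-3 numeric.
#' @export
project_feasible_angles <- function(theta) {
  theta <- pmin(pmax(theta, 5), 175)
  if (angles_feasible(theta)) return(theta)
  lo <- 0; hi <- 1
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    cand <- 90 + mid * (theta - 90)
    if (angles_feasible(cand)) lo <- mid else hi <- mid
  }
  90 + lo * (theta - 90)
}

#' Plant a noisy angle triple for a synthetic structure
#'
#' Applies the rule, adds Gaussian noise of s.d. `sigma`, clips to
#' \[5, 175\] and projects to the feasible set.
#'
#' @param layout the `layout` element of [sample_structure()] output.
#' @param sigma noise s.d. in degrees.
#' @param rule the noise-free rule (default [planted_angle_rule()]).
#' @return an `angle_set`.
#' @export
plant_angles <- function(layout, sigma = 5,
                         rule = planted_angle_rule) {
  theta <- rule(layout$seg_nt, layout$gc_frac)
  theta <- theta + stats::rnorm(3, 0, sigma)
  theta <- project_feasible_angles(theta)
  angle_set(theta[1], theta[2], theta[3])
}

# ---- coordinate planting ------------------------------------------------

branch_length_rule <- function(stem_bp) 80 + 2.8 * stem_bp

perp_unit <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- cross3(u, ref)
  w / sqrt(sum(w^2))
}

ring_offsets <- function(n, radius = 0.4) {
  if (n == 1) return(matrix(0, 1, 3))
  a <- 2 * pi * seq_len(n) / n
  cbind(radius * cos(a), radius * sin(a), 0)
}

# plant C4' coordinates for a sampled structure + angle triple such that
# the geometric extraction recovers the planted angles exactly
plant_coordinates <- function(seqlen, layout, angles) {
  s <- layout$stem_bp; lseg <- layout$seg_nt
  hp <- layout$hairpin_nt; ext <- layout$ext_nt
  u <- unit_directions_from_angles(angles)$u
  anchors <- 2 * u
  I <- triangle_incenter(anchors[1, ], anchors[2, ], anchors[3, ])
  # branch length from junction to neighbor loop node; generous so that the
  # 3-decimal PDB coordinate precision cannot perturb planted angles by
  # more than ~1e-4 degrees
  L <- branch_length_rule(s)
  Nk <- sweep(u * L, 2, I, `+`)        # row k = neighbor-node target
  xyz <- matrix(NA_real_, seqlen, 3)
  rise <- 2.8; half_w <- 1.5
  w <- lapply(1:3, function(k) perp_unit(u[k, ]))
  place_stem <- function(i5, j3, bp, k, closing_at_5prime_inner) {
    # pair r (1-based, from the outer pair inward): (i5+r-1, j3-r+1)
    for (r in seq_len(bp)) {
      t <- if (closing_at_5prime_inner) bp - r else r - 1
      mid <- anchors[k, ] + rise * t * u[k, ]
      xyz[i5 + r - 1, ] <<- mid + half_w * w[[k]]
      xyz[j3 - r + 1, ] <<- mid - half_w * w[[k]]
    }
  }
  pos <- 0L
  nxt <- function(n) {
    out <- if (n > 0) (pos + 1L):(pos + n) else integer(0)
    pos <<- pos + n
    out
  }
  i_e5 <- nxt(ext[1])
  i_s1a <- nxt(s[1]); i_sa <- nxt(lseg[1])
  i_s2a <- nxt(s[2]); i_h2 <- nxt(hp[1]); i_s2b <- nxt(s[2])
  i_sb <- nxt(lseg[2])
  i_s3a <- nxt(s[3]); i_h3 <- nxt(hp[2]); i_s3b <- nxt(s[3])
  i_sc <- nxt(lseg[3])
  i_s1b <- nxt(s[1]); i_e3 <- nxt(ext[2])
  stopifnot(pos == seqlen)
  # stems: branch 1 closing pair is its innermost; branches 2/3 outermost
  place_stem(i_s1a[1], i_s1b[s[1]], s[1], 1, TRUE)
  place_stem(i_s2a[1], i_s2b[s[2]], s[2], 2, FALSE)
  place_stem(i_s3a[1], i_s3b[s[3]], s[3], 3, FALSE)
  # external residues: centroid must equal the branch-1 neighbor target
  eidx <- c(i_e5, i_e3)
  off <- ring_offsets(length(eidx))
  xyz[eidx, ] <- rep(Nk[1, ], each = length(eidx)) + off
  # hairpin loops: centroids equal branch-2/3 neighbor targets
  off2 <- ring_offsets(length(i_h2))
  xyz[i_h2, ] <- rep(Nk[2, ], each = length(i_h2)) + off2
  off3 <- ring_offsets(length(i_h3))
  xyz[i_h3, ] <- rep(Nk[3, ], each = length(i_h3)) + off3
  # junction loop segments: near the junction center (position is free)
  midx <- c(i_sa, i_sb, i_sc)
  if (length(midx) > 0)
    xyz[midx, ] <- rep(I, each = length(midx)) +
      ring_offsets(length(midx), radius = 1.0)
  structure(list(xyz = `rownames<-`(xyz, seq_len(seqlen)),
                 resno = seq_len(seqlen)), class = "coord_map")
}

#' Write a C4'-only toy PDB file
#'
#' Minimal but legal PDB: one C4' ATOM record per residue, chain A,
#' 1-based sequential residue numbering.
#'
#' @param sequence RNA sequence string.
#' @param coords a `coord_map` with one coordinate per residue.
#' @param path output file.
#' @export
write_toy_pdb <- function(sequence, coords, path) {
  bases <- strsplit(sequence, "")[[1]]
  xyz <- coords$xyz
  lines <- vapply(seq_along(bases), function(r)
    sprintf("ATOM  %5d  C4' %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            r, bases[r], r, xyz[r, 1], xyz[r, 2], xyz[r, 3]),
    character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- record and dataset generation -------------------------------------

gen_one_record <- function(spec, id) {
  st <- sample_structure(spec)
  angles <- plant_angles(st$layout, spec$sigma)
  coords <- plant_coordinates(nchar(st$sequence), st$layout, angles)
  ss <- parse_dot_bracket(st$db, st$sequence)
  rec <- make_record(ss, truth = matrix(as.numeric(angles), 1))
  rec$id <- id
  rec$sequence <- st$sequence
  rec$db <- st$db
  rec$layout <- st$layout
  rec$angles <- angles
  rec$coords <- coords
  rec$branch_lengths <- branch_length_rule(st$layout$stem_bp)
  rec
}

#' Generate synthetic junction records in memory
#'
#' Deterministic from `spec$seed`. Each record carries the structure, the
#' model-ready features, the planted angle triple and the planted C4'
#' coordinates.
#'
#' @param spec a [synthetic_spec()].
#' @return list of records.
#' @export
generate_junction_records <- function(spec) {
  set.seed(spec$seed)
  lapply(seq_len(spec$count), function(k) gen_one_record(spec, k))
}

#' Generate a synthetic dataset on disk
#'
#' Writes per-record FASTA, dot-bracket and toy PDB files plus a
#' `manifest.csv` (id, file paths, planted angles, branch lengths).
#' Regeneration with the same spec is bit-identical.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created; must not already contain a
#'   manifest).
#' @return the manifest data.frame, invisibly.
#' @export
generate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path))
    stop("output collision: ", manifest_path, " already exists")
  records <- generate_junction_records(spec)
  rows <- lapply(records, function(r) {
    base <- sprintf("synth_%04d", r$id)
    fa <- file.path(dir, paste0(base, ".fasta"))
    dbn <- file.path(dir, paste0(base, ".dbn"))
    pdb <- file.path(dir, paste0(base, ".pdb"))
    writeLines(c(paste0(">", base), r$sequence), fa)
    writeLines(c(paste0(">", base), r$sequence, r$db), dbn)
    write_toy_pdb(r$sequence, r$coords, pdb)
    data.frame(id = base, fasta = basename(fa), dotbracket = basename(dbn),
               structure = basename(pdb),
               theta1 = r$truth[1], theta2 = r$truth[2],
               theta3 = r$truth[3],
               len1 = r$branch_lengths[1], len2 = r$branch_lengths[2],
               len3 = r$branch_lengths[3])
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param manifest_path path to `manifest.csv`.
#' @return list of records with features and ground-truth angles.
#' @export
load_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path)
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(k) {
    v <- read_vienna(file.path(dir, man$dotbracket[k]))
    rec <- make_record(v$ss, truth = matrix(c(man$theta1[k], man$theta2[k],
                                              man$theta3[k]), 1))
    rec$id <- man$id[k]
    rec$structure_file <- file.path(dir, man$structure[k])
    rec
  })
}
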