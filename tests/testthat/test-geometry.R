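test_that("C4' extraction reads toy PDB files and flags gaps", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C4'   G A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C4'   C A   2       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C4'   A A   3       2.000   0.000   0.000  1.00  0.00           C",
    "END"), tmp)
  cm <- read_structure(tmp, "A")
  expect_equal(nrow(cm$xyz), 3L)
  expect_equal(unname(cm$xyz[2, ]), c(1, 0, 0))
  expect_error(read_structure(tmp, "B"), "chain 'B' not found")

  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C4'   G A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  P     C A   2       1.000   0.000   0.000  1.00  0.00           P",
    "ATOM      3  C4'   A A   3       2.000   0.000   0.000  1.00  0.00           C",
    "END"), tmp2)
  expect_warning(cm2 <- read_structure(tmp2, "A"), "lack a C4'")
  expect_equal(nrow(cm2$xyz), 2L)
})

test_that("loop node coordinates are member centroids", {
  cm <- structure(list(xyz = matrix(c(0, 0, 0,
                                      2, 0, 0,
                                      0, 2, 0,
                                      2, 2, 0), 4, 3, byrow = TRUE,
                                    dimnames = list(1:4, NULL)),
                       resno = 1:4), class = "coord_map")
  m1 <- list(id = 1L, kind = "H", segments = list(1:2))
  expect_equal(unname(loop_node_coordinate(m1, cm)), c(1, 0, 0))
  m2 <- list(id = 2L, kind = "H", segments = list(3L))
  expect_equal(unname(loop_node_coordinate(m2, cm)), c(0, 2, 0))
  m4 <- list(id = 3L, kind = "H", segments = list(1:4))
  expect_equal(unname(loop_node_coordinate(m4, cm)), c(1, 1, 0))
  m0 <- list(id = 4L, kind = "H", segments = list(integer(0)))
  expect_error(loop_node_coordinate(m0, cm), "no member residues")
})

test_that("junction anchors are closing-pair midpoints", {
  cm <- structure(list(xyz = matrix(c(0, 0, 0, 0, 2, 0), 2, 3, byrow = TRUE,
                                    dimnames = list(1:2, NULL)),
                       resno = 1:2), class = "coord_map")
  expect_equal(unname(junction_anchor(c(1L, 2L), cm)), c(0, 1, 0))
  expect_error(junction_anchor(c(1L, 5L), cm), "unresolved")
})

test_that("incenter matches the closed-form inradius construction", {
  expect_equal(triangle_incenter(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0)),
               c(1, 1, 0), tolerance = 1e-12)
  # random right triangles: incenter at (r, r) with r = (a + b - c)/2
  set.seed(5)
  for (k in 1:20) {
    a <- runif(1, 1, 9); b <- runif(1, 1, 9)
    r <- (a + b - sqrt(a^2 + b^2)) / 2
    expect_equal(triangle_incenter(c(0, 0, 0), c(a, 0, 0), c(0, b, 0)),
                 c(r, r, 0), tolerance = 1e-9)
  }
  # equilateral: incenter = centroid
  A <- c(0, 0, 0); B <- c(1, 0, 0); C <- c(0.5, sqrt(3) / 2, 0)
  expect_equal(triangle_incenter(A, B, C), (A + B + C) / 3,
               tolerance = 1e-9)
  # translation equivariance
  t0 <- c(3, -2, 7)
  expect_equal(triangle_incenter(A + t0, B + t0, C + t0),
               triangle_incenter(A, B, C) + t0, tolerance = 1e-9)
  expect_error(triangle_incenter(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "degenerate")
})

test_that("angle_between reproduces the dot-product oracle", {
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_between(c(1, 1, 0), c(1, 0, 0)), 45)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "zero-length")
  set.seed(8)
  for (k in 1:25) {
    u <- rnorm(3); v <- rnorm(3)
    expect_equal(angle_between(u, v), oracle_angle(u, v), tolerance = 1e-9)
  }
})

test_that("inter-branch angles follow the (1,2),(2,3),(3,1) convention", {
  node_coords <- rbind(c(1, 0, 0),    # neighbor of branch 1
                       c(0, 0, 0),    # junction
                       c(0, 1, 0),    # branch 2
                       c(0, 0, 1))    # branch 3
  j <- structure(list(node_id = 2L, branches = 1:3,
                      closing_pairs = matrix(1:6, 3, 2),
                      neighbor_nodes = c(1L, 3L, 4L)),
                 class = "three_way_junction")
  a <- compute_inter_branch_angles(j, NULL, node_coords)
  expect_equal(unname(as.numeric(a)), c(90, 90, 90))

  # coplanar symmetric Y
  y <- rbind(c(1, 0, 0), c(0, 0, 0),
             c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
             c(cos(4 * pi / 3), sin(4 * pi / 3), 0))
  a <- compute_inter_branch_angles(j, NULL, y)
  expect_equal(unname(as.numeric(a)), c(120, 120, 120), tolerance = 1e-9)

  # near-antiparallel branches 1 and 2
  z <- rbind(c(1, 0, 0), c(0, 0, 0), c(-1, 1e-9, 0), c(0, 0, 1))
  a <- compute_inter_branch_angles(j, NULL, z)
  expect_equal(a[["theta1"]], 180, tolerance = 1e-6)
  expect_equal(a[["theta2"]], 90, tolerance = 1e-9)
  expect_equal(a[["theta3"]], 90, tolerance = 1e-9)
})

test_that("skeleton reconstruction places branches as specified", {
  st <- reconstruct_skeleton(angle_set(90, 90, 90), c(1, 1, 1))
  expect_equal(unname(st$endpoints),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), tolerance = 1e-12)
  expect_true(st$feasible)

  st <- reconstruct_skeleton(angle_set(60, 60, 60), c(1, 1, 1))
  u <- st$endpoints
  expect_equal(unname(u[3, ]), c(0.5, 0.288675, 0.816497), tolerance = 1e-5)
  expect_equal(sum(u[1, ] * u[2, ]), 0.5, tolerance = 1e-12)
  expect_equal(sum(u[2, ] * u[3, ]), 0.5, tolerance = 1e-12)
  expect_equal(sum(u[3, ] * u[1, ]), 0.5, tolerance = 1e-12)

  st <- reconstruct_skeleton(angle_set(10, 10, 170), c(1, 1, 1))
  expect_false(st$feasible)
  expect_equal(unname(as.numeric(realized_angles(st))), c(10, 10, 20),
               tolerance = 1e-6)
})

test_that("reconstruct -> realized is the identity on feasible triples", {
  set.seed(17)
  for (k in 1:200) {
    a <- random_feasible_angles()
    len <- runif(3, 2, 30)
    st <- reconstruct_skeleton(angle_set(a[1], a[2], a[3]), len)
    expect_true(st$feasible)
    expect_equal(unname(as.numeric(realized_angles(st))), a,
                 tolerance = 1e-6)
    expect_equal(unname(sqrt(rowSums((st$endpoints -
      rep(st$center, each = 3))^2))), len, tolerance = 1e-9)
  }
})

test_that("skeleton RMSD is superposition- and chirality-invariant", {
  set.seed(23)
  st <- reconstruct_skeleton(angle_set(110, 95, 130), c(9, 14, 11))
  expect_equal(skeleton_rmsd(st, st), 0, tolerance = 1e-12)
  for (k in 1:10) {
    moved <- rotate_star(st, random_rotation(), rnorm(3, 0, 20))
    expect_equal(skeleton_rmsd(st, moved), 0, tolerance = 1e-9)
    expect_equal(skeleton_rmsd(moved, st), skeleton_rmsd(st, moved),
                 tolerance = 1e-12)
  }
  mirror <- st
  mirror$endpoints[, 3] <- -mirror$endpoints[, 3]
  expect_equal(skeleton_rmsd(st, mirror), 0, tolerance = 1e-9)
  other <- reconstruct_skeleton(angle_set(60, 80, 100), c(9, 14, 11))
  expect_gt(skeleton_rmsd(st, other), 0.5)
})

test_that("in-house Kabsch agrees with bio3d superposition", {
  set.seed(31)
  for (k in 1:5) {
    P <- matrix(rnorm(12, 0, 5), 4, 3)
    R <- random_rotation()
    Q <- t(apply(P, 1, function(p) as.vector(R %*% p) + c(3, -1, 2))) +
      matrix(rnorm(12, 0, 0.3), 4, 3)
    ours <- rna3wj:::kabsch_rmsd(P, Q)
    ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
    expect_lt(abs(ours - ref), 6e-4)   # bio3d reports 3 decimals
  }
})

test_that("extracted angles are invariant under rigid motion", {
  r <- generate_junction_records(quick_spec(1, 91))[[1]]
  ss <- r$features$tree$ss
  base <- extract_junction_angles(ss, r$coords)
  set.seed(4)
  R <- random_rotation(); t0 <- c(12, -7, 3)
  moved <- r$coords
  moved$xyz <- t(apply(moved$xyz, 1, function(p) as.vector(R %*% p) + t0))
  rownames(moved$xyz) <- rownames(r$coords$xyz)
  got <- extract_junction_angles(ss, moved)
  expect_equal(as.numeric(got[1, c("theta1", "theta2", "theta3")]),
               as.numeric(base[1, c("theta1", "theta2", "theta3")]),
               tolerance = 1e-9)
})

test_that("extracted angle sets satisfy the spherical constraints", {
  recs <- generate_junction_records(quick_spec(10, 77))
  for (r in recs) {
    tab <- extract_junction_angles(r$features$tree$ss, r$coords)
    a <- as.numeric(tab[1, c("theta1", "theta2", "theta3")])
    expect_lte(a[1], a[2] + a[3] + 1e-9)
    expect_lte(a[2], a[3] + a[1] + 1e-9)
    expect_lte(a[3], a[1] + a[2] + 1e-9)
    expect_lte(sum(a), 360 + 1e-9)
  }
})

test_that("degenerate anchor triangles fall back to the centroid", {
  j <- structure(list(node_id = 1L, branches = 1:3,
                      closing_pairs = rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
                      neighbor_nodes = 2:4),
                 class = "three_way_junction")
  xyz <- rbind(c(-1, 0.1, 0), c(1, -0.1, 0),      # midpoint (0,0,0)
               c(1.9, 0.1, 0), c(2.1, -0.1, 0),   # midpoint (2,0,0)
               c(3.9, 0.1, 0), c(4.1, -0.1, 0))   # midpoint (4,0,0)
  cm <- structure(list(xyz = `rownames<-`(xyz, 1:6), resno = 1:6),
                  class = "coord_map")
  expect_warning(ctr <- junction_node_coordinate(j, cm), "degenerate")
  expect_equal(unname(ctr), c(2, 0, 0), tolerance = 1e-12)
})

test_that("skeleton stars export as minimal PDB files", {
  st <- reconstruct_skeleton(angle_set(100, 100, 100), c(5, 6, 7))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_star_pdb(st, tmp)
  cm <- read_structure(tmp, "A")
  expect_equal(nrow(cm$xyz), 4L)
})
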