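test_that("bead counting: bodies and linkers contribute one bead per residue", {
  topo <- simple_topology(n_body = 10, n_linker = 5)
  expect_equal(topo$n, 15)
  expect_length(topo$bodies, 1)
  expect_length(topo$linkers, 1)
  expect_equal(nrow(topo$beads), 15)

  big <- cg_topology(list(list(coords = helix_body(100),
                               residues = rep("LEU", 100))))
  expect_equal(big$n, 100)

  # every bead belongs to exactly one rigid body or one linker
  in_body <- unlist(topo$bodies)
  in_linker <- unlist(topo$linkers)
  expect_setequal(c(in_body, in_linker), seq_len(topo$n))
  expect_length(intersect(in_body, in_linker), 0)
})

test_that("a five-domain layout with four connecting linkers assembles", {
  bodies <- lapply(1:5, function(b) {
    xyz <- helix_body(8)
    xyz[, 1] <- xyz[, 1] + 40 * b
    list(id = paste0("dom", b), coords = xyz, residues = rep("ALA", 8))
  })
  linkers <- lapply(1:4, function(l) {
    list(id = paste0("link", l), sequence = "GSGSGS",
         anchor_start = paste0("dom", l, ":8"),
         anchor_end = paste0("dom", l + 1, ":1"))
  })
  topo <- cg_topology(bodies, linkers, stoichiometry = "1:1")
  expect_length(topo$bodies, 5)
  expect_length(topo$linkers, 4)
  expect_equal(topo$n, 5 * 8 + 4 * 6)
  # anchors reference existing beads on the right units
  expect_true(all(topo$anchor_start %in% unlist(topo$bodies)))
  expect_true(all(topo$anchor_end %in% unlist(topo$bodies)))
})

test_that("unknown anchors and residues are rejected with informative errors", {
  expect_error(
    cg_topology(list(list(coords = helix_body(5), residues = rep("ALA", 5))),
                list(list(sequence = "GG", anchor_start = "body1:99"))),
    "not found")
  expect_error(
    cg_topology(list(list(coords = helix_body(5), residues = rep("XYZ", 5)))),
    "unknown residue")
  expect_error(conformation(matrix(0, 4, 3), simple_topology()), "beads")
})

test_that("radius of gyration matches closed forms", {
  same <- matrix(1.5, 4, 3)
  expect_equal(radius_of_gyration(same), 0)
  expect_equal(radius_of_gyration(pair_coords(10)), 5.0)
  # uniform sphere: Rg = sqrt(3/5) R
  pts <- sphere_fill(1000, 30, seed = 42)
  expect_equal(radius_of_gyration(pts), sqrt(3 / 5) * 30, tolerance = 0.02)
})

test_that("maximum extension equals the brute-force pair maximum", {
  line <- cbind(seq(0, 270, length.out = 10), 0, 0)
  expect_equal(maximum_extension(line), 270)
  tri <- 7 * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(maximum_extension(tri), 7)
  set.seed(7)
  pts <- matrix(rnorm(150, sd = 20), 50, 3)
  brute <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    brute <- max(brute, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  }
  expect_equal(maximum_extension(pts), brute)
  expect_warning(d1 <- maximum_extension(matrix(1, 1, 3)), "single bead")
  expect_equal(d1, 0)
})

test_that("Rg and Dmax are invariant under global rigid motions", {
  set.seed(11)
  pts <- matrix(rnorm(90, sd = 15), 30, 3)
  for (rep in 1:5) {
    moved <- random_rigid_transform(pts)
    expect_equal(radius_of_gyration(moved), radius_of_gyration(pts),
                 tolerance = 1e-9)
    expect_equal(maximum_extension(moved), maximum_extension(pts),
                 tolerance = 1e-9)
  }
})

test_that("rigid-body pose updates preserve internal distances", {
  topo <- simple_topology()
  x0 <- topo$init_coords
  idx <- topo$bodies[[1]]
  d0 <- dist(x0[idx, ])
  set.seed(3)
  for (rep in 1:5) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    x1 <- set_body_pose(x0, topo, 1, q, rnorm(3, 0, 30))
    expect_equal(as.vector(dist(x1[idx, ])), as.vector(d0),
                 tolerance = 1e-6)
  }
  expect_error(set_body_pose(x0, topo, 1, c(1, 1, 0, 0)), "unit norm")
})

test_that("linkers initialize in extended geometry at the bond length", {
  topo <- simple_topology(n_body = 6, n_linker = 8)
  idx <- topo$linkers[[1]]
  x <- topo$init_coords
  steps <- sqrt(rowSums(diff(x[c(topo$anchor_start[1], idx), ])^2))
  expect_equal(steps, rep(topo$bond_length, 8), tolerance = 1e-9)
})

test_that("build_topology reads PDB-declared bodies and flags missing residues", {
  xyz <- helix_body(12)
  ref <- cg_topology(list(list(coords = xyz, residues = rep("GLY", 12))))
  f <- tempfile(fileext = ".pdb")
  write_pdb(conformation(xyz), f, ref)
  spec <- list(bodies = list(list(id = "b", file = f, residues = "1-12")))
  topo <- build_topology(spec)
  expect_equal(topo$n, 12)
  expect_equal(unname(topo$init_coords), unname(xyz), tolerance = 1e-3)

  bad <- list(bodies = list(list(id = "b", file = f, residues = "1-15")))
  expect_error(build_topology(bad), "missing")
})
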