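test_that("bonded energy vanishes in the ground-state chain and matches hand values", {
  m <- energy_model(torsion_k = 0)
  # free 6-bead chain whose bonds are all b0 and angles all theta0
  topo <- cg_topology(
    bodies = list(list(coords = matrix(c(0, 500, 0), 1), residues = "GLY")),
    linkers = list(list(sequence = "GGGGGG"))
  )
  x <- topo$init_coords
  x[topo$linkers[[1]], ] <- zigzag_chain(6, m$bond_length, m$angle_0)
  expect_equal(bonded_energy(x, topo, m), 0, tolerance = 1e-9)

  # single bond stretched by 1 A with k = 10 -> 1/2 * 10 * 1^2
  topo2 <- cg_topology(
    bodies = list(list(coords = matrix(c(0, 500, 0), 1), residues = "GLY")),
    linkers = list(list(sequence = "GG"))
  )
  x2 <- topo2$init_coords
  x2[topo2$linkers[[1]], ] <- rbind(c(0, 0, 0), c(m$bond_length + 1, 0, 0))
  expect_equal(bonded_energy(x2, topo2, m), 5.0)
})

test_that("bonded energy of a random chain equals the term-by-term oracle", {
  set.seed(21)
  topo <- simple_topology(n_body = 4, n_linker = 6)
  m <- energy_model()  # torsions on
  for (rep in 1:5) {
    x <- topo$init_coords
    idx <- topo$linkers[[1]]
    x[idx, ] <- x[idx, ] + matrix(rnorm(length(idx) * 3, 0, 1.5),
                                  length(idx), 3)
    expect_equal(bonded_energy(x, topo, m), bonded_oracle(x, topo, m),
                 tolerance = 1e-10)
  }
})

test_that("nonbonded terms follow the closed forms", {
  m <- energy_model()
  topo <- pair_topology("SER", "SER")      # neutral, h = 0 residues
  # beyond the contact range: exactly zero
  expect_equal(as.numeric(nonbonded_energy(pair_coords(9), topo, m)), 0)
  # inside the well: -eps_ij
  e_in <- nonbonded_energy(pair_coords(6), topo, m)
  expect_equal(attr(e_in, "contact"), -m$contact_eps[16, 16])
  expect_equal(attr(e_in, "electrostatic"), 0)

  # two +1 charges at r = debye length: screened Coulomb x exp(-1)
  topo_pp <- pair_topology("ARG", "LYS")
  r <- m$debye_length
  e <- nonbonded_energy(pair_coords(r), topo_pp, m)
  expect_equal(attr(e, "electrostatic"),
               332.0637 * exp(-1) / (m$dielectric * r), tolerance = 1e-12)

  # opposite charges attract
  topo_pm <- pair_topology("ARG", "GLU")
  expect_lt(attr(nonbonded_energy(pair_coords(r), topo_pm, m),
                 "electrostatic"), 0)
})

test_that("doubling all charges quadruples the electrostatic component", {
  set.seed(5)
  topo <- cg_topology(list(
    list(coords = matrix(rnorm(15, sd = 6), 5), residues = c("ARG", "GLU", "LYS", "ASP", "SER")),
    list(coords = matrix(rnorm(15, sd = 6) + 12, 5), residues = c("LYS", "LYS", "GLU", "ALA", "ARG"))
  ))
  m <- energy_model()
  x <- topo$init_coords
  e1 <- attr(nonbonded_energy(x, topo, m), "electrostatic")
  topo2 <- topo
  topo2$charge <- topo$charge * 2
  e2 <- attr(nonbonded_energy(x, topo2, m), "electrostatic")
  expect_equal(e2, 4 * e1, tolerance = 1e-12)

  # zero-charge system: exactly zero
  topo0 <- topo
  topo0$charge <- topo$charge * 0
  expect_identical(attr(nonbonded_energy(x, topo0, m), "electrostatic"), 0)
})

test_that("energy stays finite for overlapping beads", {
  topo <- pair_topology()
  m <- energy_model()
  e <- as.numeric(nonbonded_energy(pair_coords(0.01), topo, m))
  expect_true(is.finite(e))
  expect_gt(e, 1e3)   # large repulsive, no singularity
})

test_that("membrane terms follow the restraint arithmetic", {
  topo <- cg_topology(
    bodies = list(list(coords = matrix(c(0, 0, 20), 1), residues = "CYS")),
    restraints = list(list(bead = "body1:1", z = 20, k = 0.1))
  )
  m <- energy_model()
  x <- topo$init_coords
  expect_equal(attr(membrane_energy(x, topo, m), "restraint"), 0)
  x[1, 3] <- 25
  expect_equal(attr(membrane_energy(x, topo, m), "restraint"), 1.25)

  # all beads far above the plane, no restraints -> exactly zero
  topo2 <- pair_topology()
  x2 <- pair_coords(10)
  x2[, 3] <- 500
  expect_equal(as.numeric(membrane_energy(x2, topo2, m)), 0)
})

test_that("total energy respects the symmetries of the model", {
  set.seed(31)
  tc <- make_toy_complex(seed = 8, beads_per_body = 12, linker_length = 6)
  topo <- tc$topology
  m <- energy_model()
  x <- tc$conformation$coords
  e0 <- total_energy(x, topo, m, membrane = FALSE)
  # membrane off: invariant under any global rigid motion
  for (rep in 1:3) {
    expect_equal(as.numeric(total_energy(random_rigid_transform(x), topo, m)),
                 as.numeric(e0), tolerance = 1e-6)
  }
  # membrane on: invariant under x,y translation and rotation about z
  xm <- x
  xm[, 3] <- xm[, 3] - min(xm[, 3]) + 25
  em <- total_energy(xm, topo, m, membrane = TRUE)
  phi <- 1.1
  Rz <- matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  xt <- xm %*% t(Rz)
  xt[, 1] <- xt[, 1] + 40
  xt[, 2] <- xt[, 2] - 17
  expect_equal(as.numeric(total_energy(xt, topo, m, membrane = TRUE)),
               as.numeric(em), tolerance = 1e-6)
})

test_that("contact matrices are validated and round-trip through text files", {
  expect_error(energy_model(contact_eps = matrix(0, 19, 19)), "20 x 20")
  bad <- default_contact_matrix()
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(energy_model(contact_eps = bad), "symmetric")

  f <- tempfile(fileext = ".txt")
  cm <- default_contact_matrix()
  write.table(cm, f, row.names = FALSE, col.names = FALSE)
  expect_equal(unname(read_contact_matrix(f)), unname(cm), tolerance = 1e-12)
  m <- build_energy_model(list(contact_matrix_file = f, debye_length = 8))
  expect_equal(m$debye_length, 8)
})
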