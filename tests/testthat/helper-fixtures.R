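# Shared fixtures and independent oracles, all built in code.

# a single rigid helix-like body of n beads along a gentle spiral
helix_body <- function(n, rise = 1.5, radius = 2.3) {
  t <- seq_len(n)
  cbind(radius * cos(t * 100 * pi / 180),
        radius * sin(t * 100 * pi / 180),
        rise * t)
}

# one body + one anchored linker, small enough for hand checks
simple_topology <- function(n_body = 10, n_linker = 5) {
  cg_topology(
    bodies = list(list(id = "helix", coords = helix_body(n_body),
                       residues = rep("ALA", n_body))),
    linkers = list(list(id = "tail", sequence = strrep("G", n_linker),
                        anchor_start = paste0("helix:", n_body)))
  )
}

# two single-bead "bodies" with chosen residues/positions: the minimal
# system for nonbonded-pair checks (intra-body and bonded exclusions empty)
pair_topology <- function(res_a = "SER", res_b = "SER") {
  cg_topology(bodies = list(
    list(id = "a", coords = matrix(c(0, 0, 0), 1), residues = res_a),
    list(id = "b", coords = matrix(c(10, 0, 0), 1), residues = res_b)
  ))
}

pair_coords <- function(r) matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE)

# independent Debye double-loop oracle (never vectorised)
debye_oracle <- function(xyz, q, f = rep(1, nrow(xyz))) {
  n <- nrow(xyz)
  sapply(q, function(qq) {
    s <- 0
    for (i in 1:n) for (j in 1:n) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sinc <- if (qq * r == 0) 1 else sin(qq * r) / (qq * r)
      s <- s + f[i] * f[j] * sinc
    }
    s
  })
}

# independent term-by-term bonded-energy oracle
bonded_oracle <- function(xyz, topo, model) {
  e <- 0
  b0 <- model$bond_length
  for (k in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds[k, 1]; j <- topo$bonds[k, 2]
    e <- e + 0.5 * model$bond_k * (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) - b0)^2
  }
  for (k in seq_len(nrow(topo$angles))) {
    a <- topo$angles[k, 1]; b <- topo$angles[k, 2]; c <- topo$angles[k, 3]
    v1 <- xyz[a, ] - xyz[b, ]; v2 <- xyz[c, ] - xyz[b, ]
    th <- acos(max(-1, min(1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2)))))
    e <- e + 0.5 * model$angle_k * (th - model$angle_0)^2
  }
  for (k in seq_len(nrow(topo$torsions))) {
    ii <- topo$torsions[k, ]
    b1 <- xyz[ii[2], ] - xyz[ii[1], ]
    b2 <- xyz[ii[3], ] - xyz[ii[2], ]
    b3 <- xyz[ii[4], ] - xyz[ii[3], ]
    n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
    m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    e <- e + model$torsion_k * (1 + cos(phi))
  }
  e
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# zig-zag chain whose every bond is b0 and every internal angle theta0:
# the bonded ground state when the torsion amplitude is zero
zigzag_chain <- function(n, b0, theta0) {
  xyz <- matrix(0, n, 3)
  dir_angle <- 0
  for (i in 2:n) {
    xyz[i, ] <- xyz[i - 1, ] + b0 * c(cos(dir_angle), sin(dir_angle), 0)
    dir_angle <- dir_angle + (pi - theta0) * (-1)^i
  }
  xyz
}

random_rigid_transform <- function(xyz) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  c_ <- cos(ang); s_ <- sin(ang)
  x <- ax[1]; y <- ax[2]; z <- ax[3]
  R <- matrix(c(c_ + x^2 * (1 - c_), x * y * (1 - c_) - z * s_, x * z * (1 - c_) + y * s_,
                y * x * (1 - c_) + z * s_, c_ + y^2 * (1 - c_), y * z * (1 - c_) - x * s_,
                z * x * (1 - c_) - y * s_, z * y * (1 - c_) + x * s_, c_ + z^2 * (1 - c_)),
              3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, rnorm(3, 0, 50), `+`)
}

# dense lattice-filled sphere: a near-continuum bead model whose Rg is the
# closed-form sqrt(3/5) R to a fraction of a percent
lattice_sphere <- function(radius = 30, spacing = 3.5) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(g, g, g))
  unname(pts[rowSums(pts^2) <= radius^2, ])
}

# uniformly bead-filled sphere (for closed-form Rg checks)
sphere_fill <- function(n, radius, seed = 1) {
  set.seed(seed)
  pts <- matrix(runif(3 * n * 3, -radius, radius), ncol = 3)
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  while (nrow(pts) < n) {
    more <- matrix(runif(3 * n, -radius, radius), ncol = 3)
    pts <- rbind(pts, more[rowSums(more^2) <= radius^2, , drop = FALSE])
  }
  pts[seq_len(n), ]
}

# a single bead held by a harmonic z-restraint: the enumerable toy system
# for Boltzmann checks (harmonic well, k in kcal/mol/A^2)
harmonic_bead_topology <- function(k = 1) {
  cg_topology(
    bodies = list(list(id = "bead", coords = matrix(0, 1, 3),
                       residues = "GLY")),
    restraints = list(list(bead = "bead:1", z = 0, k = k))
  )
}

# membrane-off harmonic sampling: push the membrane plane far away and
# zero all surface terms so only the z-restraint acts
harmonic_model <- function() {
  energy_model(mem_eps = rep(0, 20), z_membrane = -1e6, torsion_k = 0)
}
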