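# Synthetic data: toy rigid-body/linker complexes, conformational pools and
# noisy SAXS "experiments" generated from known structures or ensembles, so
# the whole pipeline (sampling -> profiles -> selection -> clustering) can
# be exercised end to end with a known ground truth.

#' Build a toy dumbbell complex
#'
#' A deterministic toy topology: `n_bodies` rigid bodies, each a seeded
#' random bead cloud filling a sphere, joined in a chain by flexible
#' linkers. The geometry preset controls the reference conformation:
#' `"compact"` places consecutive bodies close together, `"extended"`
#' stretches the linkers to near-maximal span. This dumbbell echoes the
#' compact/extended dichotomy typical of flexible two-domain complexes.
#'
#' @param n_bodies number of rigid bodies (>= 1).
#' @param beads_per_body beads per body (> 0).
#' @param linker_length beads per connecting linker.
#' @param preset `"compact"` or `"extended"`.
#' @param seed RNG seed; fully determines the output.
#' @param membrane_anchors if TRUE, adds a soft harmonic membrane restraint
#'   (z target 20 A, k 0.1 kcal/mol/A^2) on one bead of the first and last
#'   body, and places the reference conformation above the membrane plane.
#' @return List with `topology` (a [cg_topology]) and `conformation` (the
#'   reference [conformation]).
#' @export
make_toy_complex <- function(n_bodies = 2, beads_per_body = 30,
                             linker_length = 12,
                             preset = c("compact", "extended"),
                             seed = 1, membrane_anchors = FALSE) {
  preset <- match.arg(preset)
  if (n_bodies < 1 || beads_per_body < 1) abort("zero-size bodies")
  set.seed(seed)
  radius <- 2.5 * beads_per_body^(1 / 3)
  clouds <- lapply(seq_len(n_bodies), function(b) sphere_cloud(beads_per_body, radius))
  gap <- if (preset == "compact") 8 else 0.95 * 3.8 * (linker_length + 1)
  seqpool <- rep(.aa1, length.out = beads_per_body)

  bodies <- list()
  linkers <- list()
  cx <- 0
  for (b in seq_len(n_bodies)) {
    xyz <- clouds[[b]]
    xyz[, 1] <- xyz[, 1] + cx
    bodies[[b]] <- list(id = paste0("body", b), coords = xyz,
                        residues = seqpool)
    if (b < n_bodies) {
      # anchor on the facing extremes of consecutive bodies
      a1 <- paste0("body", b, ":", which.max(xyz[, 1]))
      cx <- cx + 2 * radius + gap
      a2 <- paste0("body", b + 1, ":", which.min(clouds[[b + 1]][, 1]))
      linkers[[b]] <- list(id = paste0("linker", b),
                           sequence = paste(rep(c("G", "S", "K", "T"),
                                                length.out = linker_length),
                                            collapse = ""),
                           anchor_start = a1, anchor_end = a2)
    }
  }
  restraints <- list()
  if (membrane_anchors) {
    # anchor the most peripheral bead of the first and last body: a
    # lipid-anchored residue must be surface-exposed, and an interior bead
    # could never reach the membrane plane past the excluded-volume wall
    peripheral <- function(b) {
      xyz <- clouds[[b]]
      which.max(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
    }
    restraints <- list(
      list(bead = paste0("body1:", peripheral(1)), z = 20, k = 0.1),
      list(bead = paste0("body", n_bodies, ":", peripheral(n_bodies)),
           z = 20, k = 0.1)
    )
  }
  topo <- cg_topology(bodies, linkers, restraints,
                      stoichiometry = paste(rep(1, n_bodies), collapse = ":"))
  if (membrane_anchors) {
    # lift the reference conformation above the membrane plane
    topo$init_coords[, 3] <- topo$init_coords[, 3] -
      min(topo$init_coords[, 3]) + 21
  }
  list(topology = topo,
       conformation = conformation(topo$init_coords, topo))
}

# seeded bead cloud roughly uniform in a sphere, with a minimal-separation
# relaxation so beads do not start deeply overlapped
sphere_cloud <- function(n, radius, min_sep = 3.4) {
  pts <- matrix(0, n, 3)
  k <- 1
  tries <- 0
  while (k <= n) {
    p <- runif(3, -radius, radius)
    tries <- tries + 1
    if (sum(p^2) > radius^2) next
    if (k > 1 && tries < 200 * n) {
      d2 <- rowSums((pts[seq_len(k - 1), , drop = FALSE] -
                       matrix(p, k - 1, 3, byrow = TRUE))^2)
      if (min(d2) < min_sep^2) next
    }
    pts[k, ] <- p
    k <- k + 1
  }
  pts
}

#' Synthesize a noisy SAXS "experiment" from a known ensemble
#'
#' Computes the weighted Debye intensity of the given conformations and
#' adds Gaussian noise of standard deviation `sigma(q) = alpha + beta *
#' I(q)` (a multiplicative-plus-floor model standing in for a
#' beamline-determined error profile). The sigma column records the
#' generating standard deviation truthfully; when `alpha = beta = 0` no
#' noise is added and unit errors are recorded (zero errors would be
#' degenerate in the chi-square).
#'
#' @param conformations list of conformations / coordinate matrices.
#' @param weights ensemble weights (normalized, non-negative).
#' @param q momentum-transfer grid.
#' @param alpha,beta noise model parameters (>= 0).
#' @param seed noise seed.
#' @param form_factors see [debye_intensity()].
#' @return A [saxs_profile] with sigma.
#' @export
synthesize_saxs <- function(conformations, weights = NULL, q,
                            alpha = 0, beta = 0.01, seed = 1,
                            form_factors = 1) {
  if (alpha < 0 || beta < 0) abort("noise parameters must be >= 0")
  if (inherits(conformations, "cg_conformation") ||
      is.matrix(conformations)) {
    conformations <- list(conformations)
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(conformations), length(conformations))
  }
  profs <- lapply(conformations, debye_intensity, q = q,
                  form_factors = form_factors)
  ens <- ensemble_intensity(profs, weights)
  sig <- alpha + beta * ens$intensity
  if (all(sig == 0)) {
    return(saxs_profile(q, ens$intensity, rep(1, length(q))))
  }
  if (any(sig <= 0)) abort("noise model produced non-positive sigma")
  set.seed(seed)
  saxs_profile(q, ens$intensity + rnorm(length(q), 0, sig), sig)
}

#' Two-state ensemble-recovery fixture
#'
#' Builds a pool of toy-dumbbell conformations containing one designated
#' compact and one designated extended structure (pool ids 1 and 2) plus
#' decoys sampled around each of them by seeded Gaussian pose kicks, and a
#' target profile synthesized from the 50/50 mixture of the two designated
#' structures with multiplicative noise. The returned truth ids make
#' ensemble-recovery tests possible: a correct minimum-ensemble search
#' should return exactly the pair (1, 2) with equal weights.
#'
#' @param seed master seed; fully determines pool, decoys and noise.
#' @param n_pool total pool size (default 200).
#' @param q target q grid (default 80 points over 0.01-0.30 1/A).
#' @param beta multiplicative noise level (default 0.01, i.e. 1%).
#' @param kick_translation,kick_rotation decoy pose-kick scales
#'   (A / rad; defaults 6 and 0.35).
#' @return List with `pool` (a `cg_pool`), `target` (a [saxs_profile]),
#'   `truth` (ids 1:2), `weights` (c(0.5, 0.5)) and the `topology`.
#' @export
two_state_fixture <- function(seed = 1, n_pool = 200,
                              q = seq(0.01, 0.30, length.out = 80),
                              beta = 0.01,
                              kick_translation = 6, kick_rotation = 0.35) {
  compact <- make_toy_complex(preset = "compact", seed = seed)
  extended <- make_toy_complex(preset = "extended", seed = seed)
  topo <- compact$topology
  truth <- list(compact$conformation$coords, extended$conformation$coords)

  set.seed(seed + 104729)
  confs <- vector("list", n_pool)
  confs[[1]] <- truth[[1]]
  confs[[2]] <- truth[[2]]
  for (k in seq_len(n_pool)[-(1:2)]) {
    base <- truth[[1 + k %% 2]]
    confs[[k]] <- kick_pose(base, topo, kick_translation, kick_rotation)
  }
  target <- synthesize_saxs(truth, c(0.5, 0.5), q, alpha = 0, beta = beta,
                            seed = seed + 224737)
  list(pool = cg_pool(confs, topo), target = target, truth = 1:2,
       weights = c(0.5, 0.5), topology = topo)
}

# perturb every rigid-body pose and re-seat the linkers. Because the
# orientation-averaged profile senses mainly the inter-body distance, the
# translation kick always carries a radial component of at least
# `trans_sd`/2 (and at most ~3x it) along the separation axis, so every
# decoy is guaranteed to differ from its base state in a way the
# scattering can see; smaller perpendicular and rotational jitter is added
# on top.
kick_pose <- function(coords, topology, trans_sd, rot_sd) {
  x <- coords
  ctr1 <- colMeans(x[topology$bodies[[1]], , drop = FALSE])
  for (b in seq_along(topology$bodies)) {
    idx <- topology$bodies[[b]]
    ctr <- colMeans(x[idx, , drop = FALSE])
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- rnorm(1, 0, rot_sd)
    rel <- sweep(x[idx, , drop = FALSE], 2, ctr)
    R <- rotation_matrix(ax, ang)
    if (b == 1) {
      shift <- c(0, 0, 0)
    } else {
      u <- ctr - ctr1
      u <- u / sqrt(sum(u^2))
      radial <- sample(c(-1, 1), 1) * runif(1, trans_sd / 2, 3 * trans_sd)
      perp <- rnorm(3, 0, trans_sd / 2)
      perp <- perp - sum(perp * u) * u
      shift <- radial * u + perp
    }
    x[idx, ] <- rel %*% t(R) +
      matrix(ctr + shift, length(idx), 3, byrow = TRUE)
  }
  for (l in seq_along(topology$linkers)) {
    idx <- topology$linkers[[l]]
    x[idx, ] <- extend_linker(x, topology$bodies, topology$body_id,
                              topology$anchor_start[l],
                              topology$anchor_end[l],
                              length(idx), topology$bond_length, l)
    x[idx, ] <- x[idx, ] + matrix(rnorm(3 * length(idx), 0, 1),
                                  length(idx), 3)
  }
  x
}

rotation_matrix <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(c_ + x^2 * (1 - c_), x * y * (1 - c_) - z * s_, x * z * (1 - c_) + y * s_,
           y * x * (1 - c_) + z * s_, c_ + y^2 * (1 - c_), y * z * (1 - c_) - x * s_,
           z * x * (1 - c_) - y * s_, z * y * (1 - c_) + x * s_, c_ + z^2 * (1 - c_)),
         3, 3, byrow = TRUE)
}
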