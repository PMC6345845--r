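# Coarse-grained topology: rigid bodies (one bead per residue at the C-alpha
# position) plus flexible linker chains of amino-acid beads, with the bonded
# terms (bonds, angles, torsions) that run along each linker chain.

#' Assemble a coarse-grained rigid-body + linker topology
#'
#' Builds the simulated object: an ordered set of residue beads partitioned
#' into rigid bodies (whose internal geometry is fixed) and flexible linker
#' chains (bonded bead chains with bending and torsional terms). Beads are
#' numbered bodies first, in the order given, then linker chains.
#'
#' @param bodies list of rigid-body specs, each a list with `coords`
#'   (n x 3 matrix of C-alpha positions, Angstrom) and `residues`
#'   (length-n residue codes, 1- or 3-letter), plus an optional `id`.
#'   Alternatively each spec may name a PDB `file` with optional `chain`
#'   and `residues` range string (e.g. `"130-423,522-816"`); see
#'   [read_pdb()].
#' @param linkers list of linker specs, each a list with `sequence` (string
#'   of 1-letter codes or vector of codes), and optional `anchor_start` /
#'   `anchor_end` giving the bead the chain is attached to, as
#'   `"<unit id>:<position>"` (body: residue number; for bodies read from
#'   PDB the crystallographic residue number) or a global bead index.
#' @param restraints optional list of membrane restraints, each a list with
#'   `bead` (same addressing as anchors), `z` (target z, Angstrom) and `k`
#'   (spring constant, kcal/mol/A^2; default 0.1).
#' @param stoichiometry free-text stoichiometry label (e.g. `"2:1:1"`).
#' @param his_charge formal charge for His beads (default 0).
#' @param bond_length linker C-alpha spacing used for the extended initial
#'   geometry, Angstrom (default 3.8).
#'
#' @return An object of class `cg_topology`: a list with the bead table
#'   (`beads`, a tibble), per-bead vectors (`body_id`, `charge`, `rtype`),
#'   rigid-body and linker index lists, bonded-term index matrices, the
#'   membrane `restraints` matrix, and the initial coordinates
#'   (`init_coords`, linkers in extended geometry).
#' @export
cg_topology <- function(bodies, linkers = list(), restraints = list(),
                        stoichiometry = NA_character_, his_charge = 0,
                        bond_length = 3.8) {
  if (length(bodies) < 1) abort("at least one rigid body is required")
  aat <- amino_acid_table(his_charge)

  unit_ids <- character(0)
  coords_list <- list()
  rtypes <- integer(0)
  body_members <- list()
  body_labels <- integer(0)     # per-bead body id (0 = linker)
  resno_list <- list()          # per-unit residue numbers for addressing
  offset <- 0L

  for (b in seq_along(bodies)) {
    spec <- bodies[[b]]
    if (!is.null(spec$file)) {
      pdb <- read_pdb(spec$file, chain = spec$chain, residues = spec$residues)
      spec$coords <- pdb$coords[[1]]
      spec$residues <- pdb$atoms$resid
      resno <- pdb$atoms$resno
    } else {
      resno <- seq_len(nrow(spec$coords))
    }
    xyz <- as.matrix(spec$coords)
    if (ncol(xyz) != 3 || nrow(xyz) < 1) abort("body coords must be n x 3")
    if (!all(is.finite(xyz))) abort("body coordinates must be finite")
    nb <- nrow(xyz)
    id <- if (!is.null(spec$id)) spec$id else paste0("body", b)
    unit_ids <- c(unit_ids, id)
    coords_list[[length(coords_list) + 1L]] <- xyz
    rtypes <- c(rtypes, aa_type(spec$residues))
    body_members[[b]] <- offset + seq_len(nb)
    body_labels <- c(body_labels, rep(b, nb))
    resno_list[[id]] <- setNames(offset + seq_len(nb), resno)
    offset <- offset + nb
  }

  linker_members <- list()
  anchor_start <- integer(0)
  anchor_end <- integer(0)
  linker_seqs <- list()
  for (l in seq_along(linkers)) {
    spec <- linkers[[l]]
    seq_codes <- spec$sequence
    if (length(seq_codes) == 1 && nchar(seq_codes[1]) > 1) {
      seq_codes <- strsplit(seq_codes, "")[[1]]
    }
    nl <- length(seq_codes)
    if (nl < 1) abort("linker sequence must be non-empty")
    id <- if (!is.null(spec$id)) spec$id else paste0("linker", l)
    unit_ids <- c(unit_ids, id)
    linker_members[[l]] <- offset + seq_len(nl)
    body_labels <- c(body_labels, rep(0L, nl))
    rtypes <- c(rtypes, aa_type(seq_codes))
    linker_seqs[[l]] <- seq_codes
    resno_list[[id]] <- offset + seq_len(nl)
    names(resno_list[[id]]) <- seq_len(nl)
    anchor_start <- c(anchor_start,
                      resolve_bead(spec$anchor_start, resno_list, "anchor_start"))
    anchor_end <- c(anchor_end,
                    resolve_bead(spec$anchor_end, resno_list, "anchor_end"))
    offset <- offset + nl
  }

  n <- offset
  charge <- aat$charge[rtypes]

  # initial coordinates: bodies as given, linkers in extended geometry
  init <- matrix(NA_real_, n, 3)
  for (b in seq_along(body_members)) init[body_members[[b]], ] <- coords_list[[b]]
  for (l in seq_along(linker_members)) {
    idx <- linker_members[[l]]
    init[idx, ] <- extend_linker(init, body_members, body_labels,
                                 anchor_start[l], anchor_end[l],
                                 length(idx), bond_length, l)
  }

  bonded <- linker_bonded_terms(linker_members, anchor_start, anchor_end)

  rmat <- matrix(numeric(0), 0, 3,
                 dimnames = list(NULL, c("bead", "z", "k")))
  if (length(restraints) > 0) {
    rmat <- do.call(rbind, lapply(restraints, function(r) {
      c(resolve_bead(r$bead, resno_list, "restraint bead"),
        r$z, if (!is.null(r$k)) r$k else 0.1)
    }))
    colnames(rmat) <- c("bead", "z", "k")
    if (any(rmat[, "bead"] < 1 | rmat[, "bead"] > n)) {
      abort("restrained bead index outside topology")
    }
  }

  unit_vec <- character(n)
  for (b in seq_along(body_members)) unit_vec[body_members[[b]]] <- unit_ids[b]
  for (l in seq_along(linker_members)) {
    unit_vec[linker_members[[l]]] <- unit_ids[length(body_members) + l]
  }
  beads <- tibble(
    index = seq_len(n),
    residue = .aa3[rtypes],
    type = rtypes,
    charge = charge,
    unit = unit_vec,
    body = body_labels
  )

  structure(list(
    n = n,
    beads = beads,
    body_id = body_labels,
    charge = charge,
    rtype = rtypes,
    bodies = body_members,
    body_ids = unit_ids[seq_along(body_members)],
    body_ref = lapply(seq_along(body_members), function(b) {
      xyz <- coords_list[[b]]
      sweep(xyz, 2, colMeans(xyz))
    }),
    linkers = linker_members,
    linker_seqs = linker_seqs,
    anchor_start = anchor_start,
    anchor_end = anchor_end,
    bonds = bonded$bonds,
    angles = bonded$angles,
    torsions = bonded$torsions,
    restraints = rmat,
    stoichiometry = stoichiometry,
    bond_length = bond_length,
    init_coords = init
  ), class = "cg_topology")
}

# "unit:pos" / global integer / NULL -> global bead index (0 = none)
resolve_bead <- function(x, resno_list, what) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) return(0L)
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    abort(paste0(what, " must be 'unit:position' or a bead index, got '", x, "'"))
  }
  unit <- parts[1]
  if (is.null(resno_list[[unit]])) {
    abort(paste0(what, ": unknown unit '", unit, "'"))
  }
  hit <- resno_list[[unit]][parts[2]]
  if (is.na(hit)) {
    abort(paste0(what, ": residue ", parts[2], " not found in unit '", unit, "'"))
  }
  as.integer(hit)
}

# extended initial geometry for one linker chain
extend_linker <- function(init, body_members, body_labels, a_start, a_end,
                          nl, b0, lidx) {
  if (a_start > 0 && a_end > 0) {
    p0 <- init[a_start, ]
    p1 <- init[a_end, ]
    tt <- seq_len(nl) / (nl + 1)
    return(cbind(p0[1] + tt * (p1[1] - p0[1]),
                 p0[2] + tt * (p1[2] - p0[2]),
                 p0[3] + tt * (p1[3] - p0[3])))
  }
  if (a_start > 0 || a_end > 0) {
    a <- max(a_start, a_end)
    p0 <- init[a, ]
    body <- body_labels[a]
    ctr <- colMeans(init[body_members[[body]], , drop = FALSE])
    dir <- p0 - ctr
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) dir <- c(1, 0, 0) else dir <- dir / nrm
    steps <- if (a_start > 0) seq_len(nl) else rev(seq_len(nl))
    return(t(sapply(steps, function(i) p0 + i * b0 * dir)))
  }
  # free chain: straight line offset from the assembly
  y0 <- max(init[, 2], na.rm = TRUE) + 10 * lidx
  cbind(seq_len(nl) * b0, rep(y0, nl), rep(0, nl))
}

# bonds / angles / torsions along each linker chain, anchors included
linker_bonded_terms <- function(linker_members, anchor_start, anchor_end) {
  bonds <- matrix(integer(0), 0, 2)
  angles <- matrix(integer(0), 0, 3)
  torsions <- matrix(integer(0), 0, 4)
  for (l in seq_along(linker_members)) {
    chain <- linker_members[[l]]
    if (anchor_start[l] > 0) chain <- c(anchor_start[l], chain)
    if (anchor_end[l] > 0) chain <- c(chain, anchor_end[l])
    m <- length(chain)
    if (m >= 2) bonds <- rbind(bonds, cbind(chain[-m], chain[-1]))
    if (m >= 3) angles <- rbind(angles, cbind(chain[1:(m - 2)],
                                              chain[2:(m - 1)],
                                              chain[3:m]))
    if (m >= 4) torsions <- rbind(torsions, cbind(chain[1:(m - 3)],
                                                  chain[2:(m - 2)],
                                                  chain[3:(m - 1)],
                                                  chain[4:m]))
  }
  list(bonds = bonds, angles = angles, torsions = torsions)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("Coarse-grained topology:", x$n, "beads;",
      length(x$bodies), "rigid bodies;", length(x$linkers), "linker chains\n")
  if (!is.na(x$stoichiometry)) cat("  stoichiometry:", x$stoichiometry, "\n")
  if (nrow(x$restraints) > 0) {
    cat("  membrane restraints on beads:",
        paste(x$restraints[, "bead"], collapse = ", "), "\n")
  }
  invisible(x)
}

# list form passed to the C++ core
topo_cpp <- function(topology) {
  list(n = topology$n,
       body_id = as.integer(topology$body_id),
       charge = as.numeric(topology$charge),
       rtype = as.integer(topology$rtype),
       bonds = matrix(as.integer(topology$bonds), ncol = 2),
       angles = matrix(as.integer(topology$angles), ncol = 3),
       torsions = matrix(as.integer(topology$torsions), ncol = 4),
       bodies = lapply(topology$bodies, as.integer),
       linkers = lapply(topology$linkers, as.integer),
       anchor_start = as.integer(topology$anchor_start),
       anchor_end = as.integer(topology$anchor_end),
       restraints = matrix(as.numeric(topology$restraints), ncol = 3))
}

#' Build a topology from a configuration file or list
#'
#' Reads a topology specification (YAML file or an equivalent list) naming
#' structure files, residue ranges, linker sequences, anchors and membrane
#' restraints, and assembles the coarse-grained topology.
#'
#' The schema mirrors the arguments of [cg_topology()]:
#' ```yaml
#' bodies:
#'   - {id: kinase, file: kinase.pdb, chain: A, residues: "130-423,522-816"}
#' linkers:
#'   - {id: loop1, sequence: GSSGSSG, anchor_start: "kinase:423",
#'      anchor_end: "kinase:522"}
#' restraints:
#'   - {bead: "rab:212", z: 20, k: 0.1}
#' stoichiometry: "2:1:1"
#' ```
#'
#' @param spec path to a YAML file, or a list with elements `bodies`,
#'   `linkers`, `restraints`, `stoichiometry`, `his_charge`.
#' @param dir directory against which relative structure-file paths are
#'   resolved (defaults to the spec file's directory, or `"."`).
#' @return A [cg_topology] object.
#' @export
build_topology <- function(spec, dir = NULL) {
  if (is.character(spec)) {
    if (is.null(dir)) dir <- dirname(spec)
    spec <- yaml::read_yaml(spec)
  }
  if (is.null(dir)) dir <- "."
  bodies <- lapply(spec$bodies, function(b) {
    if (!is.null(b$file) && !file.exists(b$file)) {
      b$file <- file.path(dir, b$file)
    }
    b
  })
  cg_topology(
    bodies = bodies,
    linkers = if (is.null(spec$linkers)) list() else spec$linkers,
    restraints = if (is.null(spec$restraints)) list() else spec$restraints,
    stoichiometry = if (is.null(spec$stoichiometry)) NA_character_
                    else spec$stoichiometry,
    his_charge = if (is.null(spec$his_charge)) 0 else spec$his_charge,
    bond_length = if (is.null(spec$bond_length)) 3.8 else spec$bond_length
  )
}

#' Create a conformation of a topology
#'
#' @param coords n x 3 coordinate matrix (Angstrom), one row per bead.
#' @param topology the [cg_topology] the coordinates belong to (optional;
#'   checked when given).
#' @param energy,run,replica,temperature,sweep provenance metadata.
#' @return An object of class `cg_conformation`.
#' @export
conformation <- function(coords, topology = NULL, energy = NA_real_,
                         run = NA_integer_, replica = NA_integer_,
                         temperature = NA_real_, sweep = NA_integer_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) abort("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  if (!is.null(topology) && nrow(coords) != topology$n) {
    abort(sprintf("conformation has %d beads but topology has %d",
                  nrow(coords), topology$n))
  }
  structure(list(coords = coords, energy = energy, run = run,
                 replica = replica, temperature = temperature, sweep = sweep),
            class = "cg_conformation")
}

as_coords <- function(x) {
  if (inherits(x, "cg_conformation")) return(x$coords)
  if (is.matrix(x) || is.data.frame(x)) return(as.matrix(x))
  abort("expected a conformation or an n x 3 coordinate matrix")
}

#' Radius of gyration of a conformation
#'
#' Root-mean-square distance of the beads from their centroid, with unit
#' masses: `Rg = sqrt(mean(|r_i - <r>|^2))`.
#'
#' @param x a `cg_conformation` or an n x 3 coordinate matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(x) {
  xyz <- as_coords(x)
  if (nrow(xyz) < 1) abort("need at least one bead")
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Maximum extension (Dmax) of a conformation
#'
#' Largest Euclidean distance over all bead pairs.
#'
#' @inheritParams radius_of_gyration
#' @return Dmax in Angstrom. A single-bead conformation returns 0 with a
#'   warning.
#' @export
maximum_extension <- function(x) {
  xyz <- as_coords(x)
  if (nrow(xyz) < 1) abort("need at least one bead")
  if (nrow(xyz) == 1) {
    warn("single bead: maximum extension is 0")
    return(0)
  }
  max(dist(xyz))
}

#' Place a rigid body by a quaternion pose
#'
#' Applies a pose (unit quaternion rotation plus translation) to a rigid
#' body's internal reference coordinates and writes the result into a copy
#' of the given coordinates. Rigidity is exact: internal distances are
#' preserved to floating-point precision.
#'
#' @param coords full n x 3 coordinate matrix.
#' @param topology a [cg_topology].
#' @param body body index.
#' @param quaternion unit quaternion `c(w, x, y, z)` (norm checked to 1e-9).
#' @param translation length-3 translation applied after rotation; the body
#'   reference frame is centred on its centroid, so the translation is the
#'   new centroid position.
#' @return The updated coordinate matrix.
#' @export
set_body_pose <- function(coords, topology, body, quaternion,
                          translation = c(0, 0, 0)) {
  qn <- sqrt(sum(quaternion^2))
  if (abs(qn - 1) > 1e-9) abort("quaternion must have unit norm (1e-9)")
  R <- quat_to_matrix(quaternion)
  ref <- topology$body_ref[[body]]
  coords[topology$bodies[[body]], ] <-
    ref %*% t(R) + matrix(translation, nrow(ref), 3, byrow = TRUE)
  coords
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_unit_quaternion <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}
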