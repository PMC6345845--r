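# Coarse-grained potential energy: harmonic stretch/bend plus cosine torsion
# along linkers, residue-pair contact wells with a finite hard core, screened
# Debye-Hueckel electrostatics, and (in membrane mode) harmonic z anchors,
# a per-residue-type surface attraction and a half-space wall below the
# membrane plane.

#' Default residue-pair contact well depths
#'
#' A simple, documented 20 x 20 symmetric table of contact well depths
#' (kcal/mol): `eps_ij = base + scale * h_i * h_j`, where `h` is 1 for
#' strongly hydrophobic residues (A, C, F, I, L, M, V, W), 0.5 for weakly
#' hydrophobic ones (G, P, T, Y) and 0 otherwise. Hydrophobic pairs thus
#' attract more strongly than polar pairs. The table is fully replaceable:
#' pass any symmetric 20 x 20 matrix (row/column order of
#' [amino_acid_table()]) to [energy_model()], or load one from a text file
#' with [read_contact_matrix()]. Results should always be reported together
#' with the matrix used.
#'
#' @param base well depth shared by all pairs (kcal/mol).
#' @param scale extra depth for hydrophobic-hydrophobic pairs (kcal/mol).
#' @return 20 x 20 symmetric matrix with dimnames from the canonical
#'   residue order.
#' @export
default_contact_matrix <- function(base = 0.05, scale = 0.25) {
  h <- setNames(rep(0, 20), .aa3)
  h[c("ALA", "CYS", "PHE", "ILE", "LEU", "MET", "VAL", "TRP")] <- 1
  h[c("GLY", "PRO", "THR", "TYR")] <- 0.5
  m <- base + scale * outer(h, h)
  dimnames(m) <- list(.aa3, .aa3)
  m
}

#' Default per-residue membrane well depths
#'
#' Statistical amino-acid-dependent attraction of residue beads to the
#' membrane surface (kcal/mol), emulating a lipid-interaction profile:
#' hydrophobic and aromatic residues bind most strongly, Lys/Arg get an
#' intermediate electrostatic headgroup attraction, the rest a weak
#' background. Fully replaceable via [energy_model()].
#'
#' @return Named length-20 vector in canonical residue order.
#' @export
default_membrane_depths <- function() {
  d <- setNames(rep(0.05, 20), .aa3)
  d[c("PHE", "TRP", "TYR", "LEU", "ILE", "MET", "VAL", "CYS")] <- 0.25
  d[c("LYS", "ARG")] <- 0.15
  d
}

#' Coarse-grained energy model parameters
#'
#' Bundles every parameter of the potential. All energies kcal/mol, lengths
#' Angstrom, angles radians.
#'
#' @param bond_k harmonic stretch constant for linker bonds (kcal/mol/A^2).
#' @param bond_length equilibrium consecutive C-alpha spacing (3.8 A).
#' @param angle_k harmonic bending constant (kcal/mol/rad^2).
#' @param angle_0 equilibrium pseudo-bond angle (default 2.12 rad, a typical
#'   C-alpha trace value).
#' @param torsion_k amplitude of the cosine torsion term
#'   `k * (1 + cos(phi))` along linker chains.
#' @param contact_eps 20 x 20 symmetric contact well-depth matrix.
#' @param contact_range pair distance below which the contact well applies.
#' @param ev_radius excluded-volume radius; below it a finite steep
#'   repulsion `rep_k * ((ev/r)^6 - 1)`, capped at `rep_cap`, replaces any
#'   singularity (overlapping beads stay at a large finite energy).
#' @param rep_k,rep_cap repulsion scale and cap.
#' @param debye_length Debye screening length (default 10 A, about 150 mM
#'   monovalent salt).
#' @param dielectric relative dielectric constant (default 80).
#' @param z_membrane membrane surface plane position (default 20 A, i.e.
#'   2 nm).
#' @param mem_eps per-residue-type membrane well depths (length 20).
#' @param mem_range decay length of the membrane attraction
#'   (Gaussian in the height above the plane).
#' @param wall_k stiffness of the impenetrability wall below the plane
#'   (kcal/mol/A^2).
#' @return An object of class `cg_energy_model` (a validated list).
#' @export
energy_model <- function(bond_k = 10, bond_length = 3.8,
                         angle_k = 5, angle_0 = 2.12,
                         torsion_k = 0.2,
                         contact_eps = default_contact_matrix(),
                         contact_range = 8, ev_radius = 4,
                         rep_k = 1, rep_cap = 1e6,
                         debye_length = 10, dielectric = 80,
                         z_membrane = 20,
                         mem_eps = default_membrane_depths(),
                         mem_range = 5, wall_k = 10) {
  contact_eps <- as.matrix(contact_eps)
  if (!all(dim(contact_eps) == c(20, 20))) {
    abort("contact_eps must be a 20 x 20 matrix")
  }
  if (max(abs(contact_eps - t(contact_eps))) > 1e-12) {
    abort("contact_eps must be symmetric")
  }
  stopifnot(contact_range > 0, ev_radius > 0, debye_length > 0,
            dielectric > 0, mem_range > 0, length(mem_eps) == 20)
  structure(list(
    bond_k = bond_k, bond_length = bond_length,
    angle_k = angle_k, angle_0 = angle_0, torsion_k = torsion_k,
    contact_eps = unname(contact_eps), contact_range = contact_range,
    ev_radius = ev_radius, rep_k = rep_k, rep_cap = rep_cap,
    coulomb_k = 332.0637, debye_length = debye_length,
    dielectric = dielectric,
    z_membrane = z_membrane, mem_eps = unname(as.numeric(mem_eps)),
    mem_range = mem_range, wall_k = wall_k
  ), class = "cg_energy_model")
}

#' Read a contact matrix from a whitespace-delimited 20 x 20 text table
#'
#' @param path file with 20 rows of 20 numbers (optionally preceded by
#'   `#` comment lines); row/column order is that of [amino_acid_table()].
#' @return 20 x 20 symmetric matrix.
#' @export
read_contact_matrix <- function(path) {
  m <- as.matrix(read.table(path, comment.char = "#"))
  dimnames(m) <- list(.aa3, .aa3)
  if (!all(dim(m) == c(20, 20))) abort("contact matrix must be 20 x 20")
  if (max(abs(m - t(m))) > 1e-9) abort("contact matrix must be symmetric")
  m
}

#' Build an energy model from a configuration file or list
#'
#' @param spec YAML path or list of [energy_model()] arguments; the entry
#'   `contact_matrix_file` may name a [read_contact_matrix()] table.
#' @param dir base directory for relative file paths.
#' @return A `cg_energy_model`.
#' @export
build_energy_model <- function(spec = list(), dir = NULL) {
  if (is.character(spec)) {
    if (is.null(dir)) dir <- dirname(spec)
    spec <- yaml::read_yaml(spec)
  }
  if (!is.null(spec$contact_matrix_file)) {
    f <- spec$contact_matrix_file
    if (!file.exists(f) && !is.null(dir)) f <- file.path(dir, f)
    spec$contact_eps <- read_contact_matrix(f)
    spec$contact_matrix_file <- NULL
  }
  if (!is.null(spec$mem_eps)) spec$mem_eps <- as.numeric(spec$mem_eps)
  do.call(energy_model, spec)
}

energy_parts <- function(x, topology, model, membrane) {
  cpp_total_energy(as_coords(x), topo_cpp(topology), unclass(model), membrane)
}

#' Bonded energy of the linker chains
#'
#' Sum over linker bonds of the harmonic stretch `1/2 k (b - b0)^2`, over
#' pseudo-bond angles of the harmonic bend, and over dihedrals of the
#' cosine torsion term. Rigid-body internal pairs contribute nothing.
#'
#' @param x conformation or coordinate matrix.
#' @param topology a [cg_topology].
#' @param model a [cg_energy_model][energy_model].
#' @return Energy in kcal/mol.
#' @export
bonded_energy <- function(x, topology, model = energy_model()) {
  energy_parts(x, topology, model, FALSE)$bonded
}

#' Nonbonded energy: contacts plus screened electrostatics
#'
#' Pairs within the same rigid body and directly bonded neighbours are
#' excluded. The contact term is a well of depth `eps_ij` inside the
#' contact range with a finite hard-core repulsion below the
#' excluded-volume radius; the electrostatic term is the screened Coulomb
#' interaction `332.0637 q_i q_j exp(-r/lambda_D) / (eps_r r)`.
#'
#' @inheritParams bonded_energy
#' @return Energy in kcal/mol, with attributes `contact` and
#'   `electrostatic` carrying the two components.
#' @export
nonbonded_energy <- function(x, topology, model = energy_model()) {
  p <- energy_parts(x, topology, model, FALSE)
  structure(p$contact + p$electrostatic,
            contact = p$contact, electrostatic = p$electrostatic)
}

#' Membrane energy: anchors, surface attraction, impenetrability
#'
#' Sum of (i) soft harmonic anchor restraints `1/2 k (z_i - z_target)^2`
#' on the restrained beads, (ii) the per-residue-type attraction of beads
#' within the interaction range of the membrane plane, and (iii) a steep
#' half-space repulsion below the plane.
#'
#' @inheritParams bonded_energy
#' @return Energy in kcal/mol, with attributes `restraint` and `surface`.
#' @export
membrane_energy <- function(x, topology, model = energy_model()) {
  p <- energy_parts(x, topology, model, TRUE)
  structure(p$membrane_restraint + p$membrane_surface,
            restraint = p$membrane_restraint, surface = p$membrane_surface)
}

#' Total coarse-grained energy
#'
#' @inheritParams bonded_energy
#' @param membrane include the membrane terms?
#' @return Total energy (kcal/mol) with a `components` attribute.
#' @export
total_energy <- function(x, topology, model = energy_model(),
                         membrane = FALSE) {
  p <- energy_parts(x, topology, model, membrane)
  structure(p$total, components = p[names(p) != "total"])
}
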