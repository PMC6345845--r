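# Readers and writers: PDB (via bio3d, C-alpha bead models, multi-MODEL
# trajectory pools), ATSAS-style 3-column SAXS .dat files, TSV tables and
# JSON run manifests.

#' Read C-alpha coordinates from a PDB file
#'
#' Uses the bio3d parser; extracts one bead per residue at the C-alpha
#' position, for every MODEL in the file.
#'
#' @param path PDB file.
#' @param chain optional chain selector.
#' @param residues optional residue range string, e.g. `"130-423,522-816"`;
#'   declared residues missing from the file are an error naming them.
#' @param model_policy `"all"` (default) returns every MODEL, `"first"`
#'   only the first.
#' @return List with `coords` (list of n x 3 matrices, one per MODEL) and
#'   `atoms` (tibble: chain, resno, resid for the first model).
#' @export
read_pdb <- function(path, chain = NULL, residues = NULL,
                     model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- bio3d::read.pdb(path, multi = (model_policy == "all"), verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (length(sel$atom) == 0) abort(paste0("no C-alpha records in ", path))
  atoms <- pdb$atom[sel$atom, c("chain", "resno", "resid")]
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(residues)) {
    want <- parse_ranges(residues)
    keep <- keep & atoms$resno %in% want
    have <- unique(atoms$resno[keep])
    missing <- setdiff(want, have)
    if (length(missing) > 0) {
      abort(paste0("declared residues missing C-alpha records in ", path, ": ",
                   paste(head(missing, 10), collapse = ", "),
                   if (length(missing) > 10) " ..." else ""))
    }
  }
  if (!any(keep)) abort("no C-alpha records left after chain/residue selection")
  xyz_idx <- sel$xyz
  nm <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  xyz <- matrix(pdb$xyz, nrow = nm)
  coords <- lapply(seq_len(nm), function(m) {
    xm <- matrix(xyz[m, xyz_idx], ncol = 3, byrow = TRUE)
    xm[keep, , drop = FALSE]
  })
  list(coords = coords, atoms = as_tibble(atoms[keep, , drop = FALSE]))
}

parse_ranges <- function(s) {
  parts <- strsplit(gsub(" ", "", s), ",")[[1]]
  unlist(lapply(parts, function(p) {
    ab <- as.integer(strsplit(p, "-")[[1]])
    if (length(ab) == 1) ab else seq(ab[1], ab[2])
  }))
}

#' Write conformations as a (multi-MODEL) PDB bead trajectory
#'
#' Emits one MODEL per conformation, one C-alpha ATOM record per bead, with
#' residue names and per-unit chain identifiers taken from the topology
#' when given. Fixed-width PDB convention, coordinates in Angstrom with 3
#' decimals.
#'
#' @param conformations a conformation, coordinate matrix, list of either,
#'   or a `cg_pool`.
#' @param path output file.
#' @param topology optional [cg_topology] supplying residue names/chains.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conformations, path, topology = NULL) {
  if (inherits(conformations, "cg_pool")) {
    if (is.null(topology)) topology <- conformations$topology
    conformations <- conformations$conformations
  }
  if (inherits(conformations, "cg_conformation") || is.matrix(conformations)) {
    conformations <- list(conformations)
  }
  n <- nrow(as_coords(conformations[[1]]))
  resnames <- rep("ALA", n)
  chains <- rep("A", n)
  if (!is.null(topology)) {
    resnames <- topology$beads$residue
    chains <- LETTERS[pmin(26, as.integer(factor(topology$beads$unit,
                                                 levels = unique(topology$beads$unit))))]
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(conformations) > 1
  for (m in seq_along(conformations)) {
    xyz <- as_coords(conformations[[m]])
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n) %% 100000, resnames, chains, seq_len(n) %% 10000,
      xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a 3-column SAXS .dat file
#'
#' Whitespace-delimited `q I sigma` (sigma optional), `#` comment lines
#' ignored — the de-facto ATSAS-style convention.
#'
#' @param path file path.
#' @return A [saxs_profile].
#' @export
read_saxs <- function(path) {
  d <- read.table(path, comment.char = "#", header = FALSE)
  if (ncol(d) < 2) abort("SAXS .dat file needs at least 2 columns (q, I)")
  saxs_profile(d[[1]], d[[2]], if (ncol(d) >= 3) d[[3]] else NULL)
}

#' Write a SAXS profile as a 3-column .dat file
#'
#' @param profile a [saxs_profile].
#' @param path output file.
#' @param comment optional header comment.
#' @return `path`, invisibly.
#' @export
write_saxs <- function(profile, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("# q[1/A]  I(q)  sigma", con)
  has_sig <- !all(is.na(profile$sigma))
  lines <- if (has_sig) {
    sprintf("%.6e %.6e %.6e", profile$q, profile$intensity, profile$sigma)
  } else {
    sprintf("%.6e %.6e", profile$q, profile$intensity)
  }
  writeLines(lines, con)
  invisible(path)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
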