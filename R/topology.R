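#' Construct a Topology
#'
#' A `Topology` holds the static description of a molecular system: one row
#' per atom with names, elements, residue identifiers and role flags, plus a
#' species map translating lipid residue names into species labels (e.g.
#' `POPC -> DOPC`, `CHL1 -> CHOL`).
#'
#' Roles are boolean flags rather than an exclusive category so that, e.g., a
#' glycan-anchor atom can also be a hydrogen-bond acceptor. The recognised
#' roles are `protein`, `lipid`, `glycan_anchor`, `hbond_donor`,
#' `hbond_acceptor` and `hydrogen`.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_seq`,
#'   `residue_name`, `chain`, and optionally logical role columns
#'   `protein`, `lipid`, `glycan_anchor`, `hbond_donor`, `hbond_acceptor`,
#'   `hydrogen`. Atom indices are implicit (0-based row order).
#' @param species_map named character vector mapping lipid residue names to
#'   species labels. Lipid residue names absent from the map are mapped to
#'   themselves.
#' @return object of class `Topology`.
#' @export
Topology <- function(atoms, species_map = character()) {
  required <- c("name", "element", "residue_seq", "residue_name", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (role in .atom_roles) {
    if (is.null(atoms[[role]])) atoms[[role]] <- FALSE
    atoms[[role]] <- as.logical(atoms[[role]])
  }
  atoms$index <- seq_len(nrow(atoms)) - 1L
  bad_h <- atoms$hydrogen & toupper(atoms$element) != "H"
  if (any(bad_h))
    stop("hydrogen role set on non-H element at atom index ",
         atoms$index[which(bad_h)[1]])
  # lipid residues not covered by the map keep their own name as species
  lipid_res <- unique(atoms$residue_name[atoms$lipid])
  unmapped <- setdiff(lipid_res, names(species_map))
  if (length(unmapped)) {
    auto <- stats::setNames(unmapped, unmapped)
    species_map <- c(species_map, auto)
  }
  topo <- structure(
    list(atoms = atoms, species_map = species_map,
         residue_index = .build_residue_index(atoms)),
    class = "Topology")
  topo
}

.atom_roles <- c("protein", "lipid", "glycan_anchor",
                 "hbond_donor", "hbond_acceptor", "hydrogen")

.build_residue_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$residue_seq, sep = ":")
  split(atoms$index, factor(key, levels = unique(key)))
}

#' Number of atoms in a Topology
#' @param topology a `Topology`
#' @return integer atom count
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' @export
print.Topology <- function(x, ...) {
  a <- x$atoms
  cat("Topology:", nrow(a), "atoms,",
      length(x$residue_index), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  if (any(a$protein)) cat("  protein atoms:", sum(a$protein), "\n")
  if (any(a$lipid))
    cat("  lipid atoms:", sum(a$lipid), "( species:",
        paste(unique(x$species_map), collapse = ", "), ")\n")
  invisible(x)
}

#' Species label of a residue name
#' @param topology a `Topology`
#' @param residue_name residue name(s)
#' @return character species label(s)
#' @export
species_of <- function(topology, residue_name) {
  out <- unname(topology$species_map[residue_name])
  out[is.na(out)] <- residue_name[is.na(out)]
  out
}

#' Construct a Trajectory
#'
#' Coordinates are stored in nanometres as an array with dimensions
#' `(frame, atom, xyz)`. Box vectors, when present, are orthorhombic box
#' edge lengths in nm per frame.
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (nm), or a single
#'   `n_atoms x 3` matrix for a one-frame trajectory.
#' @param box optional `n_frames x 3` matrix (or length-3 vector recycled) of
#'   box lengths in nm.
#' @param time_ps optional numeric vector of per-frame time stamps (ps).
#' @return object of class `Trajectory`.
#' @export
Trajectory <- function(coords, box = NULL, time_ps = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  nf <- dim(coords)[1]
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    if (nrow(box) != nf) stop("box must have one row per frame")
    if (any(box <= 0)) stop("box lengths must be > 0")
  }
  if (!is.null(time_ps) && length(time_ps) != nf)
    stop("time_ps must have one value per frame")
  structure(list(coords = coords, box = box, time_ps = time_ps,
                 n_frames = nf, n_atoms = dim(coords)[2]),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frame(s) x", x$n_atoms, "atoms",
      if (!is.null(x$box)) "(periodic box)" else "(no box)", "\n")
  invisible(x)
}

#' Extract one frame of a Trajectory as an n_atoms x 3 matrix (nm)
#' @param trajectory a `Trajectory`
#' @param frame 0-based frame index
#' @return numeric matrix `n_atoms x 3`
#' @export
frame_coords <- function(trajectory, frame) {
  if (frame < 0 || frame >= trajectory$n_frames)
    stop("frame ", frame, " out of range [0, ", trajectory$n_frames, ")")
  matrix(trajectory$coords[frame + 1L, , ], ncol = 3)
}

check_topology_trajectory <- function(topology, trajectory) {
  if (n_atoms(topology) != trajectory$n_atoms)
    stop("topology has ", n_atoms(topology), " atoms but trajectory has ",
         trajectory$n_atoms)
  invisible(TRUE)
}
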