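#' Read a (multi-model) PDB structure into a Topology and Trajectory
#'
#' Multi-model files (NMR-style ensembles, fixture trajectories) yield one
#' frame per MODEL record, ordered by MODEL number; single-model files give
#' one frame. Coordinates are converted from Angstrom to nm on read. A
#' CRYST1 record populates the (orthorhombic) box for every frame.
#'
#' Role flags are assigned on read: `protein` for the 20 standard amino-acid
#' residue names, `lipid` for residue names listed in `species_map` (or
#' detected lipid names), `hydrogen` by element. Hydrogen-bond donor and
#' acceptor roles come from atom-name lookup tables (see
#' [assign_hbond_roles()]).
#'
#' @param path PDB file path
#' @param format only `"pdb"` is supported
#' @param species_map named character vector mapping lipid residue names to
#'   species labels; residue names appearing here are flagged as lipid.
#' @return list with elements `topology` ([Topology()]) and `trajectory`
#'   ([Trajectory()]).
#' @export
read_structure <- function(path, format = "pdb", species_map = character()) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("malformed PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  nat <- nrow(at)
  if (nat == 0L) stop("no ATOM/HETATM records in ", path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nat)
    stop("inconsistent atom count across MODELs in ", path)
  nf <- nrow(xyz)
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  element[blank] <- .element_from_name(at$elety[blank])
  atoms <- data.frame(
    name = trimws(at$elety),
    element = trimws(element),
    residue_seq = as.integer(at$resno),
    residue_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    stringsAsFactors = FALSE)
  atoms$protein <- atoms$residue_name %in% .protein_residues
  atoms$lipid <- atoms$residue_name %in%
    union(names(species_map), .known_lipid_residues)
  atoms$hydrogen <- toupper(atoms$element) == "H"
  topo <- Topology(atoms, species_map = species_map)
  topo <- assign_hbond_roles(topo)
  coords <- array(0, dim = c(nf, nat, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  box <- .read_cryst1(path)
  if (!is.null(box)) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  list(topology = topo, trajectory = Trajectory(coords, box = box))
}

.protein_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "HSD", "HSE", "ILE", "LEU", "LYS",
                       "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
                       "VAL")

.known_lipid_residues <- c("DOPC", "POPC", "DPPC", "CHOL", "CHL1")

.element_from_name <- function(name) {
  name <- trimws(name)
  # PDB convention: names like "1H5'" lead with a digit for hydrogens
  lead <- sub("^[0-9']*", "", name)
  two <- toupper(substr(lead, 1, 2))
  one <- toupper(substr(lead, 1, 1))
  ifelse(two %in% c("CL", "NA", "MG", "ZN", "FE", "BR"), two, one)
}

.read_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) return(NULL)
  abc <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                       substr(cr[1], 16, 24),
                                       substr(cr[1], 25, 33))))
  if (anyNA(abc) || any(abc <= 0)) return(NULL)
  abc / 10  # A -> nm
}

#' Write a Topology + Trajectory as a multi-model PDB file
#'
#' Coordinates are converted nm -> Angstrom; one MODEL per frame; a CRYST1
#' record is written from the first frame's box when present. This is the
#' fixture writer used by the synthetic-data generators, so round-tripping
#' through [read_structure()] preserves coordinates to PDB precision
#' (1e-3 A).
#'
#' @param topology a [Topology()]
#' @param trajectory a [Trajectory()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure <- function(topology, trajectory, path) {
  check_topology_trajectory(topology, trajectory)
  a <- topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(trajectory$box)) {
    b <- trajectory$box[1, ] * 10
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1], b[2], b[3], 90, 90, 90), con)
  }
  rec <- ifelse(a$protein, "ATOM  ", "HETATM")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  for (f in seq_len(trajectory$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(trajectory$coords[f, , ], ncol = 3) * 10
    writeLines(sprintf(
      "%s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, (a$index %% 99999L) + 1L, name4, substr(a$residue_name, 1, 4),
      a$chain, a$residue_seq, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      toupper(substr(a$element, 1, 2))), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
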