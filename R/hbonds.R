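#' Geometric hydrogen-bond criteria
#'
#' A donor-hydrogen-acceptor triplet counts as a hydrogen bond when the
#' donor-acceptor distance is at most `da_cutoff` and the
#' donor-hydrogen-acceptor angle is at least `dha_angle_min`.
#'
#' @param da_cutoff donor-acceptor distance cutoff in Angstrom (default 3.0)
#' @param dha_angle_min minimum D-H-A angle in degrees (default 150)
#' @return object of class `hbond_criteria`
#' @export
hbond_criteria <- function(da_cutoff = 3.0, dha_angle_min = 150) {
  if (da_cutoff <= 0) stop("da_cutoff must be > 0")
  if (dha_angle_min < 0 || dha_angle_min > 180)
    stop("dha_angle_min must lie in [0, 180]")
  structure(list(da_cutoff = da_cutoff, dha_angle_min = dha_angle_min),
            class = "hbond_criteria")
}

# Atom-name lookup tables for donor/acceptor typing without a topology file.
# Protein: backbone N donates, backbone O accepts, plus polar side chains.
.protein_donor_atoms <- c("N", "ND1", "ND2", "NE", "NE1", "NE2", "NH1",
                          "NH2", "NZ", "OG", "OG1", "OH", "SG")
.protein_acceptor_atoms <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
                             "OH", "OXT", "ND1", "NE2", "SD")
# DOPC-style phosphatidylcholine: phosphate and ester oxygens accept;
# lipids of this class have no donors.
.lipid_acceptor_atoms <- c("O11", "O12", "O13", "O14", "O21", "O22", "O31",
                           "O32", "OP1", "OP2", "OP3", "OP4")

#' Assign hydrogen-bond donor/acceptor roles from atom-name tables
#'
#' Marks protein donors and acceptors, and lipid acceptors, by atom-name
#' lookup; existing role flags are kept. Users with non-standard chemistry
#' can extend the tables through `extra_donors` / `extra_acceptors`.
#'
#' @param topology a [Topology()]
#' @param extra_donors,extra_acceptors additional atom names to flag
#' @return the updated `Topology`
#' @export
assign_hbond_roles <- function(topology, extra_donors = character(),
                               extra_acceptors = character()) {
  a <- topology$atoms
  a$hbond_donor <- a$hbond_donor |
    (a$protein & a$name %in% c(.protein_donor_atoms, extra_donors)) |
    (a$lipid & a$name %in% extra_donors)
  a$hbond_acceptor <- a$hbond_acceptor |
    (a$protein & a$name %in% c(.protein_acceptor_atoms, extra_acceptors)) |
    (a$lipid & a$name %in% c(.lipid_acceptor_atoms, extra_acceptors))
  a$hbond_donor[a$hydrogen] <- FALSE
  a$hbond_acceptor[a$hydrogen] <- FALSE
  Topology(a[, setdiff(names(a), "index")], topology$species_map)
}

#' Map hydrogens to their donor heavy atoms
#'
#' A hydrogen within `bond_cutoff` of a donor heavy atom in the reference
#' frame is considered covalently bound to it (nearest donor wins).
#'
#' @param topology a [Topology()]
#' @param coords `n_atoms x 3` matrix (nm) of the reference frame
#' @param bond_cutoff covalent D-H cutoff in Angstrom (default 1.2)
#' @return data.frame with 0-based `donor` and `hydrogen` atom indices
#' @export
assign_hydrogens <- function(topology, coords, bond_cutoff = 1.2) {
  a <- topology$atoms
  don <- a$index[a$hbond_donor]
  hyd <- a$index[a$hydrogen]
  if (!length(don) || !length(hyd))
    return(data.frame(donor = integer(), hydrogen = integer()))
  cut_nm <- bond_cutoff / 10
  out <- lapply(hyd, function(h) {
    d2 <- rowSums(sweep(coords[don + 1L, , drop = FALSE], 2,
                        coords[h + 1L, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= cut_nm)
      data.frame(donor = don[j], hydrogen = h) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(donor = integer(), hydrogen = integer())
  else out
}

#' Find hydrogen bonds in one frame
#'
#' Enumerates every (donor, hydrogen, acceptor) triplet with the donor in
#' `donors_from`, the acceptor in `acceptors_from`, a donor-acceptor
#' distance within the cutoff and a D-H-A angle above the minimum. Running
#' it a second time with the selections swapped captures bonds donated by
#' the other group.
#'
#' @param coords `n_atoms x 3` frame coordinates (nm)
#' @param topology a [Topology()]
#' @param donors_from,acceptors_from selection strings or 0-based index
#'   vectors delimiting the donor and acceptor pools
#' @param criteria an [hbond_criteria()]
#' @param hydrogen_map optional precomputed [assign_hydrogens()] table;
#'   computed from `coords` when missing
#' @return data.frame with 0-based `donor`, `hydrogen`, `acceptor` indices,
#'   `distance_A` and `angle_deg`
#' @export
find_hbonds <- function(coords, topology, donors_from, acceptors_from,
                        criteria = hbond_criteria(), hydrogen_map = NULL) {
  a <- topology$atoms
  di <- .resolve_selection(topology, donors_from)
  ai <- .resolve_selection(topology, acceptors_from)
  don <- intersect(di, a$index[a$hbond_donor])
  acc <- intersect(ai, a$index[a$hbond_acceptor])
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance_A = numeric(),
                      angle_deg = numeric())
  if (!length(don) || !length(acc)) return(empty)
  if (is.null(hydrogen_map)) hydrogen_map <- assign_hydrogens(topology, coords)
  hm <- hydrogen_map[hydrogen_map$donor %in% don, , drop = FALSE]
  orphans <- setdiff(don, hm$donor)
  if (length(orphans))
    warning(length(orphans),
            " donor(s) without a resolvable hydrogen skipped")
  if (!nrow(hm)) return(empty)
  cut_nm <- criteria$da_cutoff / 10
  recs <- empty
  for (r in seq_len(nrow(hm))) {
    D <- coords[hm$donor[r] + 1L, ]
    H <- coords[hm$hydrogen[r] + 1L, ]
    dv <- sweep(coords[acc + 1L, , drop = FALSE], 2, D)
    da <- sqrt(rowSums(dv^2))
    ok <- which(da <= cut_nm & acc != hm$donor[r])
    for (j in ok) {
      A <- coords[acc[j] + 1L, ]
      hd <- D - H; ha <- A - H
      ang <- acos(min(1, max(-1, sum(hd * ha) /
                               sqrt(sum(hd^2) * sum(ha^2))))) * 180 / pi
      if (ang >= criteria$dha_angle_min) {
        recs <- rbind(recs, data.frame(
          donor = hm$donor[r], hydrogen = hm$hydrogen[r],
          acceptor = acc[j], distance_A = da[j] * 10, angle_deg = ang))
      }
    }
  }
  recs
}

#' Hydrogen-bond records over a whole trajectory
#'
#' @inheritParams find_hbonds
#' @param trajectory a [Trajectory()]
#' @return data.frame as [find_hbonds()] with a leading 0-based `frame`
#'   column
#' @export
hbond_records <- function(trajectory, topology, donors_from, acceptors_from,
                          criteria = hbond_criteria()) {
  check_topology_trajectory(topology, trajectory)
  hm <- assign_hydrogens(topology, frame_coords(trajectory, 0))
  out <- lapply(seq_len(trajectory$n_frames) - 1L, function(f) {
    r <- find_hbonds(frame_coords(trajectory, f), topology, donors_from,
                     acceptors_from, criteria, hydrogen_map = hm)
    if (nrow(r)) cbind(frame = f, r) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), donor = integer(),
                      hydrogen = integer(), acceptor = integer(),
                      distance_A = numeric(), angle_deg = numeric())
  out
}

#' Mean hydrogen-bond count per residue
#'
#' For each protein residue, the number of records whose donor (or, with
#' `count = "both"`, donor or acceptor) belongs to the residue, divided by
#' the total frame count. Pooling replicates with equal weight amounts to
#' concatenating their record tables and summing their frame counts.
#'
#' @param records a [hbond_records()] table (possibly concatenated over
#'   replicates)
#' @param topology a [Topology()]
#' @param n_frames_total total frames the records were computed over
#' @param count `"donor"` (count bonds the residue donates, default) or
#'   `"both"` (donated plus accepted)
#' @return data.frame with `chain`, `residue_seq`, `residue_name`,
#'   `mean_bonds` for every protein residue (zero where none observed)
#' @export
per_residue_bond_average <- function(records, topology, n_frames_total,
                                     count = c("donor", "both")) {
  count <- match.arg(count)
  if (n_frames_total <= 0) stop("n_frames_total must be > 0")
  a <- topology$atoms
  prot <- a[a$protein, , drop = FALSE]
  res <- unique(prot[, c("chain", "residue_seq", "residue_name")])
  key <- paste(res$chain, res$residue_seq, sep = ":")
  counts <- stats::setNames(numeric(length(key)), key)
  idx_key <- paste(a$chain, a$residue_seq, sep = ":")
  tally <- function(atom_idx) {
    k <- idx_key[atom_idx + 1L]
    k <- k[k %in% names(counts)]
    tab <- table(k)
    counts[names(tab)] <<- counts[names(tab)] + as.numeric(tab)
  }
  if (nrow(records)) {
    tally(records$donor)
    if (count == "both") tally(records$acceptor)
  }
  res$mean_bonds <- unname(counts) / n_frames_total
  rownames(res) <- NULL
  res
}
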