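# Shared fixture builders; everything is generated in code at test time.

# Minimal protein-like topology: n residues, one CA atom each.
ca_topology <- function(n_res, chain = "A") {
  Topology(data.frame(
    name = "CA", element = "C",
    residue_seq = seq_len(n_res), residue_name = "GLY", chain = chain,
    protein = TRUE, stringsAsFactors = FALSE))
}

# Protein residue + one single-atom lipid molecule, for contact tests.
protein_lipid_topology <- function(n_lipids = 1, species = "DOPC") {
  atoms <- rbind(
    data.frame(name = "CA", element = "C", residue_seq = 1,
               residue_name = "GLY", chain = "A", protein = TRUE,
               lipid = FALSE, stringsAsFactors = FALSE),
    data.frame(name = "C1", element = "C", residue_seq = seq_len(n_lipids),
               residue_name = species, chain = "L", protein = FALSE,
               lipid = TRUE, stringsAsFactors = FALSE))
  Topology(atoms, species_map = stats::setNames(species, species))
}

random_rotation <- function() {
  rot_z(stats::runif(1, -180, 180)) %*%
    rot_y(stats::runif(1, -90, 90)) %*%
    rot_x(stats::runif(1, -180, 180))
}

# Independent brute-force hydrogen-bond oracle: scan all (donor, H,
# acceptor) combinations directly from coordinates.
brute_force_hbonds <- function(coords, topology, criteria,
                               hydrogen_map) {
  a <- topology$atoms
  acc <- a$index[a$hbond_acceptor]
  hits <- NULL
  for (r in seq_len(nrow(hydrogen_map))) {
    D <- coords[hydrogen_map$donor[r] + 1L, ]
    H <- coords[hydrogen_map$hydrogen[r] + 1L, ]
    for (aa in acc) {
      if (aa == hydrogen_map$donor[r]) next
      A <- coords[aa + 1L, ]
      dist_A <- sqrt(sum((D - A)^2)) * 10
      hd <- D - H; ha <- A - H
      ang <- acos(min(1, max(-1, sum(hd * ha) /
                               sqrt(sum(hd^2) * sum(ha^2))))) * 180 / pi
      if (dist_A <= criteria$da_cutoff && ang >= criteria$dha_angle_min)
        hits <- rbind(hits, data.frame(donor = hydrogen_map$donor[r],
                                       acceptor = aa))
    }
  }
  if (is.null(hits)) data.frame(donor = integer(), acceptor = integer())
  else hits[order(hits$donor, hits$acceptor), ]
}
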