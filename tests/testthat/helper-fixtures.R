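# Small fixtures built in code at test time.

# a CA-only single-chain structure from an explicit coordinate matrix
ca_structure <- function(coords, chain_id = "A", resno = NULL,
                         res_name = "ALA") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(
    serial = seq_len(n), atom_name = "CA", element = "C",
    res_name = rep_len(res_name, n), chain_id = rep_len(chain_id, n),
    seq_num = resno, icode = "", occupancy = 1, bfactor = 0,
    is_hetero = FALSE, stringsAsFactors = FALSE)
  xl_structure(atoms, coords)
}

# standard planted-docking scene: receptor trimer + ligand dimer toys,
# planted pose, n_true consistent DSBU links, n_false violations, decoys
planted_scene <- function(seed, n_true = 5L, n_false = 2L, n_decoys = 20L,
                          min_displacement = 50) {
  rec <- make_toy_assembly(260, n_chains = 3, leg_length = 120)
  # ligand dimer: two copies of a smaller meander domain stacked along z,
  # so both copies face the receptor at the planted placement
  lig <- build_assembly(toy_chain(200, "helix", leg_length = 90),
                        list(identity_transform(),
                             translation_transform(c(0, 0, 44))))
  # planted placement: ligand docked clash-free into the groove under two
  # receptor copies, so the interface is two-sided and extended — anchor
  # pairs under the DSBU budget span many distinct, spread-out residues
  xf <- translation_transform(c(-55, -30, -10))
  pl <- plant_pose_and_links(rec, lig, xf, "DSBU", n_true = n_true,
                             n_false = n_false, seed = seed)
  decoys <- generate_decoy_poses(n_decoys, pl$pose,
                                 min_displacement = min_displacement,
                                 seed = seed + 1000L)
  list(receptor = rec, ligand = lig, pose = pl$pose, links = pl$links,
       decoys = decoys)
}

# a minimal hand-written PDB text with altlocs, for parser policy checks
write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.400   1.000   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# structure with exactly 10 native contacts: residues 1..12 spaced 10 A on
# a line, residues 13..22 each 4.0 A from residues 1..10
ten_contact_structure <- function() {
  base <- cbind(10 * (0:11), 0, 0)
  partners <- cbind(10 * (0:9), 4.0, 0)
  ca_structure(rbind(base, partners))
}
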