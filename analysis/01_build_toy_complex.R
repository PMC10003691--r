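#!/usr/bin/env Rscript
# Builds the synthetic study system: a C3 receptor trimer and a stacked
# ligand dimer of compact meander-fold toy domains, a planted clash-free
# docking pose, a cross-link table with 5 geometrically consistent DSBU
# links plus 2 planted false positives, and 20 random decoy poses displaced
# at least 50 A from the truth. Everything is written in the pipeline's
# plain-text interchange formats under results/fixtures/ so the later
# stages can run purely from disk.

suppressMessages(library(xldyn))

seed <- 1L
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

receptor <- make_toy_assembly(260, n_chains = 3, leg_length = 120)
ligand <- build_assembly(toy_chain(200, "helix", leg_length = 90),
                         list(identity_transform(),
                              translation_transform(c(0, 0, 44))))
message(sprintf("receptor: %d chains, %d atoms; ligand: %d chains, %d atoms",
                length(receptor$transforms), nrow(receptor$atoms),
                length(ligand$transforms), nrow(ligand$atoms)))

planted <- translation_transform(c(-55, -30, -10))
scene <- plant_pose_and_links(receptor, ligand, planted, "DSBU",
                              n_true = 5, n_false = 2, seed = seed)
message("planted links (truth labels ", paste(attr(scene$links, "truth"),
        collapse = ", "), "):")
print(as.data.frame(scene$links)[, 1:5])

decoys <- generate_decoy_poses(20, scene$pose, min_displacement = 50,
                               seed = seed + 7L)

write_structure(assembly_to_structure(receptor),
                file.path(out, "receptor.pdb"))
write_structure(assembly_to_structure(ligand),
                file.path(out, "ligand.pdb"))
write_crosslink_table(scene$links, file.path(out, "crosslinks.tsv"))
write_pose_list(c(list(scene$pose), decoys), file.path(out, "poses.tsv"))
write_transforms(receptor$transforms, file.path(out, "receptor_transforms.tsv"))

message("fixtures written under ", out)
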