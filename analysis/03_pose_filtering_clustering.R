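#!/usr/bin/env Rscript
# Scores every candidate pose (planted + 20 decoys) against the
# cross-link restraints and CA-level clashes, filters at the standard
# thresholds (>= 3 satisfied restraints, zero clashes), truncates the
# ranked list to 30, and Ward-clusters the survivors with medoid
# representatives. Run through the run_xl_eval() orchestrator so every
# intermediate lands in results/run/.

suppressMessages(library(xldyn))

fixtures <- "results/fixtures"

cfg <- run_config(
  receptor_proteins = "REC", ligand_proteins = "LIG",
  receptor_pdb = file.path(fixtures, "receptor.pdb"),
  ligand_pdb = file.path(fixtures, "ligand.pdb"),
  crosslink_table = file.path(fixtures, "crosslinks.tsv"),
  pose_list = file.path(fixtures, "poses.tsv"),
  min_satisfied = 3L, max_clash = 0L, n_keep = 30L, k_clusters = 3L,
  output_dir = "results/run", seed = 1L
)
report <- run_xl_eval(cfg)
print(report)

message("poses passing the restraint/clash filter: ",
        paste(report$passed, collapse = ", "))
message("kept after truncation: ", length(report$kept))
if (!is.null(report$clusters)) {
  message("cluster representatives: ",
          paste(report$clusters$representatives, collapse = ", "))
} else {
  message("too few survivors to cluster (expected when only the planted ",
          "pose survives)")
}
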