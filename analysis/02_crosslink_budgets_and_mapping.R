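#!/usr/bin/env Rscript
# Distance budgets for the registered linker chemistries, and cross-link
# mapping/satisfaction of the fixture's identification table on the
# planted receptor-ligand pose. The mapped distance of every link is its
# minimum CA-CA distance over all symmetric copy pairs, so links that
# could have formed with any copy of a homo-oligomer are credited to the
# closest one.

suppressMessages(library(xldyn))

fixtures <- "results/fixtures"
out <- "results"

budgets <- data.frame(
  linker = names(default_linkers()),
  budget_angstrom = vapply(names(default_linkers()), distance_budget, 0)
)
print(budgets)
write.table(budgets, file.path(out, "linker_budgets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

receptor <- as_assembly(read_structure(file.path(fixtures, "receptor.pdb")))
ligand <- as_assembly(read_structure(file.path(fixtures, "ligand.pdb")))
links <- read_crosslink_table(file.path(fixtures, "crosslinks.tsv"))
poses <- read_pose_list(file.path(fixtures, "poses.tsv"))
planted <- poses[["planted"]]

sc <- score_pose(planted, receptor, ligand, links,
                 receptor_proteins = "REC", ligand_proteins = "LIG")
report <- evaluate_satisfaction(sc$mapping)
print(report)
message(sprintf("%d of %d mappable links fall within budget at the planted pose",
                report$n_satisfied, report$n_mappable))
write_satisfaction_report(report, file.path(out, "satisfaction_planted.tsv"))
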