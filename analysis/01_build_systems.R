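#!/usr/bin/env Rscript
# Build the synthetic bilayer systems for the study conditions (0, 5 and
# 10 mol% DMSO) plus two pore scenarios with planted ground truth, write
# them as GRO trajectories (scratch/) and record their compositions.

source("analysis/00_common.R")

comp <- list()
for (name in names(conditions)) {
  tr <- build_condition(name)
  write_gro(tr, file.path(SCRATCH, sprintf("dmso_%s_molpct.gro", name)))
  mols <- tr$atoms[!duplicated(tr$atoms$mol_id), ]
  comp[[name]] <- data.frame(
    dmso_mol_pct = as.numeric(name),
    n_dopc = sum(mols$kind == "DOPC"), n_chol = sum(mols$kind == "CHOL"),
    n_water = sum(mols$kind == "WATER"), n_dmso = sum(mols$kind == "DMSO"),
    n_frames = n_frames(tr), n_atoms = nrow(tr$atoms))
  message(sprintf("built %s mol%% DMSO: %d atoms, %d DMSO molecules",
                  name, nrow(tr$atoms), sum(mols$kind == "DMSO")))
}
write_tsv(do.call(rbind, comp), file.path(RESULTS, "compositions.tsv"),
          tsv_header("synthetic system compositions (molecule counts)"))

# pore scenarios at the pore-suite scale: one stable hydrophilic pore
# (regime II) and three simultaneous transient columns (regime III)
pore_base <- function(seed, plan = NULL)
  generator_spec(n_dopc = 24, chol_mol_fraction = 0.2, n_solvent = 250,
                 box_xy = 2.5, seed = seed, pore_plan = plan)

tr2 <- generate_trajectory(pore_base(9102,
  pore_plan("HYDROPHILIC_PORE", radius = 0.15, n_lining_headgroups = 8,
            frames_present = 1:10)), n_frames = 10)
write_gro(tr2, file.path(SCRATCH, "pore_stable.gro"))
write_ground_truth(tr2, file.path(RESULTS, "pore_stable_ground_truth.tsv"))

tr3 <- generate_trajectory(pore_base(9103), n_frames = 10)
for (ax in list(c(0.65, 0.65), c(1.9, 0.65), c(1.25, 1.9)))
  tr3 <- plant_pore(tr3, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.1,
                                   frames_present = 4:6, axis_xy = ax))
write_gro(tr3, file.path(SCRATCH, "pore_multi.gro"))
write_ground_truth(tr3, file.path(RESULTS, "pore_multi_ground_truth.tsv"))

message("systems written to ", SCRATCH, "; compositions to ", RESULTS)
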