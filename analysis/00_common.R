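# Shared study conditions for the analysis scripts.
#
# Conditions mirror the reference DOPC/20 mol% Chol systems at desk scale:
# half the lipid count (80 lipids instead of 160), with per-condition
# structural targets taken from the corresponding rows of the reference
# summary table (area per lipid, P-P distance, mean -S_CD, tail tilt).
# Solvent is scaled to keep the solvent-per-lipid ratio comparable.

library(dmsopore)

RESULTS <- "results"
SCRATCH <- "scratch/systems"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH, showWarnings = FALSE, recursive = TRUE)

N_FRAMES <- 8

conditions <- list(
  `0` = list(dmso = 0.00, area = 44.5, pp = 4.17, scd = 0.1528,
              tail = 28.26, chol = 30.88, seed = 9001),
  `5` = list(dmso = 0.05, area = 58.1, pp = 3.60, scd = 0.0994,
              tail = 38.17, chol = 31.05, seed = 9005),
  `10` = list(dmso = 0.10, area = 68.4, pp = 3.14, scd = 0.0775,
              tail = 41.65, chol = 39.20, seed = 9010))

condition_spec <- function(cc, n_dopc = 64, n_solvent = 1500) {
  # area scales with the lipid count: half the lipids, half the area
  box_xy <- sqrt(cc$area * (n_dopc / 128))
  generator_spec(n_dopc = n_dopc, chol_mol_fraction = 0.20,
                 n_solvent = n_solvent, dmso_solvent_mol_fraction = cc$dmso,
                 box_xy = box_xy, leaflet_z_offset = cc$pp / 2,
                 target_mean_scd = cc$scd, target_tail_tilt_deg = cc$tail,
                 target_chol_tilt_deg = cc$chol, seed = cc$seed)
}

build_condition <- function(name) {
  generate_trajectory(condition_spec(conditions[[name]]), n_frames = N_FRAMES)
}

tsv_header <- function(...) {
  c(sprintf("dmsopore %s", as.character(utils::packageVersion("dmsopore"))),
    ...)
}
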