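#!/usr/bin/env Rscript
# DMSO/water composition conversions linking cell-assay volume fractions
# to the mole fractions used for the simulated solvent.

source("analysis/00_common.R")

vol <- c(0, 10, 20, 30, 40, 50, 60)
tab <- data.frame(dmso_vol_pct = vol,
                  dmso_mol_pct = vol_to_mol(vol),
                  back_converted_vol_pct = mol_to_vol(vol_to_mol(vol)))
write_tsv(tab, file.path(RESULTS, "mixture_conversions.tsv"),
          tsv_header("DMSO volume percent <-> mole percent",
                     "constants: rho 1.10/1.00 g/mL, M 78.13/18.02 g/mol, ideal mixing"))
message(paste(sprintf("%g vol%% = %.2f mol%%", vol, tab$dmso_mol_pct),
              collapse = "; "))
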