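#!/usr/bin/env Rscript
# Water-defect detection, tracking and regime classification on the
# no-pore reference and the two planted-pore scenarios.

source("analysis/00_common.R")

pore_base <- function(seed, plan = NULL)
  generator_spec(n_dopc = 24, chol_mol_fraction = 0.2, n_solvent = 250,
                 box_xy = 2.5, seed = seed, pore_plan = plan)

scenarios <- list(
  none = generate_trajectory(pore_base(9101), n_frames = 10),
  stable = generate_trajectory(pore_base(9102,
    pore_plan("HYDROPHILIC_PORE", radius = 0.15, n_lining_headgroups = 8,
              frames_present = 1:10)), n_frames = 10),
  multi = local({
    tr <- generate_trajectory(pore_base(9103), n_frames = 10)
    for (ax in list(c(0.65, 0.65), c(1.9, 0.65), c(1.25, 1.9)))
      tr <- plant_pore(tr, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.1,
                                     frames_present = 4:6, axis_xy = ax))
    tr
  }))

rows <- list(); ev_rows <- list()
for (name in names(scenarios)) {
  tr <- scenarios[[name]]
  events <- track_defects(tr)
  tab <- pore_event_table(events, n_frames_total = n_frames(tr))
  if (nrow(tab)) ev_rows[[name]] <- cbind(scenario = name, tab)
  rr <- classify_regime(tr)
  rows[[name]] <- data.frame(scenario = name, regime = rr$regime,
                             n_stable = rr$n_stable,
                             n_transient = rr$n_transient,
                             max_simultaneous = rr$max_simultaneous_spanning,
                             bilayer_intact = rr$bilayer_intact)
  message(sprintf("%-7s regime %-3s %s", name, rr$regime, rr$evidence))
}
write_tsv(do.call(rbind, ev_rows), file.path(RESULTS, "pore_events.tsv"),
          tsv_header("tracked spanning water defects",
                     "thresholds: O-O cutoff 0.35 nm, slab margin 0.3 nm,",
                     "lining radius 0.6 nm, lining >= 6, stability >= 10 frames"))
write_tsv(do.call(rbind, rows), file.path(RESULTS, "regimes.tsv"),
          tsv_header("per-trajectory regime labels",
                     "I: no stable pores; II: >=1 stable hydrophilic pore;",
                     "III: membrane destroyed or >=3 simultaneous spanning defects"))
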