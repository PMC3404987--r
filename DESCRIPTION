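Package: dmsopore
Title: Structural Analysis of DMSO Action on Cholesterol-Containing Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses of solvated lipid-bilayer configurations aimed at the
    action of dimethyl sulfoxide (DMSO) on DOPC/cholesterol membranes:
    per-component mass-density profiles on a scaled membrane coordinate,
    potential-of-mean-force profiles by Boltzmann inversion, deuterium chain
    order parameters, acyl-chain and cholesterol tilt angles, in-plane pair
    correlation of lipid centres of mass, dipole-orientation profiles of DMSO
    and water, and detection, tracking and classification of transmembrane
    water defects into transient hydrophobic columns and stable hydrophilic
    pores, with a trajectory-level regime label. Includes a statistical
    bilayer-configuration generator with planted ground truth that replaces
    molecular-dynamics output for testing, readers and writers for GRO and
    multi-MODEL PDB coordinates, and DMSO/water volume-to-mole composition
    conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
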