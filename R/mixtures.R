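#' Default constants for DMSO/water composition conversion
#'
#' Densities and molar masses used by [vol_to_mol()] and [mol_to_vol()].
#' Defaults: DMSO 1.10 g/mL and 78.13 g/mol, water 1.00 g/mL and
#' 18.02 g/mol, assuming ideal (excess-free) volume mixing.
#'
#' @param rho_dmso,rho_water densities, g/mL.
#' @param M_dmso,M_water molar masses, g/mol.
#' @return named list of the four constants.
#' @export
mixture_constants <- function(rho_dmso = 1.10, rho_water = 1.00,
                              M_dmso = 78.13, M_water = 18.02) {
  stopifnot(rho_dmso > 0, rho_water > 0, M_dmso > 0, M_water > 0)
  list(rho_dmso = rho_dmso, rho_water = rho_water,
       M_dmso = M_dmso, M_water = M_water)
}

#' Convert DMSO volume percent to mole percent
#'
#' For `v` vol% DMSO in water: `n_d = v * rho_d / M_d`,
#' `n_w = (100 - v) * rho_w / M_w`, result `100 * n_d / (n_d + n_w)`.
#' Under the default constants 10, 20, 30 and 40 vol% map to 2.74, 5.97,
#' 9.81 and 14.47 mol%.
#'
#' @param vol_percent DMSO volume percent, in `[0, 100]` (vectorised).
#' @param constants a [mixture_constants()] list.
#' @return DMSO mole percent of the solvent.
#' @export
vol_to_mol <- function(vol_percent, constants = mixture_constants()) {
  if (any(vol_percent < -1e-9 | vol_percent > 100 + 1e-9))
    stop("vol_percent must be in [0, 100]")
  vol_percent <- pmin(pmax(vol_percent, 0), 100)
  nd <- vol_percent * constants$rho_dmso / constants$M_dmso
  nw <- (100 - vol_percent) * constants$rho_water / constants$M_water
  100 * nd / (nd + nw)
}

#' Convert DMSO mole percent to volume percent
#'
#' Exact algebraic inverse of [vol_to_mol()] under the same constants:
#' the volume/mole round trip is an identity to machine precision.
#'
#' @param mol_percent DMSO mole percent, in `[0, 100]` (vectorised).
#' @param constants a [mixture_constants()] list.
#' @return DMSO volume percent.
#' @export
mol_to_vol <- function(mol_percent, constants = mixture_constants()) {
  if (any(mol_percent < -1e-9 | mol_percent > 100 + 1e-9))
    stop("mol_percent must be in [0, 100]")
  mol_percent <- pmin(pmax(mol_percent, 0), 100)
  a <- constants$rho_dmso / constants$M_dmso
  b <- constants$rho_water / constants$M_water
  m <- mol_percent
  100 * m * b / (100 * a - m * a + m * b)
}

#' Write a data frame as TSV with a commented header
#'
#' The only tabular dialect used by the package: tab-separated, `.`
#' decimal, `#`-prefixed comment lines naming units and the parameters of
#' the run, so outputs are reproducible byte for byte.
#'
#' @param df data.frame.
#' @param path output path.
#' @param comments character vector of header comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
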