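#' Default atom-role map
#'
#' Maps `(molecule kind, atom name)` pairs to analysis roles: phosphate
#' markers, cholesterol hydroxyl oxygens, water O/H, DMSO S/O/C and tail
#' carbons. The defaults cover the naming conventions used by common
#' united-atom DOPC/cholesterol topologies, 3-site waters (SPC-style
#' `OW`/`HW1`/`HW2` and `OH2`/`H1`/`H2`) and 4-site united-atom DMSO, plus
#' the names emitted by [build_bilayer()]. Users can supply their own map
#' (or load one with [read_role_map()]) to [assign_roles()].
#'
#' @return data.frame with columns `kind`, `name`, `role`.
#' @export
default_role_map <- function() {
  tailA <- paste0("C", 1:18, "A")
  tailB <- paste0("C", 1:18, "B")
  rbind(
    data.frame(kind = "DOPC", name = c("P", "P8"), role = "PHOSPHATE_MARKER"),
    data.frame(kind = "DOPC", name = c("N4", "CG"), role = "HEAD_OTHER"),
    data.frame(kind = "DOPC", name = c(tailA, tailB), role = "TAIL_CARBON"),
    data.frame(kind = "CHOL", name = c("O3", "OH"), role = "CHOL_HYDROXYL_O"),
    data.frame(kind = "CHOL", name = paste0("C", 1:17), role = "HEAD_OTHER"),
    data.frame(kind = "WATER", name = c("OW", "OH2", "O"), role = "WATER_O"),
    data.frame(kind = "WATER", name = c("HW1", "HW2", "H1", "H2"), role = "WATER_H"),
    data.frame(kind = "DMSO", name = c("S", "SD"), role = "DMSO_S"),
    data.frame(kind = "DMSO", name = c("O", "OD"), role = "DMSO_O"),
    data.frame(kind = "DMSO", name = c("C1", "C2", "CD1", "CD2"), role = "DMSO_C"),
    stringsAsFactors = FALSE)
}

#' Read a role map from a YAML file
#'
#' The file nests molecule kind over atom name over role, e.g.
#' `DOPC: {P: PHOSPHATE_MARKER}`. A shipped default lives at
#' `system.file("extdata", "role_map.yaml", package = "dmsopore")`.
#'
#' @param path YAML file path.
#' @return data.frame with columns `kind`, `name`, `role`.
#' @export
read_role_map <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(names(y), function(kind) {
    data.frame(kind = kind, name = names(y[[kind]]),
               role = unlist(y[[kind]], use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
}

#' Assign analysis roles (and masses) to every atom
#'
#' Looks every atom up in the role map by `(kind, name)`; unmapped atoms get
#' role `NONE` with a warning naming the affected kinds. Tail carbons get
#' their chain number and carbon position parsed from names of the form
#' `C<pos><A|B>`. Atomic masses are filled from the role (united-atom
#' carbons carry their implicit hydrogens). A DOPC molecule without a
#' phosphate marker is a configuration error: the P-P distance and leaflet
#' split would be undefined.
#'
#' @param traj a `bilayer_trajectory` or `bilayer_frame`.
#' @param role_map data.frame `(kind, name, role)`; default [default_role_map()].
#' @return the trajectory with `role`, `tail_chain`, `tail_pos` and `mass`
#'   populated; role counts are attached as attribute `role_counts`.
#' @export
assign_roles <- function(traj, role_map = default_role_map()) {
  was_frame <- inherits(traj, "bilayer_frame")
  traj <- .as_traj(traj)
  atoms <- traj$atoms
  key <- paste(atoms$kind, atoms$name, sep = "\r")
  mkey <- paste(role_map$kind, role_map$name, sep = "\r")
  hit <- match(key, mkey)
  atoms$role <- ifelse(is.na(hit), "NONE", role_map$role[hit])
  unmapped_kinds <- setdiff(unique(atoms$kind[is.na(hit)]), "OTHER")
  if (length(unmapped_kinds))
    warning("role map leaves atoms of kind(s) ",
            paste(unmapped_kinds, collapse = ", "), " without a role (NONE)")
  atoms$tail_chain <- NA_integer_
  atoms$tail_pos <- NA_integer_
  it <- which(atoms$role == "TAIL_CARBON")
  if (length(it)) {
    m <- regmatches(atoms$name[it], regexec("^C([0-9]+)([AB])$", atoms$name[it]))
    pos <- vapply(m, function(g) if (length(g) == 3) as.integer(g[2]) else NA_integer_,
                  integer(1))
    chain <- vapply(m, function(g) if (length(g) == 3) match(g[3], c("A", "B"))
                                   else NA_integer_, integer(1))
    atoms$tail_pos[it] <- pos
    atoms$tail_chain[it] <- chain
  }
  atoms$mass <- .mass_for(atoms)
  dopc_mols <- unique(atoms$mol_id[atoms$kind == "DOPC"])
  with_p <- unique(atoms$mol_id[atoms$role == "PHOSPHATE_MARKER"])
  if (length(setdiff(dopc_mols, with_p)))
    stop("configuration error: ", length(setdiff(dopc_mols, with_p)),
         " DOPC molecule(s) have no PHOSPHATE_MARKER atom; ",
         "P-P distance and leaflet assignment would be undefined")
  traj$atoms <- atoms
  attr(traj, "role_counts") <- table(atoms$role)
  if (was_frame) get_frame(traj, 1) else traj
}

# united-atom masses by role; terminal tail carbons are CH3
.mass_for <- function(atoms) {
  mass <- rep(NA_real_, nrow(atoms))
  r <- atoms$role
  mass[r == "PHOSPHATE_MARKER"] <- .MASS[["P"]]
  mass[r == "CHOL_HYDROXYL_O"] <- .MASS_OH
  mass[r == "WATER_O"] <- .MASS[["O"]]
  mass[r == "WATER_H"] <- .MASS[["H"]]
  mass[r == "DMSO_S"] <- .MASS[["S"]]
  mass[r == "DMSO_O"] <- .MASS[["O"]]
  mass[r == "DMSO_C"] <- .MASS_CH3
  mass[r == "HEAD_OTHER"] <- .MASS_CH
  # DOPC headgroup pseudo-atoms carry the rest of the lipid's 786 amu:
  # choline C5H13N and glycerol backbone + ester carbonyls + phosphate oxygens
  mass[atoms$kind == "DOPC" & atoms$name == "N4"] <- 104.17
  mass[atoms$kind == "DOPC" & atoms$name == "CG"] <- 143.84
  mass[r == "TAIL_CARBON"] <- .MASS_CH2
  it <- which(r == "TAIL_CARBON" & !is.na(atoms$tail_pos))
  if (length(it)) {
    # last carbon of each chain is a terminal methyl
    mx <- stats::ave(atoms$tail_pos[it], atoms$mol_id[it], atoms$tail_chain[it],
                     FUN = max)
    mass[it][atoms$tail_pos[it] == mx] <- .MASS_CH3
  }
  # single-site water (no hydrogens in the molecule) carries the full H2O mass
  iw <- which(r == "WATER_O")
  if (length(iw)) {
    has_h <- atoms$mol_id[iw] %in% atoms$mol_id[r == "WATER_H"]
    mass[iw][!has_h] <- .MASS_H2O
  }
  mass[is.na(mass)] <- 0
  mass
}
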