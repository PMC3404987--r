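#' Plan a transmembrane water defect to plant
#'
#' @param kind `"HYDROPHOBIC_COLUMN"` (bare single-file water column) or
#'   `"HYDROPHILIC_PORE"` (column plus relocated lipid headgroups lining it).
#' @param radius column radius, nm (`> 0`, `< box_xy/4`).
#' @param n_lining_headgroups headgroup atoms relocated to line the column
#'   (0 for a hydrophobic column).
#' @param frames_present integer frame indices carrying the defect; empty
#'   for a no-op plan.
#' @param axis_xy optional in-plane axis position, nm; default box centre.
#' @return object of class `pore_plan`.
#' @export
pore_plan <- function(kind = c("HYDROPHOBIC_COLUMN", "HYDROPHILIC_PORE"),
                      radius = 0.15, n_lining_headgroups = 0,
                      frames_present = integer(0), axis_xy = NULL) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("pore radius must be > 0")
  if (kind == "HYDROPHOBIC_COLUMN" && n_lining_headgroups != 0)
    stop("a HYDROPHOBIC_COLUMN has no lining headgroups")
  structure(list(kind = kind, radius = radius,
                 n_lining_headgroups = as.integer(n_lining_headgroups),
                 frames_present = as.integer(frames_present),
                 axis_xy = axis_xy),
            class = "pore_plan")
}

#' Plant a transmembrane water column in selected frames
#'
#' Relocates bulk water molecules (always the same molecules across frames,
#' so tracked events have overlapping membership) onto a tight single-file
#' column spanning the inter-phosphate slab, with consecutive oxygen
#' spacings safely below the 0.35 nm detector cutoff and in-plane offsets
#' within the column radius. A `HYDROPHILIC_PORE` additionally translates
#' `n_lining_headgroups` DOPC molecules rigidly so their phosphates sit
#' within the lining radius of the axis inside the slab. Topology and atom
#' counts are unchanged; the operation is deterministic (no RNG). Planted
#' ground truth is appended to attribute `planted`.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @param plan a [pore_plan()].
#' @return the modified trajectory.
#' @export
plant_pore <- function(traj, plan) {
  stopifnot(inherits(plan, "pore_plan"))
  traj <- .as_traj(traj)
  if (!length(plan$frames_present)) return(traj)
  if (any(plan$frames_present < 1 | plan$frames_present > n_frames(traj)))
    stop("frames_present outside the trajectory range")
  box <- traj$box[1, ]
  if (plan$radius >= min(box[1], box[2]) / 4)
    stop("pore radius ", plan$radius, " nm >= box_xy/4: the column would ",
         "self-interact through the periodic boundaries")
  atoms <- traj$atoms
  axis <- if (is.null(plan$axis_xy)) c(box[1] / 2, box[2] / 2) else plan$axis_xy

  # phosphate planes of the first planted frame size the column
  f0 <- plan$frames_present[1]
  ip <- which(atoms$role == "PHOSPHATE_MARKER")
  if (length(ip) < 2) stop("plant_pore needs phosphate markers")
  zp <- traj$coords[[f0]][ip, 3]
  mid <- mean(zp)
  z_lo <- mean(zp[zp <= mid]); z_hi <- mean(zp[zp > mid])
  m <- ceiling((z_hi - z_lo) / 0.15) + 1L

  used <- attr(traj, "pore_used_mols")
  wat_mols <- setdiff(unique(atoms$mol_id[atoms$kind == "WATER"]), used)
  if (length(wat_mols) < m)
    stop("not enough free water molecules (", length(wat_mols), ") to plant a ",
         m, "-molecule column")
  col_mols <- utils::tail(wat_mols, m)
  o_idx <- vapply(col_mols, function(mm)
    which(atoms$mol_id == mm & atoms$role == "WATER_O")[1], integer(1))
  mol_rows <- lapply(col_mols, function(mm) which(atoms$mol_id == mm))

  rj <- min(plan$radius * 0.8, 0.12)
  golden <- 2.39996
  offx <- rj * sqrt(((seq_len(m) - 1) %% 5) / 5) * cos(seq_len(m) * golden)
  offy <- rj * sqrt(((seq_len(m) - 1) %% 5) / 5) * sin(seq_len(m) * golden)

  lining_mols <- integer(0)
  if (plan$kind == "HYDROPHILIC_PORE" && plan$n_lining_headgroups > 0) {
    dopc <- unique(atoms$mol_id[atoms$kind == "DOPC"])
    if (length(dopc) < plan$n_lining_headgroups)
      stop("fewer DOPC molecules than requested lining headgroups")
    # draw evenly from both leaflets so neither mean phosphate plane is
    # dragged far toward the centre by the relocation
    pm <- atoms$mol_id[ip]
    pz <- traj$coords[[f0]][ip, 3]
    up_m <- intersect(dopc, pm[pz > mid])
    lo_m <- intersect(dopc, pm[pz <= mid])
    n_up <- ceiling(plan$n_lining_headgroups / 2)
    n_lo <- plan$n_lining_headgroups - n_up
    if (length(up_m) < n_up || length(lo_m) < n_lo)
      stop("not enough DOPC per leaflet for the requested lining")
    lining_mols <- c(utils::tail(up_m, n_up), utils::tail(lo_m, n_lo))
  }

  for (f in plan$frames_present) {
    xyz <- traj$coords[[f]]
    zpf <- xyz[ip, 3]
    midf <- mean(zpf)
    zlo <- mean(zpf[zpf <= midf]); zhi <- mean(zpf[zpf > midf])
    zs <- seq(zlo, zhi, length.out = m)
    for (k in seq_len(m)) {
      target <- c((axis[1] + offx[k]) %% box[1], (axis[2] + offy[k]) %% box[2],
                  zs[k])
      delta <- target - xyz[o_idx[k], ]
      rows <- mol_rows[[k]]
      xyz[rows, ] <- .wrap_positions(sweep(xyz[rows, , drop = FALSE], 2, -delta),
                                     box)
    }
    if (length(lining_mols)) {
      nl <- length(lining_mols)
      ang <- 2 * pi * (seq_len(nl) - 1) / nl
      # cluster the lining near the slab centre: safely inside the shrunken
      # slab even after the planes relax toward the relocated lipids
      zl <- (zlo + zhi) / 2 + seq(-0.5, 0.5, length.out = nl)
      rad <- plan$radius + 0.12
      for (k in seq_len(nl)) {
        rows <- which(atoms$mol_id == lining_mols[k])
        prow <- rows[atoms$role[rows] == "PHOSPHATE_MARKER"][1]
        target <- c((axis[1] + rad * cos(ang[k])) %% box[1],
                    (axis[2] + rad * sin(ang[k])) %% box[2], zl[k])
        delta <- target - xyz[prow, ]
        xyz[rows, ] <- .wrap_positions(sweep(xyz[rows, , drop = FALSE], 2, -delta),
                                       box)
      }
    }
    traj$coords[[f]] <- xyz
  }
  gt <- data.frame(frame = plan$frames_present, kind = plan$kind,
                   axis_x = axis[1], axis_y = axis[2], radius = plan$radius,
                   n_lining = plan$n_lining_headgroups, n_column_waters = m)
  attr(traj, "planted") <- rbind(attr(traj, "planted"), gt)
  attr(traj, "pore_used_mols") <- c(used, col_mols,
                                    if (length(lining_mols)) NULL)
  attr(traj, "pore_column_mols") <- c(attr(traj, "pore_column_mols"),
                                      list(col_mols))
  traj
}

#' Write planted-pore ground truth as TSV
#'
#' @param traj a trajectory that went through [plant_pore()].
#' @param path output path.
#' @return `path`, invisibly; writes an empty table when nothing was planted.
#' @export
write_ground_truth <- function(traj, path) {
  gt <- attr(traj, "planted")
  if (is.null(gt))
    gt <- data.frame(frame = integer(0), kind = character(0),
                     axis_x = numeric(0), axis_y = numeric(0),
                     radius = numeric(0), n_lining = integer(0),
                     n_column_waters = integer(0))
  write_tsv(gt, path, c("planted-pore ground truth",
                        "axis_x/axis_y/radius in nm"))
}

#' Sample solvent-only frames from a prescribed z-density
#'
#' Builds frames of single-site water molecules (mass 18.02 amu, role
#' `WATER_O`) whose z-coordinates are drawn by rejection sampling from a
#' user-supplied relative density; x and y are uniform. This is the ground
#' truth for density and potential-of-mean-force checks: sampling from
#' `exp(-U(z)/RT)` must Boltzmann-invert back to `U`.
#'
#' @param n_molecules molecules per frame.
#' @param n_frames_out number of frames.
#' @param box length-3 box, nm.
#' @param z_density function of z (nm) returning a relative density in
#'   `[0, 1]`; `NULL` for uniform.
#' @param seed RNG seed.
#' @return a `bilayer_trajectory`.
#' @export
sample_solvent_frames <- function(n_molecules, n_frames_out, box,
                                  z_density = NULL, seed = 1) {
  stopifnot(n_molecules > 0, n_frames_out >= 1, length(box) == 3)
  set.seed(seed)
  atoms <- data.frame(atom_id = seq_len(n_molecules),
                      mol_id = seq_len(n_molecules),
                      kind = "WATER", name = "OW", resname = "SOL",
                      resid = seq_len(n_molecules), role = "WATER_O",
                      tail_chain = NA_integer_, tail_pos = NA_integer_,
                      mass = .MASS_H2O, stringsAsFactors = FALSE)
  draw_z <- function(n) {
    if (is.null(z_density)) return(stats::runif(n, 0, box[3]))
    out <- numeric(0)
    while (length(out) < n) {
      z <- stats::runif(2 * n + 100, 0, box[3])
      keep <- stats::runif(length(z)) < z_density(z)
      out <- c(out, z[keep])
    }
    out[seq_len(n)]
  }
  frames <- lapply(seq_len(n_frames_out), function(f) {
    xyz <- cbind(stats::runif(n_molecules, 0, box[1]),
                 stats::runif(n_molecules, 0, box[2]), draw_z(n_molecules))
    bilayer_frame(atoms, xyz, box, time = f - 1)
  })
  as_trajectory(frames, frame_interval = 1)
}

#' A frame of isotropically oriented DMSO molecules
#'
#' Positions uniform in the box, O-to-S dipole directions uniform on the
#' sphere: the reference configuration for the random-orientation baseline
#' of the dipole-orientation profile (mean angle 90 degrees).
#'
#' @param n_molecules DMSO count.
#' @param box length-3 box, nm.
#' @param seed RNG seed.
#' @param sites `"full"` (S, O and two methyls) or `"dipole"` (S and O only).
#' @return a single-frame `bilayer_trajectory` with roles assigned.
#' @export
random_dmso_frame <- function(n_molecules, box = c(6, 6, 6), seed = 1,
                              sites = c("full", "dipole")) {
  sites <- match.arg(sites)
  set.seed(seed)
  s <- cbind(stats::runif(n_molecules, 0, box[1]),
             stats::runif(n_molecules, 0, box[2]),
             stats::runif(n_molecules, 0, box[3]))
  d <- .random_units(n_molecules)
  nsite <- if (sites == "full") 4L else 2L
  xyz <- matrix(0, nsite * n_molecules, 3)
  xyz[seq(1, by = nsite, length.out = n_molecules), ] <- s
  xyz[seq(2, by = nsite, length.out = n_molecules), ] <- s - 0.153 * d
  nm <- c("S", "O")
  if (sites == "full") {
    e <- .perp_units(d)
    cm <- cos(.rad(100)); sm <- sin(.rad(100))
    xyz[seq(3, by = nsite, length.out = n_molecules), ] <- s + 0.18 * (cm * d + sm * e)
    xyz[seq(4, by = nsite, length.out = n_molecules), ] <- s + 0.18 * (cm * d - sm * e)
    nm <- c("S", "O", "C1", "C2")
  }
  atoms <- data.frame(atom_id = seq_len(nsite * n_molecules),
                      mol_id = rep(seq_len(n_molecules), each = nsite),
                      kind = "DMSO", name = rep(nm, n_molecules),
                      resname = "DMSO", resid = rep(seq_len(n_molecules), each = nsite),
                      role = "NONE", tail_chain = NA_integer_,
                      tail_pos = NA_integer_, mass = NA_real_,
                      stringsAsFactors = FALSE)
  fr <- assign_roles(bilayer_frame(atoms, xyz, box))
  as_trajectory(list(fr), frame_interval = 1)
}
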