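#' @title Bilayer configuration data model
#' @description Internal constructors and accessors for the shared data model:
#' a topology table of atoms plus per-frame coordinate matrices and boxes.
#' @name model
NULL

.MOL_KINDS <- c("DOPC", "CHOL", "WATER", "DMSO", "OTHER")
.ROLES <- c("PHOSPHATE_MARKER", "CHOL_HYDROXYL_O", "WATER_O", "WATER_H",
            "DMSO_S", "DMSO_O", "DMSO_C", "TAIL_CARBON", "HEAD_OTHER", "NONE")

#' Construct a bilayer frame
#'
#' A frame couples a topology table (one row per atom) with an `n x 3`
#' coordinate matrix (nm) and a rectangular box. Positions are wrapped into
#' `[0, L)` on every axis; the bilayer normal is fixed to z.
#'
#' @param atoms data.frame with columns `atom_id`, `mol_id`, `kind`
#'   (DOPC/CHOL/WATER/DMSO/OTHER), `name`, `role`, `tail_chain`, `tail_pos`,
#'   `mass` (amu). `tail_chain`/`tail_pos` are `NA` except for tail carbons.
#' @param coords numeric matrix, one row per atom, columns x, y, z in nm.
#' @param box length-3 numeric, box edges `(Lx, Ly, Lz)` in nm, all `> 0`.
#' @param time frame time in ps.
#' @return object of class `bilayer_frame`.
#' @export
bilayer_frame <- function(atoms, coords, box, time = 0) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  stopifnot(nrow(atoms) == nrow(coords), ncol(coords) == 3)
  if (any(!is.finite(coords))) stop("non-finite coordinates in frame")
  if (any(box <= 0)) stop("box components must be > 0")
  coords <- .wrap_positions(coords, box)
  structure(list(atoms = atoms, coords = coords,
                 box = as.numeric(box), time = time),
            class = "bilayer_frame")
}

#' Construct a trajectory from frames sharing one topology
#'
#' @param frames list of [bilayer_frame()] objects with identical atom tables.
#' @param frame_interval time between frames, ps.
#' @return object of class `bilayer_trajectory` holding the shared `atoms`
#'   table, a list of coordinate matrices, a frames-by-3 `box` matrix and a
#'   `time` vector.
#' @export
as_trajectory <- function(frames, frame_interval = NULL) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  n <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(n)) != 1L)
    stop("frames disagree on atom count: ", paste(unique(n), collapse = ", "))
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0))
    times <- seq(0, by = if (is.null(frame_interval)) 1 else frame_interval,
                 length.out = length(frames))
  if (is.null(frame_interval))
    frame_interval <- if (length(times) > 1) diff(times)[1] else 1
  structure(list(
    atoms = frames[[1]]$atoms,
    coords = lapply(frames, `[[`, "coords"),
    box = do.call(rbind, lapply(frames, `[[`, "box")),
    time = times,
    frame_interval = frame_interval
  ), class = "bilayer_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `bilayer_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Extract one frame of a trajectory
#' @param traj a `bilayer_trajectory`.
#' @param i frame index (1-based).
#' @return a `bilayer_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  structure(list(atoms = traj$atoms, coords = traj$coords[[i]],
                 box = traj$box[i, ], time = traj$time[i]),
            class = "bilayer_frame")
}

#' @export
print.bilayer_trajectory <- function(x, ...) {
  cat(sprintf("bilayer_trajectory: %d frames, %d atoms, box %.2f x %.2f x %.2f nm\n",
              n_frames(x), nrow(x$atoms), x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  print(table(x$atoms$kind[!duplicated(x$atoms$mol_id)]))
  invisible(x)
}

#' @export
print.bilayer_frame <- function(x, ...) {
  cat(sprintf("bilayer_frame: %d atoms, t = %g ps, box %.2f x %.2f x %.2f nm\n",
              nrow(x$atoms), x$time, x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

.as_traj <- function(x) {
  if (inherits(x, "bilayer_trajectory")) return(x)
  if (inherits(x, "bilayer_frame")) return(as_trajectory(list(x)))
  stop("expected a bilayer_frame or bilayer_trajectory")
}

# reference atom per lipid molecule: DOPC phosphate marker, CHOL hydroxyl O
.lipid_ref_atoms <- function(atoms) {
  ref <- which((atoms$kind == "DOPC" & atoms$role == "PHOSPHATE_MARKER") |
               (atoms$kind == "CHOL" & atoms$role == "CHOL_HYDROXYL_O"))
  ref[!duplicated(atoms$mol_id[ref])]
}

#' Assign lipid molecules to leaflets
#'
#' The midplane is the mean z of all phosphate-marker atoms. Lipid and
#' cholesterol molecules whose reference atom (phosphate marker, hydroxyl
#' oxygen) lies above the midplane are assigned UPPER, all others LOWER;
#' a reference exactly at the midplane goes to LOWER (deterministic
#' tie-break). The outward normal of the UPPER leaflet is +z.
#'
#' @param frame a `bilayer_frame` with roles assigned.
#' @return list with `leaflet` (named character vector over lipid `mol_id`s,
#'   "UPPER"/"LOWER"), `midplane_z` (nm), `outward_normal` (list of unit
#'   z-vectors per leaflet) and `quality` ("ok" or "collapsed" when all
#'   phosphates sit on one side).
#' @export
assign_leaflets <- function(frame) {
  atoms <- frame$atoms
  ip <- which(atoms$role == "PHOSPHATE_MARKER")
  if (length(ip) < 2) stop("assign_leaflets needs at least 2 phosphate markers")
  zp <- frame$coords[ip, 3]
  mid <- mean(zp)
  ref <- .lipid_ref_atoms(atoms)
  zr <- frame$coords[ref, 3]
  side <- ifelse(zr > mid, "UPPER", "LOWER")
  names(side) <- atoms$mol_id[ref]
  up <- zp > mid
  # a bilayer that has lost its two phosphate planes (or whose planes have
  # merged) is flagged, not rejected: downstream regime logic uses the flag
  gap <- if (any(up) && any(!up)) mean(zp[up]) - mean(zp[!up]) else 0
  quality <- if (gap < 1.0) "collapsed" else "ok"
  list(leaflet = side, midplane_z = mid,
       outward_normal = list(UPPER = c(0, 0, 1), LOWER = c(0, 0, -1)),
       quality = quality)
}
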