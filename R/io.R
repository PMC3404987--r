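#' Read a GRO coordinate file (single- or multi-frame)
#'
#' Parses the fixed-column GRO dialect: title, atom count, `natoms` atom
#' lines (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f`, velocities ignored) and a box
#' line. Concatenated frames are read as a trajectory. Coordinates are nm
#' (GRO native). Frame times are taken from a `t=` tag on the title line
#' when present, otherwise numbered by `frame_interval`.
#'
#' @param path path to a `.gro` file.
#' @param frame_interval fallback time step between frames, ps.
#' @return a `bilayer_trajectory` (roles unassigned, all `NONE`).
#' @seealso [assign_roles()], [write_gro()]
#' @export
read_gro <- function(path, frame_interval = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  nat_ref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(nat))
      stop(sprintf("GRO parse error at line %d: expected atom count, got '%s'",
                   i + 1, lines[i + 1]))
    if (!is.na(nat_ref) && nat != nat_ref)
      stop(sprintf("GRO format error: frame at line %d has %d atoms, expected %d",
                   i, nat, nat_ref))
    nat_ref <- nat
    al <- lines[(i + 2):(i + 1 + nat)]
    if (length(al) < nat || any(nchar(al) < 44))
      stop(sprintf("GRO parse error: truncated atom line near line %d", i + 2))
    resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
    resname <- trimws(substr(al, 6, 10))
    aname <- trimws(substr(al, 11, 15))
    aid <- suppressWarnings(as.integer(substr(al, 16, 20)))
    x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    if (any(is.na(resid)) || any(is.na(x)) || any(is.na(y)) || any(is.na(z)))
      stop(sprintf("GRO parse error: malformed atom line near line %d",
                   i + 1 + which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))[1]))
    box <- as.numeric(strsplit(trimws(lines[i + 2 + nat]), "\\s+")[[1]])[1:3]
    if (any(is.na(box)) || any(box <= 0))
      stop(sprintf("GRO parse error at line %d: bad box line", i + 2 + nat))
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    time <- if (length(tm) == 2) as.numeric(tm[2])
            else (length(frames)) * frame_interval
    # new molecule whenever the residue number changes (GRO resids wrap at 99999)
    newmol <- c(TRUE, resid[-1] != resid[-nat] | resname[-1] != resname[-nat])
    atoms <- data.frame(
      atom_id = if (any(is.na(aid))) seq_len(nat) else aid,
      mol_id = cumsum(newmol),
      kind = .kind_from_resname(resname),
      name = aname, resname = resname, resid = resid,
      role = "NONE", tail_chain = NA_integer_, tail_pos = NA_integer_,
      mass = NA_real_, stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <-
      bilayer_frame(atoms, cbind(x, y, z), box, time = time)
    i <- i + nat + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("GRO parse error: no frames found in ", path)
  as_trajectory(frames, frame_interval = frame_interval)
}

.kind_from_resname <- function(resname) {
  up <- toupper(resname)
  out <- rep("OTHER", length(up))
  out[up %in% c("DOPC", "POPC", "DPPC")] <- "DOPC"
  out[up %in% c("CHOL", "CHL1", "CHO")] <- "CHOL"
  out[up %in% c("SOL", "WAT", "SPC", "TIP3", "HOH", "W")] <- "WATER"
  out[up %in% c("DMSO", "DMS")] <- "DMSO"
  out
}

#' Write a trajectory (or frame) as a GRO file
#'
#' Multi-frame trajectories are written as concatenated GRO frames with the
#' time on each title line. Coordinates are written at the format's native
#' three-decimal precision; atom and residue numbers wrap at 99999.
#'
#' @param traj a `bilayer_trajectory` or `bilayer_frame`.
#' @param path output path.
#' @param title title string for each frame.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, title = "dmsopore configuration") {
  traj <- .as_traj(traj)
  atoms <- traj$atoms
  resid <- if ("resid" %in% names(atoms)) atoms$resid else atoms$mol_id
  resname <- if ("resname" %in% names(atoms)) atoms$resname
             else .resname_from_kind(atoms$kind)
  con <- file(path, "w")
  on.exit(close(con))
  body_fmt <- "%5d%-5s%5s%5d%8.3f%8.3f%8.3f"
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[f]]
    writeLines(sprintf("%s, t= %.5f", title, traj$time[f]), con)
    writeLines(sprintf("%5d", nrow(atoms)), con)
    writeLines(sprintf(body_fmt, resid %% 100000L, resname, atoms$name,
                       atoms$atom_id %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1], traj$box[f, 2],
                       traj$box[f, 3]), con)
  }
  invisible(path)
}

.resname_from_kind <- function(kind) {
  c(DOPC = "DOPC", CHOL = "CHOL", WATER = "SOL", DMSO = "DMSO",
    OTHER = "UNK")[kind]
}

#' Read a (multi-MODEL) PDB coordinate file
#'
#' Minimal fixed-column ATOM/HETATM parser: coordinates are converted from
#' Angstrom to nm, the box is taken from the CRYST1 record, and
#' MODEL/ENDMDL blocks become trajectory frames.
#'
#' @param path path to a `.pdb` file.
#' @param frame_interval time step between MODELs, ps.
#' @return a `bilayer_trajectory`.
#' @export
read_pdb <- function(path, frame_interval = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  cr <- lines[trimws(rec) == "CRYST1"]
  box <- if (length(cr)) as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                                      substr(cr[1], 25, 33))) / 10
         else stop("PDB parse error: no CRYST1 record (box required)")
  model_starts <- which(trimws(rec) == "MODEL")
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  if (!any(is_atom)) stop("PDB parse error: no ATOM records in ", path)
  if (!length(model_starts)) {
    groups <- list(which(is_atom))
  } else {
    model_of <- findInterval(which(is_atom), model_starts)
    groups <- split(which(is_atom), model_of)
  }
  frames <- lapply(seq_along(groups), function(g) {
    al <- lines[groups[[g]]]
    aname <- trimws(substr(al, 13, 16))
    resname <- trimws(substr(al, 18, 21))
    resid <- as.integer(substr(al, 23, 26))
    xyz <- cbind(as.numeric(substr(al, 31, 38)),
                 as.numeric(substr(al, 39, 46)),
                 as.numeric(substr(al, 47, 54))) / 10
    if (any(is.na(xyz))) stop("PDB parse error: malformed coordinates in MODEL ", g)
    n <- length(al)
    newmol <- c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n])
    atoms <- data.frame(atom_id = seq_len(n), mol_id = cumsum(newmol),
                        kind = .kind_from_resname(resname), name = aname,
                        resname = resname, resid = resid, role = "NONE",
                        tail_chain = NA_integer_, tail_pos = NA_integer_,
                        mass = NA_real_, stringsAsFactors = FALSE)
    bilayer_frame(atoms, xyz, box, time = (g - 1) * frame_interval)
  })
  as_trajectory(frames, frame_interval = frame_interval)
}
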