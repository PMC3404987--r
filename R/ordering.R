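# Chain order, tilt, lateral pair correlation and dipole orientation.

# index triplets (prev, cur, next) over consecutive tail carbons, built once
# from the topology; chains shorter than 3 carbons are skipped with a warning
.tail_triplets <- function(atoms) {
  it <- which(atoms$role == "TAIL_CARBON" & !is.na(atoms$tail_pos))
  if (!length(it)) stop("no TAIL_CARBON atoms with tail_index present")
  key <- paste(atoms$mol_id[it], atoms$tail_chain[it])
  ord <- order(atoms$mol_id[it], atoms$tail_chain[it], atoms$tail_pos[it])
  it <- it[ord]; key <- key[ord]
  len <- ave(seq_along(it), key, FUN = length)
  if (any(len < 3)) {
    warning(sum(len < 3 & !duplicated(key)), " chain(s) shorter than 3 carbons skipped")
    it <- it[len >= 3]; key <- key[len >= 3]
  }
  # interior positions: rows i whose neighbours i-1, i+1 are in the same chain
  n <- length(it)
  interior <- which(seq_len(n) > 1 & seq_len(n) < n &
                    c(FALSE, key[-1] == key[-n]) &
                    c(key[-1] == key[-n], FALSE))
  list(idx = it, prev = it[interior - 1L], cur = it[interior],
       nxt = it[interior + 1L],
       chain = atoms$tail_chain[it[interior]],
       carbon = atoms$tail_pos[it[interior]])
}

#' Deuterium order parameter profile, -S_CD
#'
#' For every interior tail carbon the two C-H(D) directions are
#' reconstructed assuming ideal tetrahedral geometry (perpendicular to the
#' C(i-1) to C(i+1) axis, symmetric about the local chain plane; explicit
#' hydrogens are not expected in the united-atom model). `S_CD =
#' <(3 cos^2 theta - 1)/2>` with theta the C-H angle to the bilayer normal
#' (z); `-S_CD` is reported so larger means more ordered. Values are
#' averaged over the two hydrogens, all molecules and all frames; the mean
#' is the average over all CD segments.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @return an `order_profile`: list with `profile` (data.frame `chain`,
#'   `carbon`, `minus_scd`, `n_samples`) and `mean_minus_scd`.
#' @export
scd_profile <- function(traj) {
  traj <- .as_traj(traj)
  tri <- .tail_triplets(traj$atoms)
  acc <- NULL
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[f]]
    box <- traj$box[f, ]
    a <- .min_image(xyz[tri$prev, , drop = FALSE] - xyz[tri$cur, , drop = FALSE],
                    box, axes = 1:3)
    b <- .min_image(xyz[tri$nxt, , drop = FALSE] - xyz[tri$cur, , drop = FALSE],
                    box, axes = 1:3)
    v <- .ch_minus_scd(a, b)
    acc <- if (is.null(acc)) v else acc + v
  }
  acc <- acc / n_frames(traj)
  key <- paste(tri$chain, tri$carbon)
  agg <- rowsum(cbind(acc, 1), key)
  kk <- strsplit(rownames(agg), " ")
  prof <- data.frame(chain = as.integer(vapply(kk, `[`, "", 1)),
                     carbon = as.integer(vapply(kk, `[`, "", 2)),
                     minus_scd = agg[, 1] / agg[, 2],
                     n_samples = agg[, 2] * n_frames(traj))
  prof <- prof[order(prof$chain, prof$carbon), ]
  rownames(prof) <- NULL
  structure(list(profile = prof, mean_minus_scd = mean(acc)),
            class = "order_profile")
}

#' @export
print.order_profile <- function(x, ...) {
  cat(sprintf("order_profile: mean -S_CD = %.4f over %d (chain, carbon) segments\n",
              x$mean_minus_scd, nrow(x$profile)))
  invisible(x)
}

#' Mean acyl-chain and cholesterol tilt angles
#'
#' The acyl vector runs from the first to the last tail carbon, the
#' cholesterol axis from the hydroxyl oxygen to its last ring-axis carbon.
#' Each angle is measured against the molecule's leaflet outward normal and
#' folded to `[0, 90]` degrees (vector vs axis), then averaged over
#' molecules and frames.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @return list with `tail_tilt_deg` and `chol_tilt_deg` (`NA` without Chol).
#' @export
tilt_angles <- function(traj) {
  traj <- .as_traj(traj)
  atoms <- traj$atoms
  it <- which(atoms$role == "TAIL_CARBON" & !is.na(atoms$tail_pos))
  ord <- it[order(atoms$mol_id[it], atoms$tail_chain[it], atoms$tail_pos[it])]
  key <- paste(atoms$mol_id[ord], atoms$tail_chain[ord])
  first <- ord[!duplicated(key)]
  last <- rev(rev(ord)[!duplicated(rev(key))])
  # cholesterol axis atoms: hydroxyl O and the highest-numbered ring carbon
  io <- which(atoms$role == "CHOL_HYDROXYL_O")
  chol_last <- integer(0)
  if (length(io)) {
    ic <- which(atoms$kind == "CHOL" & grepl("^C[0-9]+$", atoms$name))
    cnum <- as.integer(sub("^C", "", atoms$name[ic]))
    keep <- !is.na(cnum)
    ic <- ic[keep]; cnum <- cnum[keep]
    if (length(ic)) {
      mx <- ave(cnum, atoms$mol_id[ic], FUN = max)
      sel <- ic[cnum == mx]
      chol_last <- sel[match(atoms$mol_id[io], atoms$mol_id[sel])]
      miss <- is.na(chol_last)
      if (any(miss)) {
        warning(sum(miss), " cholesterol molecule(s) without ring-axis carbons skipped")
        io <- io[!miss]; chol_last <- chol_last[!miss]
      }
    } else {
      warning("cholesterol present but no ring-axis carbons found; Chol tilt skipped")
      io <- integer(0)
    }
  }
  tail_sum <- 0; tail_n <- 0L; chol_sum <- 0; chol_n <- 0L
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[f]]
    box <- traj$box[f, ]
    v <- .min_image(xyz[last, , drop = FALSE] - xyz[first, , drop = FALSE],
                    box, axes = 1:3)
    cz <- abs(v[, 3] / .row_norms(v))
    ang <- .deg(acos(pmin(cz, 1)))
    tail_sum <- tail_sum + sum(ang); tail_n <- tail_n + length(ang)
    if (length(io)) {
      vc <- .min_image(xyz[chol_last, , drop = FALSE] - xyz[io, , drop = FALSE],
                       box, axes = 1:3)
      czc <- abs(vc[, 3] / .row_norms(vc))
      angc <- .deg(acos(pmin(czc, 1)))
      chol_sum <- chol_sum + sum(angc); chol_n <- chol_n + length(angc)
    }
  }
  list(tail_tilt_deg = tail_sum / tail_n,
       chol_tilt_deg = if (chol_n) chol_sum / chol_n else NA_real_)
}

#' In-plane pair correlation of DOPC centres of mass
#'
#' Per leaflet, the two-dimensional radial distribution of DOPC centres of
#' mass with in-plane minimum image: ordered pair counts per annulus,
#' normalised by the exact annulus area times the reference density
#' `(n - 1)/area` times the reference count, so an ideal (Poisson) system
#' gives 1 at all r. Cross-leaflet pairs are excluded; the two leaflet
#' curves are averaged.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @param bin_width annulus width, nm.
#' @param r_max maximum distance, nm; must be at most `min(Lx, Ly)/2`
#'   (default exactly that bound).
#' @return a `lateral_correlation`: data.frame `r_nm`, `c_value`, plus
#'   attributes `reference_density` (molecules/nm^2) and `n_pairs`.
#' @export
lateral_correlation <- function(traj, bin_width = 0.1, r_max = NULL) {
  traj <- .as_traj(traj)
  box <- traj$box[1, ]
  bound <- min(box[1], box[2]) / 2
  if (is.null(r_max)) r_max <- bound
  if (r_max > bound + 1e-9)
    stop("r_max = ", r_max, " nm exceeds min(Lx, Ly)/2 = ", bound, " nm")
  nb <- ceiling(r_max / bin_width)
  atoms <- traj$atoms
  dopc_rows <- which(atoms$kind == "DOPC")
  if (!length(dopc_rows)) stop("no DOPC molecules")
  mols <- unique(atoms$mol_id[dopc_rows])
  first_row <- dopc_rows[!duplicated(atoms$mol_id[dopc_rows])]
  counts <- matrix(0, 2, nb)   # per leaflet
  norm <- c(0, 0)
  rho_ref <- 0
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[f]]
    boxf <- traj$box[f, ]
    # molecule centres of mass, unwrapped relative to each first atom
    rel <- .min_image(xyz[dopc_rows, , drop = FALSE] -
                      xyz[first_row[match(atoms$mol_id[dopc_rows], mols)], ,
                          drop = FALSE], boxf, axes = 1:3)
    w <- atoms$mass[dopc_rows]
    grp <- match(atoms$mol_id[dopc_rows], mols)
    com <- rowsum(rel * w, grp) / rowsum(w, grp)[, 1] +
      xyz[first_row, , drop = FALSE]
    lf <- assign_leaflets(get_frame(traj, f))
    side <- lf$leaflet[as.character(mols)]
    for (s in 1:2) {
      pts <- com[side == c("UPPER", "LOWER")[s], , drop = FALSE]
      n <- nrow(pts)
      if (n < 2) stop("lateral_correlation needs at least 2 DOPC per leaflet")
      dx <- outer(pts[, 1], pts[, 1], "-"); dx <- dx - boxf[1] * round(dx / boxf[1])
      dy <- outer(pts[, 2], pts[, 2], "-"); dy <- dy - boxf[2] * round(dy / boxf[2])
      d2 <- dx^2 + dy^2
      r <- sqrt(d2[upper.tri(d2)])
      h <- tabulate(floor(r / bin_width) + 1L, nb)
      counts[s, ] <- counts[s, ] + 2 * h      # ordered pairs
      norm[s] <- norm[s] + n * (n - 1) / (boxf[1] * boxf[2])
      rho_ref <- rho_ref + (n - 1) / (boxf[1] * boxf[2])
    }
  }
  area_k <- pi * diff((seq(0, nb) * bin_width)^2)
  cmat <- sweep(counts, 2, area_k, "/") / norm
  out <- data.frame(r_nm = (seq_len(nb) - 0.5) * bin_width,
                    c_value = colMeans(cmat))
  structure(out, class = c("lateral_correlation", "data.frame"),
            reference_density = rho_ref / (2 * n_frames(traj)),
            n_pairs = sum(counts) / 2, annulus_area = area_k,
            per_leaflet_counts = counts, per_leaflet_norm = norm)
}

#' Dipole orientation profile along the scaled membrane coordinate
#'
#' Per molecule and frame: the DMSO dipole is the O-to-S vector, the water
#' dipole the bisector of the two O-H bonds (negative to positive end in
#' both cases). The angle is taken against the outward normal of the
#' molecule's nearer leaflet (by the sign of its Z') and binned by Z'. In a
#' system without phosphate markers the raw distance to the box midplane
#' (nm) is used as the coordinate. A random orientation averages to 90
#' degrees.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @param species `"DMSO"` or `"WATER"`.
#' @param bin_width bin width in Z' units (or nm without a membrane).
#' @return an `orientation_profile`: data.frame `z_scaled`,
#'   `mean_angle_deg`, `n_samples`; empty bins are `NA` and flagged.
#' @export
dipole_orientation_profile <- function(traj, species = c("DMSO", "WATER"),
                                       bin_width = 0.1) {
  traj <- .as_traj(traj)
  species <- match.arg(species)
  atoms <- traj$atoms
  if (species == "DMSO") {
    i_ref <- which(atoms$role == "DMSO_S")
    i_o <- which(atoms$role == "DMSO_O")
    if (!length(i_ref) || !length(i_o))
      stop("DMSO dipole atoms (DMSO_S, DMSO_O) not mapped")
    i_o <- i_o[match(atoms$mol_id[i_ref], atoms$mol_id[i_o])]
    if (any(is.na(i_o))) stop("DMSO molecules missing their O atom")
  } else {
    i_ref <- which(atoms$role == "WATER_O")
    ih <- which(atoms$role == "WATER_H")
    if (!length(i_ref) || !length(ih))
      stop("water dipole atoms (WATER_O, 2x WATER_H) not mapped")
    h_by_mol <- split(ih, atoms$mol_id[ih])
    if (any(vapply(h_by_mol, length, integer(1)) != 2))
      stop("each water molecule needs exactly two WATER_H atoms")
    hm <- do.call(rbind, h_by_mol)
    hm <- hm[match(atoms$mol_id[i_ref], as.integer(rownames(hm))), , drop = FALSE]
    ih1 <- hm[, 1]; ih2 <- hm[, 2]
  }
  has_p <- any(atoms$role == "PHOSPHATE_MARKER")
  sc <- if (has_p) .scaling_params(traj) else NULL
  zs_all <- numeric(0); ang_all <- numeric(0)
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[f]]
    box <- traj$box[f, ]
    if (species == "DMSO") {
      d <- .min_image(xyz[i_ref, , drop = FALSE] - xyz[i_o, , drop = FALSE],
                      box, axes = 1:3)
    } else {
      b1 <- .unit_rows(.min_image(xyz[ih1, , drop = FALSE] -
                                  xyz[i_ref, , drop = FALSE], box, axes = 1:3))
      b2 <- .unit_rows(.min_image(xyz[ih2, , drop = FALSE] -
                                  xyz[i_ref, , drop = FALSE], box, axes = 1:3))
      d <- b1 + b2
    }
    d <- .unit_rows(d)
    z <- xyz[i_ref, 3]
    zs <- if (has_p) .scale_z(z, sc) else z - box[3] / 2
    outward <- ifelse(zs >= 0, 1, -1)
    ang <- .deg(acos(pmin(pmax(d[, 3] * outward, -1), 1)))
    zs_all <- c(zs_all, zs); ang_all <- c(ang_all, ang)
  }
  zmax <- max(abs(zs_all))
  nb <- ceiling(zmax / bin_width + 1e-9)
  breaks <- seq(-nb * bin_width, nb * bin_width, by = bin_width)
  bin <- findInterval(zs_all, breaks, rightmost.closed = TRUE)
  agg_n <- tabulate(bin, 2 * nb)
  agg_s <- numeric(2 * nb)
  t <- rowsum(ang_all, bin)
  agg_s[as.integer(rownames(t))] <- t[, 1]
  out <- data.frame(z_scaled = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    mean_angle_deg = ifelse(agg_n > 0, agg_s / agg_n, NA_real_),
                    n_samples = agg_n)
  structure(out, class = c("orientation_profile", "data.frame"),
            species = species, scaled = has_p,
            n_empty_bins = sum(agg_n == 0))
}
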