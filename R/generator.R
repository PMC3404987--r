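#' Specify a synthetic bilayer system
#'
#' Describes a DOPC/cholesterol bilayer solvated in a water/DMSO mixture.
#' Configurations are drawn statistically (no forces, no dynamics): frames
#' are independent samples whose ensemble statistics are tuned to the
#' requested observables, which is what the time-averaged analyses consume.
#' Defaults reproduce the reference composition: 128 DOPC with 20 mol%
#' cholesterol (32 Chol), 6186 solvent molecules, phosphate-plane
#' half-separation 2.085 nm (P-P distance 4.17 nm), mean deuterium order
#' parameter 0.1528, tail tilt 28.26 deg and Chol tilt 30.88 deg.
#'
#' @param n_dopc number of DOPC molecules (even; split over two leaflets).
#' @param chol_mol_fraction cholesterol fraction of all lipids, in `[0, 1)`;
#'   the Chol count is `round(f/(1-f) * n_dopc)`, ties away from zero.
#' @param n_solvent total solvent molecules (water + DMSO).
#' @param dmso_solvent_mol_fraction DMSO mole fraction of the solvent, `[0, 1]`.
#' @param box_xy lateral box edge, nm.
#' @param box_z box height, nm; default leaves ~2.5 nm of solvent per side.
#' @param leaflet_z_offset phosphate-plane half-separation, nm.
#' @param target_mean_scd ensemble mean `-S_CD` the chains are tuned to,
#'   in `[0, 0.5]`.
#' @param target_tail_tilt_deg mean acyl-chain tilt versus the bilayer
#'   normal, degrees.
#' @param target_chol_tilt_deg mean cholesterol-axis tilt, degrees.
#' @param dmso_interface_width width (sd, nm) of the interfacial Gaussian
#'   component of the DMSO distribution, centred just below the phosphate
#'   planes.
#' @param dmso_interface_fraction fraction of DMSO placed in the
#'   interfacial component (the rest is bulk).
#' @param dmso_dipole_mean_angle mean angle (degrees) between the O-to-S
#'   dipole of interfacial DMSO and the outward leaflet normal; `NA` for
#'   isotropic orientations everywhere.
#' @param water_core_penetration relative water density at the bilayer
#'   centre (`Z' = 0`), `[0, 1]`; the water density decays smoothly from the
#'   bulk value at the phosphate planes to this floor.
#' @param undulation_amplitude amplitude (nm) of a single-mode height
#'   undulation of the lipid planes; default 0 (flat).
#' @param pore_plan optional [pore_plan()] executed by [generate_trajectory()].
#' @param seed integer; fixes all randomness.
#' @param excluded_volume enforce a 0.25 nm minimum distance between solvent
#'   heavy atoms (rejection with retry cap).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_dopc = 128, chol_mol_fraction = 0.20,
                           n_solvent = 6186, dmso_solvent_mol_fraction = 0,
                           box_xy = 6.67, box_z = NULL,
                           leaflet_z_offset = 2.085,
                           target_mean_scd = 0.1528,
                           target_tail_tilt_deg = 28.26,
                           target_chol_tilt_deg = 30.88,
                           dmso_interface_width = 0.35,
                           dmso_interface_fraction = 0.5,
                           dmso_dipole_mean_angle = 110,
                           water_core_penetration = 0.05,
                           undulation_amplitude = 0,
                           pore_plan = NULL, seed = 1,
                           excluded_volume = TRUE) {
  if (n_dopc %% 2 != 0) stop("n_dopc must be even (two equal leaflets)")
  if (chol_mol_fraction < 0 || chol_mol_fraction >= 1)
    stop("chol_mol_fraction must be in [0, 1)")
  if (dmso_solvent_mol_fraction < 0 || dmso_solvent_mol_fraction > 1)
    stop("dmso_solvent_mol_fraction must be in [0, 1]")
  if (water_core_penetration < 0 || water_core_penetration > 1)
    stop("water_core_penetration must be in [0, 1]")
  if (target_mean_scd < 0 || target_mean_scd > 0.5)
    stop("target_mean_scd must be in [0, 0.5]")
  if (box_xy <= 0 || leaflet_z_offset <= 0) stop("box_xy and leaflet_z_offset must be > 0")
  if (n_solvent < 0 || n_dopc < 0) stop("counts must be >= 0")
  if (is.null(box_z)) box_z <- 2 * leaflet_z_offset + 5
  if (box_z <= 2 * leaflet_z_offset + 1)
    stop("box_z leaves no solvent slab; increase it")
  n_chol <- chol_count(n_dopc, chol_mol_fraction)
  if (n_chol %% 2 != 0)
    stop("cholesterol count ", n_chol, " is odd; adjust composition for equal leaflets")
  structure(list(n_dopc = n_dopc, chol_mol_fraction = chol_mol_fraction,
                 n_chol = n_chol, n_solvent = n_solvent,
                 dmso_solvent_mol_fraction = dmso_solvent_mol_fraction,
                 box_xy = box_xy, box_z = box_z,
                 leaflet_z_offset = leaflet_z_offset,
                 target_mean_scd = target_mean_scd,
                 target_tail_tilt_deg = target_tail_tilt_deg,
                 target_chol_tilt_deg = target_chol_tilt_deg,
                 dmso_interface_width = dmso_interface_width,
                 dmso_interface_fraction = dmso_interface_fraction,
                 dmso_dipole_mean_angle = dmso_dipole_mean_angle,
                 water_core_penetration = water_core_penetration,
                 undulation_amplitude = undulation_amplitude,
                 pore_plan = pore_plan, seed = as.integer(seed),
                 excluded_volume = excluded_volume),
            class = "generator_spec")
}

#' Cholesterol count for a lipid composition
#'
#' Nearest-integer count (ties away from zero) such that Chol makes up
#' `chol_mol_fraction` of all lipids: `round(f/(1-f) * n_dopc)`.
#' At 20 mol% with 128 DOPC this gives 32.
#'
#' @param n_dopc DOPC count.
#' @param chol_mol_fraction Chol fraction of total lipids, `[0, 1)`.
#' @return integer Chol count.
#' @export
chol_count <- function(n_dopc, chol_mol_fraction) {
  stopifnot(chol_mol_fraction >= 0, chol_mol_fraction < 1)
  as.integer(.round_half_away(chol_mol_fraction / (1 - chol_mol_fraction) * n_dopc))
}

#' DMSO molecule count for a solvent composition
#'
#' Nearest-integer count, ties away from zero: `round(f * n_solvent)`.
#' 10 mol% of 6186 solvent molecules gives 619 DMSO (and 5567 waters).
#'
#' @param n_solvent total solvent molecules.
#' @param dmso_solvent_mol_fraction DMSO mole fraction, `[0, 1]`.
#' @return integer DMSO count.
#' @export
dmso_count <- function(n_solvent, dmso_solvent_mol_fraction) {
  stopifnot(dmso_solvent_mol_fraction >= 0, dmso_solvent_mol_fraction <= 1)
  as.integer(.round_half_away(dmso_solvent_mol_fraction * n_solvent))
}

# ---------------------------------------------------------------------------
# chain-order calibration
#
# Acyl chains are built from bond segments whose directions follow a von
# Mises-Fisher distribution about the chain axis; the concentration kappa is
# solved by bisection so that the -S_CD implied by the same tetrahedral C-H
# reconstruction the analysis uses matches target_mean_scd. The solution
# depends only on (target_mean_scd, tilt distribution), so it is cached.
# ---------------------------------------------------------------------------

.gen_cache <- new.env(parent = emptyenv())

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# mean -S_CD of the two reconstructed C-H vectors, one value per carbon;
# a, b are the minimum-imaged vectors C_i -> C_{i-1} and C_i -> C_{i+1}
.ch_minus_scd <- function(a, b) {
  v <- .unit_rows(b - a)
  m <- -(a + b) / 2
  s <- m - v * rowSums(m * v)
  ns <- .row_norms(s)
  bad <- ns < 1e-9
  if (any(bad)) {
    # collinear backbone: any perpendicular pair serves (deterministic pick)
    vb <- v[bad, , drop = FALSE]
    e <- matrix(rep(c(1, 0, 0), each = nrow(vb)), ncol = 3)
    par <- abs(vb[, 1]) > 0.9
    if (any(par)) e[par, ] <- matrix(rep(c(0, 1, 0), each = sum(par)), ncol = 3)
    s[bad, ] <- .cross_rows(vb, e)
    ns[bad] <- .row_norms(s[bad, , drop = FALSE])
  }
  s <- s / pmax(ns, 1e-300)
  p <- .cross_rows(v, s)
  ca <- 1 / sqrt(3)   # cos / sin of the tetrahedral half-angle (54.7356 deg)
  sa <- sqrt(2 / 3)
  h1z <- ca * s[, 3] + sa * p[, 3]
  h2z <- ca * s[, 3] - sa * p[, 3]
  -((3 * h1z^2 - 1) / 2 + (3 * h2z^2 - 1) / 2) / 2
}

# draw segment direction sets for n_chain chains about per-chain unit axes;
# each chain's segments are rigidly rotated so their vector sum points
# exactly along its axis (first-to-last carbon vector == axis direction)
.sample_chain_segments <- function(axis, kappa, n_seg) {
  n_chain <- nrow(axis)
  n <- n_chain * n_seg
  ct <- pmin(pmax(.rvmf_cos(n, kappa), -1), 1)
  phi <- stats::runif(n, 0, 2 * pi)
  d0 <- .sph_unit(acos(ct), phi)
  arep <- axis[rep(seq_len(n_chain), each = n_seg), , drop = FALSE]
  ez <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  d <- .rotate_align(d0, ez, arep)
  grp <- rep(seq_len(n_chain), each = n_seg)
  S <- rowsum(d, grp)
  Sh <- .unit_rows(S)
  .rotate_align(d, Sh[rep(seq_len(n_chain), each = n_seg), , drop = FALSE], arep)
}

# implied mean -S_CD for a candidate kappa under the generator's own
# geometry (same axis distribution, same alignment, same reconstruction)
.implied_scd <- function(kappa, tilt_deg, tilt_sd_deg, n_carbons, n_chain, seed) {
  .with_seed(seed, {
    n_seg <- n_carbons - 1L
    th <- .rtrunc_angle(n_chain, .rad(tilt_deg), .rad(tilt_sd_deg), 0, pi / 2)
    ph <- stats::runif(n_chain, 0, 2 * pi)
    axis <- .sph_unit(th, ph)
    d <- .sample_chain_segments(axis, kappa, n_seg)
    keep <- rep(seq_len(n_seg - 1L), n_chain) +
      rep((seq_len(n_chain) - 1L) * n_seg, each = n_seg - 1L)
    a <- -d[keep, , drop = FALSE]
    b <- d[keep + 1L, , drop = FALSE]
    mean(.ch_minus_scd(a * 0.125, b * 0.125))
  })
}

.chain_kappa <- function(spec, n_chain = 12000, seed = 48151) {
  key <- sprintf("%.6f|%.4f|%d", spec$target_mean_scd, spec$target_tail_tilt_deg, seed)
  if (!is.null(.gen_cache[[key]])) return(.gen_cache[[key]])
  f <- function(k) .implied_scd(k, spec$target_tail_tilt_deg, 3, 18, n_chain, seed)
  lo <- 0; hi <- 500
  fhi <- f(hi)
  if (fhi < spec$target_mean_scd - 0.004) {
    warning(sprintf(paste0("target_mean_scd = %.4f exceeds the maximum ~%.4f ",
                           "attainable at tail tilt %.2f deg; using straight chains"),
                    spec$target_mean_scd, fhi, spec$target_tail_tilt_deg))
    .gen_cache[[key]] <- hi
    return(hi)
  }
  flo <- f(lo)
  if (flo > spec$target_mean_scd) {
    .gen_cache[[key]] <- lo
    return(lo)
  }
  for (i in 1:36) {
    mid <- (lo + hi) / 2
    if (f(mid) < spec$target_mean_scd) lo <- mid else hi <- mid
  }
  .gen_cache[[key]] <- (lo + hi) / 2
  (lo + hi) / 2
}

# ---------------------------------------------------------------------------
# frame construction
# ---------------------------------------------------------------------------

# DOPC sites: phosphate marker, choline (N4) and glycerol/ester (CG)
# pseudo-atoms carrying the remaining headgroup mass, then two 18-carbon tails
.DOPC_NAMES <- c("P", "N4", "CG", paste0("C", 1:18, "A"), paste0("C", 1:18, "B"))
.DOPC_NATOMS <- length(.DOPC_NAMES)
.CHOL_NAMES <- c("O3", paste0("C", 1:8))
.BOND <- 0.125       # C-C step projected on the chain direction, nm
.CHOL_STEP <- 0.11   # ring-axis carbon spacing, nm

.undulation <- function(x, y, spec) {
  if (spec$undulation_amplitude == 0) return(rep(0, length(x)))
  spec$undulation_amplitude * sin(2 * pi * x / spec$box_xy) *
    cos(2 * pi * y / spec$box_xy)
}

# one leaflet of lipids; side = +1 (upper) or -1 (lower); uses current RNG
.build_leaflet <- function(spec, kappa, side) {
  nd <- spec$n_dopc %/% 2L
  nc <- spec$n_chol %/% 2L
  m <- nd + nc
  if (m == 0) return(NULL)
  mid <- spec$box_z / 2
  plane <- mid + side * spec$leaflet_z_offset
  k <- ceiling(sqrt(m))
  sp <- spec$box_xy / k
  if (sp < 0.5)
    stop("generation error: box_xy too small to place ", m,
         " lipids per leaflet without overlap; use a larger box")
  g <- expand.grid(ix = seq_len(k), iy = seq_len(k))
  g <- g[sample.int(nrow(g), m), , drop = FALSE]
  sx <- (g$ix - 0.5) * sp + stats::rnorm(m, 0, 0.08 * sp)
  sy <- (g$iy - 0.5) * sp + stats::rnorm(m, 0, 0.08 * sp)
  is_chol <- rep(c(FALSE, TRUE), c(nd, nc))

  out <- list()
  if (nd > 0) {
    px <- sx[!is_chol]; py <- sy[!is_chol]
    pz <- plane + .undulation(px, py, spec) + stats::rnorm(nd, 0, 0.03)
    nch <- 2L * nd
    th <- .rtrunc_angle(nch, .rad(spec$target_tail_tilt_deg), .rad(3), 0, pi / 2)
    ph <- stats::runif(nch, 0, 2 * pi)
    axis <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), -side * cos(th))
    segs <- .sample_chain_segments(axis, kappa, 17L)
    adir <- stats::runif(nd, 0, 2 * pi)
    ax <- rep(px, each = 2) + c(rbind(cos(adir), -cos(adir))) * 0.15
    ay <- rep(py, each = 2) + c(rbind(sin(adir), -sin(adir))) * 0.15
    az <- rep(pz, each = 2) - side * 0.30
    C <- array(0, c(nch, 18L, 3L))
    C[, 1L, ] <- cbind(ax, ay, az)
    for (j in 1:17)
      C[, j + 1L, ] <- C[, j, ] + .BOND * segs[(seq_len(nch) - 1L) * 17L + j, ,
                                               drop = FALSE]
    na <- .DOPC_NATOMS
    coords <- matrix(0, nd * na, 3L)
    coords[seq(1L, by = na, length.out = nd), ] <- cbind(px, py, pz)
    coords[seq(2L, by = na, length.out = nd), ] <-    # choline, just outside P
      cbind(px, py, pz + side * 0.25 + stats::rnorm(nd, 0, 0.03))
    coords[seq(3L, by = na, length.out = nd), ] <-    # glycerol/esters, inside
      cbind(px, py, pz - side * 0.22 + stats::rnorm(nd, 0, 0.03))
    iA <- rep(seq_len(nd), each = 18L); jA <- rep(1:18, nd)
    for (dd in 1:3) {
      coords[(iA - 1L) * na + 3L + jA, dd] <- C[cbind(2L * iA - 1L, jA, dd)]
      coords[(iA - 1L) * na + 21L + jA, dd] <- C[cbind(2L * iA, jA, dd)]
    }
    out$dopc <- coords
  }
  if (nc > 0) {
    ox <- sx[is_chol]; oy <- sy[is_chol]
    oz <- plane + .undulation(ox, oy, spec) - side * 0.30 + stats::rnorm(nc, 0, 0.03)
    th <- .rtrunc_angle(nc, .rad(spec$target_chol_tilt_deg), .rad(3), 0, pi / 2)
    ph <- stats::runif(nc, 0, 2 * pi)
    axis <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), -side * cos(th))
    coords <- matrix(0, nc * 9L, 3L)
    coords[seq(1L, by = 9L, length.out = nc), ] <- cbind(ox, oy, oz)
    for (j in 1:8)
      coords[seq(1L, by = 9L, length.out = nc) + j, ] <-
        cbind(ox, oy, oz) + j * .CHOL_STEP * axis
    out$chol <- coords
  }
  out
}

.lipid_atom_table <- function(spec) {
  nd <- spec$n_dopc; nc <- spec$n_chol
  ndl <- nd %/% 2L; ncl <- nc %/% 2L
  blocks <- list()
  mol0 <- 0L
  for (side in c(1, -1)) {
    if (ndl > 0)
      blocks[[length(blocks) + 1L]] <- data.frame(
        mol_id = rep(mol0 + seq_len(ndl), each = .DOPC_NATOMS),
        kind = "DOPC", name = rep(.DOPC_NAMES, ndl), stringsAsFactors = FALSE)
    mol0 <- mol0 + ndl
    if (ncl > 0)
      blocks[[length(blocks) + 1L]] <- data.frame(
        mol_id = rep(mol0 + seq_len(ncl), each = 9L),
        kind = "CHOL", name = rep(.CHOL_NAMES, ncl), stringsAsFactors = FALSE)
    mol0 <- mol0 + ncl
  }
  at <- do.call(rbind, blocks)
  at$atom_id <- seq_len(nrow(at))
  at$resname <- .resname_from_kind(at$kind)
  at$resid <- at$mol_id
  at$role <- "NONE"; at$tail_chain <- NA_integer_; at$tail_pos <- NA_integer_
  at$mass <- NA_real_
  at[, c("atom_id", "mol_id", "kind", "name", "resname", "resid", "role",
         "tail_chain", "tail_pos", "mass")]
}

.build_frame_lipids <- function(spec, kappa, time = 0) {
  up <- .build_leaflet(spec, kappa, +1)
  lo <- .build_leaflet(spec, kappa, -1)
  coords <- rbind(up$dopc, up$chol, lo$dopc, lo$chol)
  atoms <- .lipid_atom_table(spec)
  if (is.null(coords)) stop("empty bilayer: n_dopc + n_chol must be > 0")
  fr <- bilayer_frame(atoms, coords, c(spec$box_xy, spec$box_xy, spec$box_z),
                      time = time)
  assign_roles(fr)
}

#' Build one synthetic bilayer configuration (lipids only)
#'
#' Places DOPC and cholesterol on jittered lattices in two equal leaflets
#' around the phosphate planes at `box_z/2 +- leaflet_z_offset`. Acyl chains
#' are 18-carbon segment walks whose wobble is calibrated (by bisection, see
#' the methods vignette) so the analysed mean `-S_CD` matches
#' `target_mean_scd`; each chain's end-to-end vector follows the tail-tilt
#' distribution exactly. Cholesterol is a hydroxyl oxygen plus a straight
#' 8-carbon ring axis at the Chol tilt. Deterministic under `spec$seed`.
#' Use [place_solvent()] or [generate_trajectory()] to add solvent.
#'
#' @param spec a [generator_spec()].
#' @return a `bilayer_frame` with roles assigned.
#' @export
build_bilayer <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  kappa <- .chain_kappa(spec)
  set.seed(spec$seed)
  .build_frame_lipids(spec, kappa)
}

# ---------------------------------------------------------------------------
# solvent
# ---------------------------------------------------------------------------

# relative (to bulk) water number density along z: 1 outside the phosphate
# planes, decaying geometrically to water_core_penetration at the centre
.water_relative_density <- function(z, spec) {
  zp <- abs(z - spec$box_z / 2) / spec$leaflet_z_offset
  ifelse(zp >= 1, 1, spec$water_core_penetration^(1 - zp))
}

# sequential excluded-volume filter on candidate points (first three columns;
# extra columns such as component flags travel with their row); regenerates
# rejected candidates with `resample(n)` up to `retries` rounds
.excluded_volume_place <- function(cand, box, rmin, resample, retries = 60) {
  cell <- rmin
  nx <- max(1L, floor(box[1] / cell)); ny <- max(1L, floor(box[2] / cell))
  nz <- max(1L, floor(box[3] / cell))
  occ <- new.env(parent = emptyenv())
  n_target <- nrow(cand)
  acc <- matrix(NA_real_, n_target, ncol(cand))
  n_acc <- 0L
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  round_i <- 0L
  while (n_acc < n_target && round_i <= retries) {
    round_i <- round_i + 1L
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, 1:3]
      cx <- floor(p[1] / box[1] * nx); cy <- floor(p[2] / box[2] * ny)
      cz <- floor(p[3] / box[3] * nz)
      kx <- (cx + offs[, 1]) %% nx; ky <- (cy + offs[, 2]) %% ny
      kz <- pmin(pmax(cz + offs[, 3], 0), nz - 1)
      keys <- unique(kx + nx * (ky + ny * kz))
      ok <- TRUE
      for (kk in keys) {
        q <- occ[[as.character(kk)]]
        if (!is.null(q)) {
          d <- .min_image(sweep(q, 2, p), box)
          if (any(rowSums(d * d) < rmin^2)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        n_acc <- n_acc + 1L
        acc[n_acc, ] <- cand[i, ]
        key <- as.character(cx + nx * (cy + ny * cz))
        occ[[key]] <- rbind(occ[[key]], matrix(p, 1))
        if (n_acc == n_target) break
      }
    }
    if (n_acc < n_target) cand <- resample(n_target - n_acc)
  }
  if (n_acc < n_target) {
    # retry cap reached: accept the remaining candidates as-is
    rest <- resample(n_target - n_acc)
    acc[(n_acc + 1L):n_target, ] <- rest
    warning("excluded-volume retry cap reached for ", n_target - n_acc,
            " solvent molecules; placed without the distance check")
  }
  acc
}

# sample water oxygen z-coordinates by rejection from the piecewise profile
.sample_water_z <- function(n, spec) {
  out <- numeric(0)
  while (length(out) < n) {
    z <- stats::runif(2 * n + 100, 0, spec$box_z)
    u <- stats::runif(length(z))
    out <- c(out, z[u < .water_relative_density(z, spec)])
  }
  out[seq_len(n)]
}

# unit dipole vectors with given polar angles about the outward normal of
# the leaflet on each molecule's side (side = +-1)
.dipole_units <- function(theta, side) {
  phi <- stats::runif(length(theta), 0, 2 * pi)
  d <- .sph_unit(theta, phi)
  d[, 3] <- d[, 3] * side
  d
}

.random_units <- function(n) {
  .sph_unit(acos(stats::runif(n, -1, 1)), stats::runif(n, 0, 2 * pi))
}

# a unit vector perpendicular to each row of d, random azimuth
.perp_units <- function(d) {
  r <- .random_units(nrow(d))
  e <- r - d * rowSums(r * d)
  n <- .row_norms(e)
  bad <- n < 1e-6
  if (any(bad)) {
    r2 <- .random_units(sum(bad))
    e[bad, ] <- r2 - d[bad, , drop = FALSE] * rowSums(r2 * d[bad, , drop = FALSE])
    n[bad] <- .row_norms(e[bad, , drop = FALSE])
  }
  e / pmax(n, 1e-300)
}

.solvent_atom_table <- function(n_water, n_dmso, mol0, atom0) {
  blocks <- list()
  if (n_water > 0)
    blocks$w <- data.frame(
      mol_id = mol0 + rep(seq_len(n_water), each = 3L),
      kind = "WATER", name = rep(c("OW", "HW1", "HW2"), n_water),
      stringsAsFactors = FALSE)
  if (n_dmso > 0)
    blocks$d <- data.frame(
      mol_id = mol0 + n_water + rep(seq_len(n_dmso), each = 4L),
      kind = "DMSO", name = rep(c("S", "O", "C1", "C2"), n_dmso),
      stringsAsFactors = FALSE)
  at <- do.call(rbind, blocks)
  at$atom_id <- atom0 + seq_len(nrow(at))
  at$resname <- .resname_from_kind(at$kind)
  at$resid <- at$mol_id
  at$role <- "NONE"; at$tail_chain <- NA_integer_; at$tail_pos <- NA_integer_
  at$mass <- NA_real_
  at[, c("atom_id", "mol_id", "kind", "name", "resname", "resid", "role",
         "tail_chain", "tail_pos", "mass")]
}

.place_solvent_impl <- function(frame, spec) {
  n_dmso <- dmso_count(spec$n_solvent, spec$dmso_solvent_mol_fraction)
  n_water <- spec$n_solvent - n_dmso
  box <- frame$box
  mid <- box[3] / 2
  off <- spec$leaflet_z_offset

  # --- heavy-atom anchor positions (water O, DMSO S) ----------------------
  sample_water <- function(n)
    cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
          .sample_water_z(n, spec))
  # fourth column flags the interfacial mixture component (stays with its row
  # through excluded-volume resampling)
  sample_dmso <- function(n) {
    interf <- stats::runif(n) < spec$dmso_interface_fraction
    side <- sample(c(-1, 1), n, replace = TRUE)
    z <- numeric(n)
    ni <- sum(interf)
    if (ni) z[interf] <- mid + side[interf] *
        (off - 0.15 + stats::rnorm(ni, 0, spec$dmso_interface_width))
    nb <- sum(!interf)
    if (nb) {
      zb <- stats::runif(nb, 0, box[3] - 2 * off)
      z[!interf] <- ifelse(zb < mid - off, zb, zb + 2 * off)
    }
    cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
          z %% box[3], as.numeric(interf))
  }

  if (spec$excluded_volume) {
    wpos <- if (n_water) .excluded_volume_place(sample_water(n_water), box,
                                                0.25, sample_water)
    dfull <- if (n_dmso) .excluded_volume_place(sample_dmso(n_dmso), box,
                                                0.25, sample_dmso)
  } else {
    wpos <- if (n_water) sample_water(n_water)
    dfull <- if (n_dmso) sample_dmso(n_dmso)
  }
  dpos <- NULL
  dmso_interf <- logical(0)
  if (n_dmso) {
    dpos <- dfull[, 1:3, drop = FALSE]
    dmso_interf <- dfull[, 4] > 0.5
  }

  coords <- list()
  # --- water sites: O + 2 H, dipole along the H-H bisector ---------------
  if (n_water) {
    zo <- wpos[, 3]
    dist_up <- abs(zo - (mid + off)); dist_lo <- abs(zo - (mid - off))
    near_if <- pmin(dist_up, dist_lo) < 0.45
    side <- ifelse(zo > mid, 1, -1)
    th <- numeric(n_water)
    ni <- sum(near_if)
    # interfacial waters: H toward the membrane => dipole past 90 deg
    if (ni) th[near_if] <- .rtrunc_angle(ni, .rad(105), .rad(15), 0, pi)
    if (n_water - ni) th[!near_if] <- acos(stats::runif(n_water - ni, -1, 1))
    d <- .dipole_units(th, side)
    e <- .perp_units(d)
    cb <- cos(.rad(52.26)); sb <- sin(.rad(52.26))
    h1 <- wpos + 0.1 * (cb * d + sb * e)
    h2 <- wpos + 0.1 * (cb * d - sb * e)
    wc <- matrix(0, 3L * n_water, 3L)
    wc[seq(1, by = 3, length.out = n_water), ] <- wpos
    wc[seq(2, by = 3, length.out = n_water), ] <- h1
    wc[seq(3, by = 3, length.out = n_water), ] <- h2
    coords$w <- wc
  }
  # --- DMSO sites: S, O (O->S is the dipole), two methyl carbons ---------
  if (n_dmso) {
    zs <- dpos[, 3]
    side <- ifelse(zs > mid, 1, -1)
    th <- numeric(n_dmso)
    oriented <- dmso_interf & !is.na(spec$dmso_dipole_mean_angle)
    no <- sum(oriented)
    if (no) th[oriented] <- .rtrunc_angle(no, .rad(spec$dmso_dipole_mean_angle),
                                          .rad(10), 0, pi)
    if (n_dmso - no) th[!oriented] <- acos(stats::runif(n_dmso - no, -1, 1))
    d <- .dipole_units(th, side)
    e <- .perp_units(d)
    cm <- cos(.rad(100)); sm <- sin(.rad(100))
    dc <- matrix(0, 4L * n_dmso, 3L)
    dc[seq(1, by = 4, length.out = n_dmso), ] <- dpos
    dc[seq(2, by = 4, length.out = n_dmso), ] <- dpos - 0.153 * d
    dc[seq(3, by = 4, length.out = n_dmso), ] <- dpos + 0.18 * (cm * d + sm * e)
    dc[seq(4, by = 4, length.out = n_dmso), ] <- dpos + 0.18 * (cm * d - sm * e)
    coords$d <- dc
  }
  sat <- .solvent_atom_table(n_water, n_dmso, max(c(0L, frame$atoms$mol_id)),
                             max(c(0L, frame$atoms$atom_id)))
  atoms <- rbind(frame$atoms[, names(sat)], sat)
  xyz <- rbind(frame$coords, do.call(rbind, coords))
  assign_roles(bilayer_frame(atoms, xyz, box, time = frame$time))
}

#' Add water and DMSO to a bilayer frame
#'
#' Waters are placed by rejection sampling from a piecewise z-density
#' (bulk-constant outside the phosphate planes, decaying geometrically to
#' `water_core_penetration` at the bilayer centre); DMSO from a mixture of a
#' bulk component and an interfacial Gaussian centred just below the
#' phosphate planes. Interfacial DMSO dipoles (O to S) follow
#' `dmso_dipole_mean_angle` versus the outward leaflet normal; interfacial
#' water dipoles are biased H-toward-membrane; everything else is
#' isotropic. Water is a rigid 3-site model (dipole along the H-H
#' bisector); DMSO is reduced to S, O and two methyl carbons. A 0.25 nm
#' minimum distance between solvent heavy atoms is enforced by rejection
#' unless `spec$excluded_volume` is `FALSE`.
#'
#' @param frame a lipid `bilayer_frame` from [build_bilayer()].
#' @param spec the [generator_spec()] used to build it.
#' @return the frame with solvent appended and roles assigned.
#' @export
place_solvent <- function(frame, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$n_solvent <= 0) stop("place_solvent needs n_solvent > 0")
  set.seed(spec$seed + 1L)
  .place_solvent_impl(frame, spec)
}

#' Generate a synthetic bilayer trajectory
#'
#' Frames are independent draws from the configuration model (plus any
#' planted pores): there is no dynamics, which suffices because every
#' analysis here is an ensemble average. Identical spec and seed give
#' bit-identical output.
#'
#' @param spec a [generator_spec()].
#' @param n_frames number of frames.
#' @param frame_interval nominal frame spacing, ps.
#' @return a `bilayer_trajectory` with roles assigned; the spec is attached
#'   as attribute `generator_spec`, planted-pore ground truth (if any) as
#'   attribute `planted`.
#' @export
generate_trajectory <- function(spec, n_frames = 10, frame_interval = 10) {
  stopifnot(inherits(spec, "generator_spec"), n_frames >= 1)
  kappa <- .chain_kappa(spec)
  set.seed(spec$seed)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fr <- .build_frame_lipids(spec, kappa, time = (f - 1) * frame_interval)
    if (spec$n_solvent > 0) fr <- .place_solvent_impl(fr, spec)
    fr$time <- (f - 1) * frame_interval
    frames[[f]] <- fr
  }
  traj <- as_trajectory(frames, frame_interval = frame_interval)
  attr(traj, "generator_spec") <- spec
  if (!is.null(spec$pore_plan)) traj <- plant_pore(traj, spec$pore_plan)
  traj
}
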