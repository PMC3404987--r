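#' Mass density profile of one component along the bilayer normal
#'
#' Histograms the atomic masses of all atoms belonging to molecules of the
#' component along z, divides by the bin volume (`Lx * Ly * dz` per frame)
#' and averages over frames. Bins uniformly tile `[0, Lz]` of the first
#' frame; mass is conserved exactly: `sum(rho * bin_volume)` equals the
#' component mass in the box.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @param component one of `"WATER"`, `"DOPC"`, `"CHOL"`, `"DMSO"`.
#' @param bin_width nominal bin width, nm (default 0.05; the actual width
#'   divides `Lz` exactly).
#' @return a `density_profile`: data.frame with `z_nm` (bin centres) and
#'   `rho_kg_m3`, plus attributes `component`, `n_frames`, `bin_width`,
#'   `box`. A component absent from the system gives an all-zero profile.
#' @export
mass_density_profile <- function(traj, component, bin_width = 0.05) {
  traj <- .as_traj(traj)
  component <- match.arg(component, .MOL_KINDS)
  if (bin_width <= 0) stop("bin_width must be > 0")
  Lz <- traj$box[1, 3]
  nb <- max(1L, round(Lz / bin_width))
  dz <- Lz / nb
  sel <- which(traj$atoms$kind == component)
  acc <- numeric(nb)
  for (f in seq_len(n_frames(traj))) {
    vol <- traj$box[f, 1] * traj$box[f, 2] * dz
    if (length(sel)) {
      z <- traj$coords[[f]][sel, 3]
      bin <- pmin(pmax(floor(z / dz) + 1L, 1L), nb)
      acc <- acc + .bincount_mass(bin, traj$atoms$mass[sel], nb) / vol
    }
  }
  rho <- acc / n_frames(traj) * .AMU_PER_NM3_TO_KG_M3
  out <- data.frame(z_nm = (seq_len(nb) - 0.5) * dz, rho_kg_m3 = rho)
  structure(out, class = c("density_profile", "data.frame"),
            component = component, n_frames = n_frames(traj),
            bin_width = dz, box = traj$box[1, ],
            empty = length(sel) == 0L)
}

.bincount_mass <- function(bin, mass, nb) {
  v <- numeric(nb)
  agg <- rowsum(mass, bin)
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}

# scaled-coordinate parameters from the phosphate-marker density:
# midplane = mean phosphate z; one scale per leaflet from that leaflet's
# density maximum, so both maxima land exactly at Z' = +-1
.scaling_params <- function(traj, bin_width = 0.05) {
  traj <- .as_traj(traj)
  ip <- which(traj$atoms$role == "PHOSPHATE_MARKER")
  if (length(ip) < 2) stop("scaling error: no phosphate markers to define Z'")
  zall <- unlist(lapply(traj$coords, function(m) m[ip, 3]))
  mid <- mean(zall)
  Lz <- traj$box[1, 3]
  nb <- max(1L, round(Lz / bin_width))
  dz <- Lz / nb
  h <- tabulate(pmin(pmax(floor(zall / dz) + 1L, 1L), nb), nb)
  centers <- (seq_len(nb) - 0.5) * dz
  upper <- centers > mid
  if (!any(h[upper] > 0) || !any(h[!upper] > 0))
    stop("scaling error: phosphate density lacks a maximum on each side of ",
         "the midplane (membrane not intact)")
  z_up <- centers[upper][which.max(h[upper])]
  z_lo <- centers[!upper][which.max(h[!upper])]
  if (z_up - z_lo < 2 * dz)
    stop("scaling error: phosphate maxima not separated (membrane not intact)")
  list(midplane_z = mid, d_upper = z_up - mid, d_lower = mid - z_lo)
}

.scale_z <- function(z, sc) {
  ifelse(z >= sc$midplane_z,
         (z - sc$midplane_z) / sc$d_upper,
         (z - sc$midplane_z) / sc$d_lower)
}

#' Populate the scaled membrane coordinate Z' of a density profile
#'
#' `Z' = (z - z_mid) / |z_P - z_mid|` with each side scaled by its own
#' leaflet's phosphate-density maximum, so the maxima sit exactly at
#' `Z' = +-1` and the bilayer centre at 0. Also records the bulk density
#' `rho0` as the mean over the bulk region `|Z'| > bulk_min`.
#'
#' @param profile a `density_profile`.
#' @param traj the trajectory it came from (for the phosphate reference).
#' @param bulk_min `|Z'|` beyond which the solvent counts as bulk (default 1.5).
#' @return the profile with a `z_scaled` column and attributes `scaling`
#'   and `rho_bulk` (`NA` when the component has no bulk presence).
#' @export
scale_coordinate <- function(profile, traj, bulk_min = 1.5) {
  stopifnot(inherits(profile, "density_profile"))
  sc <- .scaling_params(traj, attr(profile, "bin_width"))
  zs <- .scale_z(profile$z_nm, sc)
  profile$z_scaled <- zs
  bulk <- abs(zs) > bulk_min
  rho0 <- if (any(bulk) && !attr(profile, "empty")) mean(profile$rho_kg_m3[bulk])
          else NA_real_
  if (!is.na(rho0) && rho0 <= 0) rho0 <- NA_real_
  attr(profile, "scaling") <- sc
  attr(profile, "rho_bulk") <- rho0
  attr(profile, "bulk_min") <- bulk_min
  profile
}

#' Potential of mean force by Boltzmann inversion of a density profile
#'
#' `dG(z) = -RT ln(rho(z)/rho0)` in kJ/mol, with `rho0` the bulk density of
#' the component. Bins with zero density are flagged unbounded (`NA`), never
#' imputed. The additive gauge is fixed so the mean over finite bulk bins is
#' exactly zero; the barrier height is the maximum over finite bins.
#'
#' @param profile a `density_profile`, scaled with [scale_coordinate()]
#'   unless `rho0` and `bulk` are supplied directly.
#' @param temperature K (default 310).
#' @param rho0 bulk density override, kg/m3; default from the profile.
#' @param bulk optional logical vector (per bin) marking the bulk region
#'   used for the gauge; default `|z_scaled| > bulk_min` of the profile.
#' @return a `free_energy_profile`: data.frame with the profile's
#'   coordinates, `delta_G_kJ_mol` and `unbounded`; attributes
#'   `barrier_kJ_mol`, `n_unbounded`, `temperature`.
#' @export
pmf_from_density <- function(profile, temperature = 310, rho0 = NULL,
                             bulk = NULL) {
  stopifnot(inherits(profile, "density_profile"), temperature > 0)
  if (is.null(rho0)) rho0 <- attr(profile, "rho_bulk")
  if (is.null(rho0) || is.na(rho0) || rho0 <= 0)
    stop("rho0 undefined: scale the profile first (bulk region |Z'| > ",
         "bulk_min) or pass rho0 explicitly")
  if (is.null(bulk)) {
    if (is.null(profile$z_scaled))
      stop("no bulk region: profile has no z_scaled and no bulk mask given")
    bulk <- abs(profile$z_scaled) > attr(profile, "bulk_min")
  }
  rt <- .RGAS * temperature / 1000
  dg <- ifelse(profile$rho_kg_m3 > 0, -rt * log(profile$rho_kg_m3 / rho0), NA_real_)
  fin_bulk <- bulk & !is.na(dg)
  if (!any(fin_bulk)) stop("no finite bins in the bulk region; cannot fix the gauge")
  dg <- dg - mean(dg[fin_bulk])
  out <- data.frame(z_nm = profile$z_nm,
                    delta_G_kJ_mol = dg, unbounded = is.na(dg))
  if (!is.null(profile$z_scaled)) out$z_scaled <- profile$z_scaled
  structure(out, class = c("free_energy_profile", "data.frame"),
            temperature = temperature, rho0 = rho0,
            barrier_kJ_mol = max(dg, na.rm = TRUE),
            n_unbounded = sum(is.na(dg)))
}

#' Average P-P distance (bilayer thickness proxy)
#'
#' Per frame, the absolute difference between the mean z of upper-leaflet
#' and lower-leaflet phosphate markers (split at the frame's phosphate
#' midplane), averaged over frames.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @return distance in nm.
#' @export
pp_distance <- function(traj) {
  traj <- .as_traj(traj)
  ip <- which(traj$atoms$role == "PHOSPHATE_MARKER")
  if (length(ip) < 2) stop("pp_distance needs phosphate markers")
  per_frame <- vapply(seq_len(n_frames(traj)), function(f) {
    z <- traj$coords[[f]][ip, 3]
    mid <- mean(z)
    up <- z > mid
    if (!any(up) || all(up)) {
      # all phosphates at one z: a zero-thickness (degenerate) membrane
      if (max(z) - min(z) < 1e-9) return(0)
      stop("pp_distance: a leaflet has zero phosphates in frame ", f)
    }
    abs(mean(z[up]) - mean(z[!up]))
  }, numeric(1))
  mean(per_frame)
}

#' Structural summary of a bilayer trajectory
#'
#' One row with the standard observables: mean membrane area (`Lx*Ly`), P-P
#' distance, mean `-S_CD`, mean acyl-tail tilt and mean cholesterol tilt.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @param label condition label for the row.
#' @return data.frame with columns `label`, `area_nm2`, `pp_distance_nm`,
#'   `mean_minus_scd`, `tail_tilt_deg`, `chol_tilt_deg`.
#' @export
membrane_summary <- function(traj, label = "") {
  traj <- .as_traj(traj)
  tl <- tilt_angles(traj)
  data.frame(label = label,
             area_nm2 = mean(traj$box[, 1] * traj$box[, 2]),
             pp_distance_nm = pp_distance(traj),
             mean_minus_scd = scd_profile(traj)$mean_minus_scd,
             tail_tilt_deg = tl$tail_tilt_deg,
             chol_tilt_deg = tl$chol_tilt_deg)
}

#' Signed relative change between two summary values
#'
#' `100 * (b - a) / a` in percent: the worked-example arithmetic relating
#' two conditions of a summary table (e.g. membrane area with and without
#' DMSO).
#'
#' @param a,b scalar values, or one-row summaries from [membrane_summary()].
#' @param field column name when summaries are given.
#' @return signed percent change.
#' @export
relative_change <- function(a, b, field = NULL) {
  if (!is.null(field)) {
    a <- a[[field]]; b <- b[[field]]
  }
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (a == 0) stop("relative change undefined: reference value is 0")
  100 * (b - a) / a
}
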