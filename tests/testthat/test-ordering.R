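# Chain order parameters, tilt angles, lateral correlation, dipole profiles.

test_that("all-trans chains parallel to the normal give -S_CD = 0.5 exactly", {
  set.seed(1)
  tr <- zigzag_chain_frame(rep(0, 20), runif(20, 0, 2 * pi), runif(20, 0, 2 * pi))
  s <- scd_profile(tr)
  expect_true(all(abs(s$profile$minus_scd - 0.5) < 1e-12))
  expect_equal(s$mean_minus_scd, 0.5, tolerance = 1e-12)
})

test_that("chains at the magic angle average to -S_CD = 0 within 1e-3", {
  n <- 720
  theta_m <- acos(1 / sqrt(3)) * 180 / pi       # 54.7356 deg
  set.seed(2)
  # uniform azimuth grids for both the chain axis and the zigzag plane
  tr <- zigzag_chain_frame(rep(theta_m, n),
                           phi = 2 * pi * (seq_len(n) - 0.5) / n,
                           psi = 2 * pi * ((seq_len(n) * 7) %% n) / n)
  s <- scd_profile(tr)
  expect_lt(abs(s$mean_minus_scd), 1e-3)
})

test_that("isotropic chain axes give -S_CD near 0 and values stay in bounds", {
  set.seed(3)
  n <- 4000
  tr <- zigzag_chain_frame(acos(runif(n, -1, 1)) * 180 / pi,
                           runif(n, 0, 2 * pi), runif(n, 0, 2 * pi))
  s <- scd_profile(tr)
  expect_lt(abs(s$mean_minus_scd), 0.01)
  expect_true(all(s$profile$minus_scd >= -1 & s$profile$minus_scd <= 0.5))
})

test_that("short chains are skipped with a warning", {
  atoms <- make_atoms(rep(1:2, c(18, 2)), "DOPC",
                      c(paste0("C", 1:18, "A"), paste0("C", 1:2, "A")),
                      "TAIL_CARBON", mass = 14,
                      tail_chain = 1L, tail_pos = c(1:18, 1:2))
  coords <- cbind(1, 1, c(seq(1, by = 0.125, length.out = 18), 4, 4.2))
  tr <- as_trajectory(list(bilayer_frame(atoms, coords, c(10, 10, 10))))
  expect_warning(s <- scd_profile(tr), "skipped")
  expect_equal(nrow(s$profile), 16)   # interior carbons of the long chain only
})

test_that("tilt angles are exact for planted parallel and in-plane chains", {
  mk <- function(vec) {
    atoms <- rbind(
      make_atoms(1, "DOPC", "P", "PHOSPHATE_MARKER", mass = 31),
      make_atoms(2, "DOPC", "P", "PHOSPHATE_MARKER", mass = 31),
      make_atoms(rep(3, 3), "DOPC", paste0("C", 1:3, "A"), "TAIL_CARBON",
                 mass = 14, tail_chain = 1L, tail_pos = 1:3))
    atoms$atom_id <- seq_len(nrow(atoms))
    start <- c(5, 5, 6.5)
    coords <- rbind(c(1, 1, 7), c(1, 1, 3),
                    start, start + 0.5 * vec, start + 1 * vec)
    as_trajectory(list(bilayer_frame(atoms, coords, c(10, 10, 10))))
  }
  expect_equal(tilt_angles(mk(c(0, 0, -1)))$tail_tilt_deg, 0, tolerance = 1e-9)
  expect_equal(tilt_angles(mk(c(1, 0, 0)))$tail_tilt_deg, 90, tolerance = 1e-9)
  expect_equal(tilt_angles(mk(c(0, 1, 1)))$tail_tilt_deg, 45, tolerance = 1e-9)
})

test_that("tilt and order are invariant under a z-mirrored frame", {
  tr <- lipid_traj()
  trm <- mirror_traj(tr)
  t1 <- tilt_angles(tr); t2 <- tilt_angles(trm)
  expect_equal(t2$tail_tilt_deg, t1$tail_tilt_deg, tolerance = 1e-9)
  expect_equal(t2$chol_tilt_deg, t1$chol_tilt_deg, tolerance = 1e-9)
  expect_equal(scd_profile(trm)$mean_minus_scd, scd_profile(tr)$mean_minus_scd,
               tolerance = 1e-9)
})

test_that("Poisson-placed lipids give C(r) = 1 within 3 sigma beyond the first bin", {
  set.seed(7)
  box <- c(12, 12, 6)
  n <- 150
  frames <- lapply(1:6, function(f)
    point_lipid_frame(cbind(runif(n, 0, 12), runif(n, 0, 12)),
                      cbind(runif(n, 0, 12), runif(n, 0, 12)), box))
  tr <- as_trajectory(frames)
  lc <- lateral_correlation(tr, bin_width = 0.2)
  counts <- attr(lc, "per_leaflet_counts")
  # relative 1-sigma of pooled C(r) from the unordered pair counts
  sigma <- sqrt(2) / sqrt(pmax(colSums(counts), 1))
  dev <- abs(lc$c_value - 1)
  expect_true(all(dev[-1] < 3.5 * sigma[-1] + 0.02))
  expect_lt(abs(mean(lc$c_value[-1]) - 1), 0.01)
})

test_that("a square lattice has its first peak at the lattice constant", {
  a <- 1
  g <- expand.grid(x = seq(0.5, 9.5, by = a), y = seq(0.5, 9.5, by = a))
  fr <- point_lipid_frame(as.matrix(g), as.matrix(g), c(10, 10, 6))
  tr <- as_trajectory(list(fr))
  lc <- lateral_correlation(tr, bin_width = 0.1, r_max = 3)
  expect_true(all(lc$c_value[lc$r_nm < a - 0.05] == 0))
  first_nonzero <- min(which(lc$c_value > 0))
  expect_true(a >= (first_nonzero - 1) * 0.1 && a <= first_nonzero * 0.1)
  # brute-force pair-count oracle: same annulus counts from an O(n^2) loop
  pts <- as.matrix(g)
  cnt <- numeric(30)
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts))) if (i != j) {
    d <- pts[i, ] - pts[j, ]
    d <- d - 10 * round(d / 10)
    r <- sqrt(sum(d^2))
    k <- floor(r / 0.1) + 1
    if (k <= 30) cnt[k] <- cnt[k] + 1
  }
  counts <- attr(lc, "per_leaflet_counts")
  expect_equal(unname(counts[1, ]), cnt)
  expect_equal(unname(counts[2, ]), cnt)
})

test_that("C(r) normalisation integrates back to the counted pairs exactly", {
  set.seed(9)
  n <- 60
  fr <- point_lipid_frame(cbind(runif(n, 0, 8), runif(n, 0, 8)),
                          cbind(runif(n, 0, 8), runif(n, 0, 8)), c(8, 8, 6))
  tr <- as_trajectory(list(fr))
  lc <- lateral_correlation(tr, bin_width = 0.25)
  counts <- attr(lc, "per_leaflet_counts")
  norm <- attr(lc, "per_leaflet_norm")
  area_k <- attr(lc, "annulus_area")
  for (s in 1:2) {
    c_s <- counts[s, ] / area_k / norm[s]
    # sum(C * annulus_area * rho_ref * n_ref) == ordered pairs counted
    expect_equal(sum(c_s * area_k) * norm[s], sum(counts[s, ]), tolerance = 1e-12)
  }
})

test_that("degenerate lateral inputs are rejected", {
  fr <- point_lipid_frame(matrix(c(1, 1), 1), matrix(c(2, 2), 1), c(8, 8, 6))
  expect_error(lateral_correlation(as_trajectory(list(fr))), "at least 2")
  tr <- solvated_traj()
  expect_error(lateral_correlation(tr, r_max = 3), "exceeds")
})

test_that("lateral correlation runs on generator bilayers and tends to 1", {
  tr <- lipid_traj()
  lc <- lateral_correlation(tr, bin_width = 0.2)
  far <- lc$r_nm > 1.5
  expect_equal(mean(lc$c_value[far]), 1, tolerance = 0.1)
})

test_that("dipoles planted along the outward normals read 0 degrees", {
  n <- 50
  set.seed(4)
  s <- cbind(runif(n, 0, 5), runif(n, 0, 5), runif(n, 0, 5))
  d <- cbind(0, 0, ifelse(s[, 3] >= 2.5, 1, -1))     # along outward normal
  atoms <- make_atoms(rep(seq_len(n), each = 2), "DMSO",
                      rep(c("S", "O"), n), rep(c("DMSO_S", "DMSO_O"), n),
                      mass = 32)
  atoms$atom_id <- seq_len(2 * n)
  xyz <- matrix(0, 2 * n, 3)
  xyz[seq(1, by = 2, length.out = n), ] <- s
  xyz[seq(2, by = 2, length.out = n), ] <- s - 0.153 * d
  tr <- as_trajectory(list(bilayer_frame(atoms, xyz, c(5, 5, 5))))
  op <- dipole_orientation_profile(tr, "DMSO", bin_width = 0.5)
  expect_true(all(abs(op$mean_angle_deg[op$n_samples > 0]) < 1e-6))
})

test_that("isotropic dipoles average to 90 degrees in every populated bin", {
  tr <- random_dmso_frame(500000, box = c(6, 6, 6), seed = 5, sites = "dipole")
  op <- dipole_orientation_profile(tr, "DMSO", bin_width = 1.5)
  pop <- op$n_samples > 0
  expect_true(all(op$n_samples[pop] >= 1e5))
  expect_true(all(abs(op$mean_angle_deg[pop] - 90) < 0.5))
  overall <- weighted.mean(op$mean_angle_deg[pop], op$n_samples[pop])
  expect_equal(overall, 90, tolerance = 0.2 / 90)
})

test_that("the orientation profile of a z-mirrored frame is the Z'-mirrored profile", {
  tr <- solvated_traj()
  op <- dipole_orientation_profile(tr, "DMSO", bin_width = 0.25)
  opm <- dipole_orientation_profile(mirror_traj(tr), "DMSO", bin_width = 0.25)
  # align the two symmetric bin grids around 0 (rounded against float drift)
  op$z_scaled <- round(-op$z_scaled, 9)
  opm$z_scaled <- round(opm$z_scaled, 9)
  m2 <- merge(op, opm, by = "z_scaled")
  both <- m2[m2$n_samples.x > 0 & m2$n_samples.y > 0, ]
  expect_gt(nrow(both), 5)
  expect_equal(both$mean_angle_deg.y, both$mean_angle_deg.x, tolerance = 1e-6)
})

test_that("water dipole profiles use the O-H bisector and need both hydrogens", {
  tr <- solvated_traj()
  op <- dipole_orientation_profile(tr, "WATER", bin_width = 0.25)
  expect_true(any(op$n_samples > 0))
  bulk <- abs(op$z_scaled) > 1.6 & op$n_samples > 50
  expect_equal(weighted.mean(op$mean_angle_deg[bulk], op$n_samples[bulk]),
               90, tolerance = 5 / 90)
})
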