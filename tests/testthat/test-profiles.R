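# Density profiles, scaled coordinate, Boltzmann-inversion PMF, summaries.

RT310 <- 8.314 * 310 / 1000

test_that("uniform solvent gives a flat profile at the closed-form density", {
  n <- 20000
  box <- c(4, 4, 5)
  tr <- sample_solvent_frames(n, 5, box, seed = 8)
  dp <- mass_density_profile(tr, "WATER", bin_width = 0.1)
  expected <- n * 18.015 / prod(box) * 1.66053907   # N * m_w / V in kg/m3
  # every bin within ~3 sigma of the Poisson bin error (5 frames pooled)
  sigma <- expected / sqrt(n * 5 * attr(dp, "bin_width") / box[3])
  expect_true(all(abs(dp$rho_kg_m3 - expected) < 3.5 * sigma))
  expect_equal(mean(dp$rho_kg_m3), expected, tolerance = 0.01)
})

test_that("an absent component yields an all-zero profile", {
  tr <- sample_solvent_frames(100, 1, c(3, 3, 3), seed = 1)
  dp <- mass_density_profile(tr, "CHOL")
  expect_true(all(dp$rho_kg_m3 == 0))
  expect_true(attr(dp, "empty"))
})

test_that("mass is conserved exactly: sum(rho * bin_volume) = component mass", {
  tr <- solvated_traj()
  for (comp in c("WATER", "DOPC", "CHOL", "DMSO")) {
    dp <- mass_density_profile(tr, comp, bin_width = 0.07)
    binvol <- tr$box[1, 1] * tr$box[1, 2] * attr(dp, "bin_width")
    total <- sum(dp$rho_kg_m3) * binvol / 1.66053907
    sel <- tr$atoms$kind == comp
    expect_equal(total, sum(tr$atoms$mass[sel]), tolerance = 1e-10)
  }
})

test_that("halving the bin width moves bulk density less than the Poisson bound", {
  n <- 20000
  tr <- sample_solvent_frames(n, 5, c(4, 4, 5), seed = 8)
  r1 <- mass_density_profile(tr, "WATER", bin_width = 0.1)
  r2 <- mass_density_profile(tr, "WATER", bin_width = 0.05)
  m1 <- mean(r1$rho_kg_m3); m2 <- mean(r2$rho_kg_m3)
  poisson_bound <- m1 / sqrt(n * 5)
  expect_lt(abs(m1 - m2), poisson_bound)
})

test_that("mirrored frames give exactly mirrored profiles", {
  tr <- solvated_traj()
  dp <- mass_density_profile(tr, "WATER")
  dpm <- mass_density_profile(mirror_traj(tr), "WATER")
  expect_equal(dpm$rho_kg_m3, rev(dp$rho_kg_m3), tolerance = 1e-12)
})

test_that("the generator DOPC profile peaks near Z' = +-1 with a central minimum", {
  tr <- solvated_traj()
  dp <- scale_coordinate(mass_density_profile(tr, "DOPC", bin_width = 0.1), tr)
  up <- dp[dp$z_scaled > 0 & dp$z_scaled < 2, ]
  lo <- dp[dp$z_scaled < 0 & dp$z_scaled > -2, ]
  expect_equal(up$z_scaled[which.max(up$rho_kg_m3)], 1, tolerance = 0.3)
  expect_equal(lo$z_scaled[which.max(lo$rho_kg_m3)], -1, tolerance = 0.3)
  centre <- mean(dp$rho_kg_m3[abs(dp$z_scaled) < 0.2])
  expect_lt(centre, 0.5 * max(up$rho_kg_m3))
})

test_that("the scaled coordinate is a leaflet-wise linear map with Z'=+-1 at the peaks", {
  # phosphate planes at z_mid +- 1.97 (off bin edges): symmetric case
  atoms <- make_atoms(1:40, "DOPC", "P", "PHOSPHATE_MARKER", mass = 31)
  z <- rep(c(2.53, 6.47), each = 20)    # mid = 4.5
  fr <- bilayer_frame(atoms, cbind(runif(40, 0, 5), runif(40, 0, 5), z),
                      c(5, 5, 9))
  tr <- as_trajectory(list(fr))
  dp <- mass_density_profile(tr, "DOPC", bin_width = 0.1)
  dp <- scale_coordinate(dp, tr)
  sc <- attr(dp, "scaling")
  expect_equal(sc$midplane_z, 4.5)
  expect_equal(sc$d_upper, 1.97, tolerance = 0.06 / 1.97)
  # a point 0.985 nm above the midplane maps to Z' = +0.5
  expect_equal(dmsopore:::.scale_z(4.5 + 1.97 / 2, sc), 0.5, tolerance = 0.03)
  expect_equal(dmsopore:::.scale_z(4.5, sc), 0)
  # the peaks themselves map to exactly +-1 up to bin discretisation
  expect_equal(dmsopore:::.scale_z(6.47, sc), 1, tolerance = 0.03)
  # asymmetric case: 30 lower phosphates at 2.03, 10 upper at 5.57, so the
  # midplane (mean) is off-centre and each side gets its own scale
  atoms2 <- make_atoms(1:40, "DOPC", "P", "PHOSPHATE_MARKER", mass = 31)
  za <- c(rep(2.03, 30), rep(5.57, 10))   # mid = mean = 2.915
  fr2 <- bilayer_frame(atoms2, cbind(runif(40, 0, 5), runif(40, 0, 5), za),
                       c(5, 5, 9))
  tr2 <- as_trajectory(list(fr2))
  dp2 <- scale_coordinate(mass_density_profile(tr2, "DOPC", bin_width = 0.1), tr2)
  sc2 <- attr(dp2, "scaling")
  expect_equal(dmsopore:::.scale_z(5.57, sc2), 1, tolerance = 0.04)
  expect_equal(dmsopore:::.scale_z(2.03, sc2), -1, tolerance = 0.04)
})

test_that("scaling fails on a membrane without two separated phosphate maxima", {
  atoms <- make_atoms(1:20, "DOPC", "P", "PHOSPHATE_MARKER", mass = 31)
  fr <- bilayer_frame(atoms, cbind(runif(20, 0, 5), runif(20, 0, 5),
                                   rep(4.5, 20)), c(5, 5, 9))
  tr <- as_trajectory(list(fr))
  dp <- mass_density_profile(tr, "DOPC")
  expect_error(scale_coordinate(dp, tr), "not intact|maximum")
})

test_that("PMF of a constant-density profile is identically zero", {
  dp <- structure(data.frame(z_nm = seq(0.05, 4.95, by = 0.1),
                             rho_kg_m3 = rep(500, 50)),
                  class = c("density_profile", "data.frame"),
                  bin_width = 0.1, empty = FALSE)
  fe <- pmf_from_density(dp, 310, rho0 = 500, bulk = rep(TRUE, 50))
  expect_true(all(fe$delta_G_kJ_mol == 0))
  expect_equal(attr(fe, "barrier_kJ_mol"), 0)
})

test_that("a density ratio of exp(-2) costs exactly 2RT at 310 K", {
  rho <- c(rep(1000, 20), rep(1000 * exp(-2), 10), rep(1000, 20))
  dp <- structure(data.frame(z_nm = seq(0.05, by = 0.1, length.out = 50),
                             rho_kg_m3 = rho),
                  class = c("density_profile", "data.frame"),
                  bin_width = 0.1, empty = FALSE)
  bulk <- rho == 1000
  fe <- pmf_from_density(dp, 310, rho0 = 1000, bulk = bulk)
  expect_equal(max(fe$delta_G_kJ_mol), 2 * RT310, tolerance = 1e-12)
  expect_equal(2 * RT310, 5.15, tolerance = 0.01 / 5.15)
  # gauge: mean over bulk bins is zero by construction
  expect_equal(mean(fe$delta_G_kJ_mol[bulk]), 0, tolerance = 1e-12)
})

test_that("zero-density bins are flagged unbounded, never imputed", {
  rho <- c(rep(800, 20), rep(0, 5), rep(800, 25))
  dp <- structure(data.frame(z_nm = seq(0.05, by = 0.1, length.out = 50),
                             rho_kg_m3 = rho),
                  class = c("density_profile", "data.frame"),
                  bin_width = 0.1, empty = FALSE)
  fe <- pmf_from_density(dp, 310, rho0 = 800, bulk = rho > 0)
  expect_equal(attr(fe, "n_unbounded"), 5)
  expect_true(all(is.na(fe$delta_G_kJ_mol[rho == 0])))
  expect_true(all(fe$unbounded == (rho == 0)))
})

test_that("a known Gaussian barrier is recovered by Boltzmann inversion", {
  U <- function(z) 6 * exp(-(z - 3)^2 / (2 * 0.5^2))
  tr <- sample_solvent_frames(40000, 8, c(5, 5, 6),
                              z_density = function(z) exp(-U(z) / RT310),
                              seed = 13)
  dp <- mass_density_profile(tr, "WATER")
  bulk <- dp$z_nm < 1 | dp$z_nm > 5
  fe <- pmf_from_density(dp, 310, rho0 = mean(dp$rho_kg_m3[bulk]), bulk = bulk)
  fin <- !fe$unbounded
  uref <- U(fe$z_nm) - mean(U(fe$z_nm)[bulk])
  expect_lt(max(abs(fe$delta_G_kJ_mol[fin] - uref[fin])), 0.5)
  expect_equal(attr(fe, "barrier_kJ_mol"), 6, tolerance = 0.5 / 6)
})

test_that("P-P distance matches planted phosphate planes", {
  atoms <- make_atoms(1:20, "DOPC", "P", "PHOSPHATE_MARKER", mass = 31)
  mk <- function(offset) {
    z <- rep(c(4.5 - offset, 4.5 + offset), each = 10)
    as_trajectory(list(bilayer_frame(atoms, cbind(runif(20, 0, 5),
                                                  runif(20, 0, 5), z),
                                     c(5, 5, 9))))
  }
  expect_equal(pp_distance(mk(2.085)), 4.17, tolerance = 1e-12)
  expect_equal(pp_distance(mk(1e-9)), 0, tolerance = 1e-6)
  expect_equal(pp_distance(mk(0)), 0)   # both leaflets at the same z
  tr <- lipid_traj()
  expect_equal(pp_distance(tr), 2 * 2.085, tolerance = 0.02 / 4.17)
})

test_that("relative changes reproduce the summary-table arithmetic", {
  expect_equal(relative_change(44.5, 58.1), 30.6, tolerance = 0.02)
  expect_equal(relative_change(4.17, 3.60), -13.7, tolerance = 0.01)
  expect_equal(relative_change(7, 7), 0)
  expect_error(relative_change(0, 5), "undefined")
  a <- data.frame(area_nm2 = 44.5); b <- data.frame(area_nm2 = 58.1)
  expect_equal(relative_change(a, b, "area_nm2"), 30.56, tolerance = 0.001)
})

test_that("membrane_summary collects the five structural observables", {
  tr <- lipid_traj()
  s <- membrane_summary(tr, label = "0 mol% DMSO")
  expect_named(s, c("label", "area_nm2", "pp_distance_nm", "mean_minus_scd",
                    "tail_tilt_deg", "chol_tilt_deg"))
  expect_equal(s$area_nm2, 4.75^2)
  expect_true(all(is.finite(unlist(s[, -1]))))
})
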