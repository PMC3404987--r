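# Internal vector/geometry helpers shared by the generator and the analyses.
# All coordinates are in nm; the bilayer normal is the z axis throughout.

# gas constant, J mol^-1 K^-1
.RGAS <- 8.314

# standard atomic masses (amu); united-atom carbons carry their implicit H mass
.MASS <- c(H = 1.008, C = 12.011, O = 15.999, P = 30.974, S = 32.06)
.MASS_CH2 <- .MASS[["C"]] + 2 * .MASS[["H"]]
.MASS_CH3 <- .MASS[["C"]] + 3 * .MASS[["H"]]
.MASS_CH  <- .MASS[["C"]] + .MASS[["H"]]
.MASS_OH  <- .MASS[["O"]] + .MASS[["H"]]
.MASS_H2O <- .MASS[["O"]] + 2 * .MASS[["H"]]

# amu nm^-3 -> kg m^-3
.AMU_PER_NM3_TO_KG_M3 <- 1.66053907

.row_norms <- function(m) sqrt(rowSums(m * m))

.unit_rows <- function(m) m / pmax(.row_norms(m), 1e-300)

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# minimum-image difference; periodic in the axes given (xy for pairwise
# in-plane operations, xyz for intramolecular vectors of wrapped molecules)
.min_image <- function(d, box, axes = c(1L, 2L)) {
  d <- as.matrix(d)
  for (ax in axes) {
    L <- box[ax]
    d[, ax] <- d[, ax] - L * round(d[, ax] / L)
  }
  d
}

.wrap_positions <- function(x, box) {
  for (ax in 1:3) x[, ax] <- x[, ax] %% box[ax]
  x
}

# rotation (Rodrigues) taking unit vector `from` to unit vector `to`,
# applied row-wise to v; all three are n x 3 with paired rows
.rotate_align <- function(v, from, to) {
  cosang <- rowSums(from * to)
  k <- .cross_rows(from, to)
  s <- .row_norms(k)
  ok <- s > 1e-12
  out <- v
  if (any(ok)) {
    kh <- k[ok, , drop = FALSE] / s[ok]
    vv <- v[ok, , drop = FALSE]
    c1 <- cosang[ok]
    s1 <- s[ok]
    kv <- rowSums(kh * vv)
    out[ok, ] <- vv * c1 + .cross_rows(kh, vv) * s1 + kh * (kv * (1 - c1))
  }
  # anti-parallel rows: rotate 180 degrees about any axis perpendicular to `from`
  flip <- !ok & cosang < 0
  if (any(flip)) {
    f <- from[flip, , drop = FALSE]
    e <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
    par <- abs(f[, 1]) > 0.9
    e[par, ] <- matrix(rep(c(0, 1, 0), each = sum(par)), ncol = 3)
    ax <- .unit_rows(.cross_rows(f, e))
    vv <- v[flip, , drop = FALSE]
    out[flip, ] <- 2 * ax * rowSums(ax * vv) - vv
  }
  out
}

# unit vectors with polar angle theta (radians, vs +z) and azimuth phi
.sph_unit <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# draw polar angles (radians) from a normal truncated to [lo, hi], vectorised
.rtrunc_angle <- function(n, mean, sd, lo = 0, hi = pi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    keep <- x >= lo & x <= hi
    out[todo[keep]] <- x[keep]
    todo <- todo[!keep]
  }
  out
}

# von Mises-Fisher polar cosines about +z, exact inverse-CDF sampling
.rvmf_cos <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -1, 1))
  u <- stats::runif(n)
  1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180
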