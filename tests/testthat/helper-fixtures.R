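# Shared fixtures (built once per session) and independent oracles.

.fixture_env <- new.env()

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

# lipid-only bilayer at the reference targets (order/tilt analyses)
lipid_traj <- function() fixture("lipid_traj", function()
  generate_trajectory(generator_spec(n_dopc = 64, chol_mol_fraction = 0.2,
                                     n_solvent = 0, box_xy = 4.75, seed = 101),
                      n_frames = 10))

# solvated bilayer with 15 mol% DMSO (profiles, dipoles)
solvated_traj <- function() fixture("solvated_traj", function()
  generate_trajectory(generator_spec(n_dopc = 32, chol_mol_fraction = 0.2,
                                     n_solvent = 1200,
                                     dmso_solvent_mol_fraction = 0.15,
                                     box_xy = 3.4, seed = 202),
                      n_frames = 6))

# --- hand-built frames ------------------------------------------------------

# atoms table scaffold with roles set directly (bypasses assign_roles)
make_atoms <- function(mol_id, kind, name, role, mass = 1,
                       tail_chain = NA_integer_, tail_pos = NA_integer_) {
  n <- length(mol_id)
  data.frame(atom_id = seq_len(n), mol_id = mol_id, kind = rep_len(kind, n),
             name = rep_len(name, n), resname = rep_len(kind, n),
             resid = mol_id, role = rep_len(role, n),
             tail_chain = rep_len(tail_chain, n),
             tail_pos = rep_len(tail_pos, n), mass = rep_len(mass, n),
             stringsAsFactors = FALSE)
}

# planar zigzag 18-carbon chains: axis at polar angle theta/azimuth phi,
# zigzag plane azimuth psi about the axis; returns a one-frame trajectory
# of DOPC tail carbons
zigzag_chain_frame <- function(theta_deg, phi, psi, box = c(50, 50, 50),
                               bond = 0.125, width = 0.05) {
  nch <- length(theta_deg)
  th <- theta_deg * pi / 180
  a <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  # e: unit vector perpendicular to a with azimuth psi about it
  ref <- cbind(-sin(phi), cos(phi), 0)            # perpendicular to a
  ref2 <- cbind(a[, 2] * ref[, 3] - a[, 3] * ref[, 2],
                a[, 3] * ref[, 1] - a[, 1] * ref[, 3],
                a[, 1] * ref[, 2] - a[, 2] * ref[, 1])
  e <- ref * cos(psi) + ref2 * sin(psi)
  coords <- matrix(0, nch * 18, 3)
  anchors <- cbind(runif(nch, 10, 40), runif(nch, 10, 40), 25)
  for (j in 1:18)
    coords[(seq_len(nch) - 1) * 18 + j, ] <-
      anchors + (j - 1) * bond * a + ((-1)^j) * (width / 2) * e
  atoms <- make_atoms(rep(seq_len(nch), each = 18), "DOPC",
                      rep(paste0("C", 1:18, "A"), nch), "TAIL_CARBON",
                      mass = 14, tail_chain = 1L,
                      tail_pos = rep(1:18, nch))
  as_trajectory(list(bilayer_frame(atoms, coords, box)))
}

# single-site waters at given positions, with phosphate planes at z_lo/z_hi
# defining the membrane slab
slab_frame <- function(water_xyz, box = c(5, 5, 8), z_lo = 2, z_hi = 6,
                       n_p = 8) {
  nw <- nrow(water_xyz)
  pxy <- cbind(rep(seq(0.5, box[1] - 0.5, length.out = n_p), 2),
               rep(c(1, box[2] - 1), each = n_p),
               rep(c(z_lo, z_hi), each = 2 * n_p)[1:(2 * n_p)])
  pxy <- rbind(cbind(pxy[1:n_p, 1], pxy[1:n_p, 2], z_lo),
               cbind(pxy[1:n_p, 1], pxy[1:n_p, 2], z_hi))
  atoms <- rbind(
    make_atoms(1:(2 * n_p), "DOPC", "P", "PHOSPHATE_MARKER", mass = 31),
    make_atoms(2 * n_p + seq_len(nw), "WATER", "OW", "WATER_O", mass = 18))
  atoms$atom_id <- seq_len(nrow(atoms))
  bilayer_frame(atoms, rbind(pxy, water_xyz), box)
}

# DOPC point "molecules" (single marker atom) split over two leaflets,
# for the in-plane pair-correlation tests
point_lipid_frame <- function(xy_upper, xy_lower, box) {
  n1 <- nrow(xy_upper); n2 <- nrow(xy_lower)
  atoms <- make_atoms(seq_len(n1 + n2), "DOPC", "P", "PHOSPHATE_MARKER",
                      mass = 31)
  coords <- rbind(cbind(xy_upper, box[3] * 0.75),
                  cbind(xy_lower, box[3] * 0.25))
  bilayer_frame(atoms, coords, box)
}

# --- independent oracles ----------------------------------------------------

# brute-force single-linkage partition: O(n^2) distances (in-plane minimum
# image, plain z) then breadth-first search over the contact graph
bf_partition <- function(pos, box, cutoff) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  adj <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d <- pos[i, ] - pos[j, ]
    d[1] <- d[1] - box[1] * round(d[1] / box[1])
    d[2] <- d[2] - box[2] * round(d[2] / box[2])
    if (sum(d * d) <= cutoff^2) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lab <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (lab[v] > 0) next
      lab[v] <- comp
      queue <- c(queue, adj[[v]][lab[adj[[v]]] == 0])
    }
  }
  lab
}

# partitions as canonical set-of-sets for equality checks
partition_sets <- function(ids, lab) {
  s <- lapply(split(ids, lab), sort)
  unname(s[order(vapply(s, `[`, ids[0][1] * 0, 1))])
}

# trajectory mirrored in z (z -> Lz - z)
mirror_traj <- function(traj) {
  for (f in seq_len(n_frames(traj))) {
    Lz <- traj$box[f, 3]
    traj$coords[[f]][, 3] <- (Lz - traj$coords[[f]][, 3]) %% Lz
  }
  traj
}
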