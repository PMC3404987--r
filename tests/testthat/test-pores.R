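# Water-defect detection, tracking, classification and regime labels.

# small, fast bilayer spec for pore work; n_frames = 10 equals the
# stability threshold so regimes are defined
pore_spec <- function(seed, plan = NULL, n_dopc = 16, n_solvent = 250)
  generator_spec(n_dopc = n_dopc, chol_mol_fraction = 0.2, n_solvent = n_solvent,
                 box_xy = 2.5, seed = seed, pore_plan = plan)

test_that("an empty slab yields no defects; far-apart waters split into defects", {
  fr <- slab_frame(matrix(numeric(0), 0, 3))
  d <- detect_defects(fr)
  expect_length(d, 0)
  expect_true(attr(d, "bilayer_intact"))
  # two waters 2 nm apart in the slab: two non-spanning defects
  fr2 <- slab_frame(rbind(c(1, 1, 4), c(3, 1, 4)))
  d2 <- detect_defects(fr2)
  expect_length(d2, 2)
  expect_false(any(vapply(d2, `[[`, logical(1), "spans_slab")))
  # the same two waters within the cutoff: one defect
  fr3 <- slab_frame(rbind(c(1, 1, 4), c(1.3, 1, 4)))
  expect_length(detect_defects(fr3), 1)
})

test_that("a hand-planted single-file column is one spanning defect", {
  zs <- seq(2.05, 5.95, by = 0.2)
  col <- cbind(2.5, 2.5, zs)
  extra <- rbind(c(0.5, 0.5, 4), c(4.5, 4.5, 3.2))
  fr <- slab_frame(rbind(col, extra))
  d <- detect_defects(fr)
  spans <- vapply(d, `[[`, logical(1), "spans_slab")
  expect_equal(sum(spans), 1)
  expect_length(d, 3)
  sp <- d[[which(spans)]]
  # members are the column waters inside the shrunken slab [2.3, 5.7]
  expect_equal(length(sp$member_water_ids), sum(zs >= 2.3 & zs <= 5.7))
  expect_equal(sp$axis_xy, c(2.5, 2.5), tolerance = 1e-6)
  expect_lt(sp$max_radius, 0.01)
})

test_that("clustering uses the in-plane minimum image across the boundary", {
  # two waters straddling the periodic x boundary, 0.2 nm apart
  fr <- slab_frame(rbind(c(0.05, 2, 4), c(4.95, 2, 4)), box = c(5, 5, 8))
  expect_length(detect_defects(fr), 1)
})

test_that("detector partition equals the brute-force single-linkage oracle", {
  set.seed(42)
  for (rep in 1:8) {
    nw <- sample(30:120, 1)
    pos <- cbind(runif(nw, 0, 5), runif(nw, 0, 5), runif(nw, 2.4, 5.6))
    fr <- slab_frame(pos)
    d <- detect_defects(fr)
    atoms <- fr$atoms
    io <- which(atoms$role == "WATER_O")
    z <- fr$coords[io, 3]
    ins <- z >= 2.3 & z <= 5.7          # slab [2+0.3, 6-0.3]
    ids <- atoms$mol_id[io][ins]
    lab <- bf_partition(fr$coords[io, , drop = FALSE][ins, , drop = FALSE],
                        fr$box, 0.35)
    got <- lapply(d, `[[`, "member_water_ids")
    expect_setequal_partitions <- function(a, b) {
      expect_equal(partition_sets(unlist(a), rep(seq_along(a),
                                                 lengths(a))),
                   partition_sets(unlist(b), rep(seq_along(b), lengths(b))))
    }
    want <- split(ids, lab)
    expect_equal(length(got), length(want))
    expect_setequal_partitions(got, unname(want))
  }
})

test_that("relabelling water ids never changes defect count or sizes", {
  set.seed(5)
  nw <- 80
  pos <- cbind(runif(nw, 0, 5), runif(nw, 0, 5), runif(nw, 2.4, 5.6))
  fr <- slab_frame(pos)
  d1 <- detect_defects(fr)
  # permute the water molecules (atoms and coordinates together)
  iw <- which(fr$atoms$kind == "WATER")
  perm <- sample(iw)
  fr2 <- fr
  fr2$atoms[iw, ] <- fr$atoms[perm, ]
  fr2$atoms$mol_id[iw] <- fr$atoms$mol_id[iw]    # fresh ids in new order
  fr2$atoms$atom_id <- seq_len(nrow(fr2$atoms))
  fr2$coords[iw, ] <- fr$coords[perm, ]
  d2 <- detect_defects(fr2)
  expect_equal(length(d2), length(d1))
  expect_equal(sort(lengths(lapply(d2, `[[`, "member_water_ids"))),
               sort(lengths(lapply(d1, `[[`, "member_water_ids"))))
})

test_that("raising the O-O cutoff only merges clusters, never splits them", {
  set.seed(6)
  nw <- 100
  pos <- cbind(runif(nw, 0, 5), runif(nw, 0, 5), runif(nw, 2.4, 5.6))
  fr <- slab_frame(pos)
  d_small <- detect_defects(fr, oo_cutoff = 0.35)
  d_large <- detect_defects(fr, oo_cutoff = 0.55)
  expect_lte(length(d_large), length(d_small))
  # every small-cutoff cluster is contained in one large-cutoff cluster
  for (ds in d_small) {
    hosts <- vapply(d_large, function(dl)
      all(ds$member_water_ids %in% dl$member_water_ids), logical(1))
    expect_equal(sum(hosts), 1)
  }
})

test_that("lining headgroups are counted within the lining radius", {
  zs <- seq(2.05, 5.95, by = 0.2)
  fr <- slab_frame(cbind(2.5, 2.5, zs))
  # relocate six phosphates (three per plane, so the plane means stay put)
  # next to the column, near the slab centre
  ip <- which(fr$atoms$role == "PHOSPHATE_MARKER")[c(1:3, 9:11)]
  fr$coords[ip, ] <- cbind(2.5 + c(0.3, -0.3, 0, 0, 0.2, -0.2),
                           2.5 + c(0, 0, 0.3, -0.3, 0.2, -0.2),
                           seq(3.6, 4.4, length.out = 6))
  d <- detect_defects(fr)
  sp <- d[[which(vapply(d, `[[`, logical(1), "spans_slab"))]]
  expect_equal(sp$lining_headgroup_count, 6L)
})

test_that("planted columns are found in exactly their frames and tracked once", {
  spec <- pore_spec(301)
  tr <- generate_trajectory(spec, n_frames = 10)
  tr <- plant_pore(tr, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.15,
                                 frames_present = 5L))
  ev <- track_defects(tr)
  expect_equal(attr(ev, "per_frame_spanning"), c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  expect_length(ev, 1)
  expect_equal(ev[[1]]$first_frame, 5)
  expect_equal(ev[[1]]$lifetime_ps, tr$frame_interval)
  # 7-frame column with shared membership is a single event
  tr2 <- generate_trajectory(pore_spec(302), n_frames = 10)
  tr2 <- plant_pore(tr2, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.15,
                                   frames_present = 3:9))
  ev2 <- track_defects(tr2)
  expect_length(ev2, 1)
  expect_equal(c(ev2[[1]]$first_frame, ev2[[1]]$last_frame), c(3, 9))
  expect_equal(ev2[[1]]$lifetime_ps, 7 * tr2$frame_interval)
})

test_that("two disjoint simultaneous columns give two events", {
  tr <- generate_trajectory(pore_spec(303), n_frames = 10)
  tr <- plant_pore(tr, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.12,
                                 frames_present = 4:5,
                                 axis_xy = c(0.7, 0.7)))
  tr <- plant_pore(tr, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.12,
                                 frames_present = 4:5,
                                 axis_xy = c(1.9, 1.9)))
  ev <- track_defects(tr)
  expect_length(ev, 2)
  expect_equal(attr(ev, "per_frame_spanning")[4:5], c(2, 2))
})

test_that("pore classes follow the lifetime and lining criteria", {
  # persistent hydrophilic pore: stable lifetime + lining met
  tr <- generate_trajectory(pore_spec(304, n_dopc = 24), n_frames = 10)
  tr <- plant_pore(tr, pore_plan("HYDROPHILIC_PORE", radius = 0.15,
                                 n_lining_headgroups = 8, frames_present = 1:10))
  ev <- track_defects(tr)
  expect_length(ev, 1)
  expect_equal(classify_pore(ev[[1]], n_frames_total = 10), "STABLE_HYDROPHILIC")
  # one-frame bare column: transient hydrophobic
  tr2 <- generate_trajectory(pore_spec(305), n_frames = 10)
  tr2 <- plant_pore(tr2, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.15,
                                   frames_present = 4L))
  ev2 <- track_defects(tr2)
  expect_equal(classify_pore(ev2[[1]], n_frames_total = 10),
               "TRANSIENT_HYDROPHOBIC")
  # long-lived bare column: flagged INDETERMINATE
  tr3 <- generate_trajectory(pore_spec(306), n_frames = 12)
  tr3 <- plant_pore(tr3, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.15,
                                   frames_present = 1:11))
  ev3 <- track_defects(tr3)
  expect_equal(classify_pore(ev3[[1]], n_frames_total = 12), "INDETERMINATE")
})

test_that("trajectories shorter than the stability threshold are UNDETERMINED", {
  tr <- generate_trajectory(pore_spec(307), n_frames = 4)
  rr <- classify_regime(tr)
  expect_equal(rr$regime, "UNDETERMINED")
  expect_match(rr$evidence, "shorter")
})

test_that("planted-pore recall and precision are 1.0 over a 20-trajectory suite", {
  plans <- rep(c("none", "stable", "multi"), length.out = 20)
  got_regime <- character(20)
  ok_frames <- logical(20)
  oracle_ok <- TRUE
  for (i in seq_len(20)) {
    plan <- switch(plans[i],
      none = NULL,
      stable = pore_plan("HYDROPHILIC_PORE", radius = 0.15,
                         n_lining_headgroups = 8, frames_present = 1:10),
      multi = NULL)
    tr <- generate_trajectory(pore_spec(400 + i, plan = plan, n_dopc = 24),
                              n_frames = 10)
    if (plans[i] == "multi") {
      for (ax in list(c(0.65, 0.65), c(1.9, 0.65), c(1.25, 1.9)))
        tr <- plant_pore(tr, pore_plan("HYDROPHOBIC_COLUMN", radius = 0.1,
                                       frames_present = 4:6, axis_xy = ax))
    }
    ev <- track_defects(tr)
    span <- attr(ev, "per_frame_spanning")
    expected_span <- switch(plans[i],
      none = rep(0L, 10),
      stable = rep(1L, 10),
      multi = c(0L, 0L, 0L, 3L, 3L, 3L, 0L, 0L, 0L, 0L))
    ok_frames[i] <- identical(span, expected_span)
    got_regime[i] <- classify_regime(tr)$regime
    # brute-force detector oracle on one frame of each trajectory
    fr <- get_frame(tr, 5)
    ip <- which(fr$atoms$role == "PHOSPHATE_MARKER")
    zp <- fr$coords[ip, 3]
    midp <- mean(zp)
    lo <- mean(zp[zp <= midp]) + 0.3; hi <- mean(zp[zp > midp]) - 0.3
    io <- which(fr$atoms$role == "WATER_O")
    ins <- fr$coords[io, 3] >= lo & fr$coords[io, 3] <= hi
    if (sum(ins) <= 500) {
      lab <- bf_partition(fr$coords[io[ins], , drop = FALSE], fr$box, 0.35)
      d <- detect_defects(fr)
      sizes_bf <- sort(tabulate(lab))
      sizes_det <- sort(lengths(lapply(d, `[[`, "member_water_ids")))
      oracle_ok <- oracle_ok && identical(sizes_bf[sizes_bf > 0], sizes_det)
    }
  }
  expect_true(all(ok_frames))          # recall and precision both 1.0
  expect_true(oracle_ok)
  expect_equal(got_regime, c(none = "I", stable = "II", multi = "III")[plans],
               ignore_attr = TRUE)
})

test_that("regime evidence names the triggering events and thresholds", {
  tr <- generate_trajectory(pore_spec(500, n_dopc = 24,
    plan = pore_plan("HYDROPHILIC_PORE", radius = 0.15,
                     n_lining_headgroups = 8, frames_present = 1:10)),
    n_frames = 10)
  rr <- classify_regime(tr)
  expect_equal(rr$regime, "II")
  expect_equal(rr$n_stable, 1)
  expect_match(rr$evidence, "stable hydrophilic")
  expect_true(all(c("oo_cutoff", "stability_frames", "lining_min") %in%
                  names(rr$thresholds)))
  tab <- pore_event_table(track_defects(tr), n_frames_total = 10)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pore_class, "STABLE_HYDROPHILIC")
  expect_gte(tab$max_lining_count, 6)
})
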