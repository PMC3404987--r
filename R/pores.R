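# Detection, tracking and classification of transmembrane water defects.
#
# Thresholds (pre-registered constants, echoed in every output):
#   oo_cutoff      0.35 nm  O-O single-linkage clustering cutoff
#                           (first hydration-shell distance)
#   slab_margin    0.30 nm  slab = between leaflet mean phosphate planes,
#                           shrunk by this per side (excludes ordinary
#                           headgroup hydration water)
#   lining_radius  0.60 nm  headgroups within this of the axis line a pore
#   lining_min        6     headgroup atoms required for the lining criterion
#   stability_frames 10     lifetime (frames) separating stable from transient
#   overlap_min       1     shared waters linking defects across frames

.pore_defaults <- function() {
  list(oo_cutoff = 0.35, slab_margin = 0.30, lining_radius = 0.60,
       lining_min = 6L, stability_frames = 10L, overlap_min = 1L)
}

# single linkage by union-find over contact pairs (in-plane minimum image,
# plain z); the test suite holds this against an independent breadth-first
# search oracle
.single_linkage <- function(pos, box, cutoff) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  dx <- outer(pos[, 1], pos[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(pos[, 2], pos[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(pos[, 3], pos[, 3], "-")
  touch <- which(dx^2 + dy^2 + dz^2 <= cutoff^2 & upper.tri(dx), arr.ind = TRUE)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(touch)) for (e in seq_len(nrow(touch))) {
    a <- find(touch[e, 1]); b <- find(touch[e, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# circular (periodic-aware) in-plane centroid
.periodic_centroid <- function(xy, box) {
  vapply(1:2, function(ax) {
    th <- xy[, ax] / box[ax] * 2 * pi
    (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * box[ax]) %% box[ax]
  }, numeric(1))
}

#' Detect water defects in the hydrophobic slab of one frame
#'
#' Water oxygens inside the slab (between the leaflet mean phosphate
#' planes, shrunk by `slab_margin` per side) are clustered by single
#' linkage at the O-O cutoff with in-plane minimum image. Each cluster is a
#' defect; it spans the slab iff its members reach within one cutoff of
#' both slab faces. The lining count is the number of phosphate-marker and
#' Chol-hydroxyl atoms inside the slab within `lining_radius` of the
#' defect axis.
#'
#' @param frame a roles-assigned `bilayer_frame`.
#' @param oo_cutoff,slab_margin,lining_radius thresholds, nm (see defaults).
#' @param include_dmso count DMSO sulfur positions as defect members too
#'   (never toward the lining criterion); default `FALSE`.
#' @return list of defects, each a list with `frame_index`,
#'   `member_water_ids` (molecule ids), `spans_slab`, `axis_xy`,
#'   `max_radius`, `lining_headgroup_count`; attribute `bilayer_intact` is
#'   `FALSE` (with an empty list) when no slab can be defined.
#' @export
detect_defects <- function(frame, oo_cutoff = 0.35, slab_margin = 0.30,
                           lining_radius = 0.60, include_dmso = FALSE) {
  stopifnot(inherits(frame, "bilayer_frame"))
  atoms <- frame$atoms
  box <- frame$box
  ip <- which(atoms$role == "PHOSPHATE_MARKER")
  empty <- structure(list(), bilayer_intact = FALSE)
  if (length(ip) < 2) return(empty)
  zp <- frame$coords[ip, 3]
  mid <- mean(zp)
  up <- zp > mid
  if (!any(up) || all(up)) return(empty)
  z_lo <- mean(zp[!up]); z_hi <- mean(zp[up])
  if (z_hi - z_lo < max(1.0, 2 * slab_margin)) return(empty)
  slab_lo <- z_lo + slab_margin; slab_hi <- z_hi - slab_margin

  io <- which(atoms$role == "WATER_O")
  if (include_dmso) io <- c(io, which(atoms$role == "DMSO_S"))
  z <- frame$coords[io, 3]
  ins <- z >= slab_lo & z <= slab_hi
  io <- io[ins]
  if (!length(io)) return(structure(list(), bilayer_intact = TRUE))
  pos <- frame$coords[io, , drop = FALSE]
  lab <- .single_linkage(pos, box, oo_cutoff)

  ihead <- which(atoms$role %in% c("PHOSPHATE_MARKER", "CHOL_HYDROXYL_O"))
  hz <- frame$coords[ihead, 3]
  ihead <- ihead[hz >= slab_lo & hz <= slab_hi]
  hpos <- frame$coords[ihead, , drop = FALSE]

  defects <- lapply(seq_len(max(lab)), function(k) {
    rows <- which(lab == k)
    p <- pos[rows, , drop = FALSE]
    axis <- .periodic_centroid(p[, 1:2, drop = FALSE], box)
    dxy <- .min_image(cbind(p[, 1] - axis[1], p[, 2] - axis[2], 0), box)
    spans <- min(p[, 3]) <= slab_lo + oo_cutoff &&
             max(p[, 3]) >= slab_hi - oo_cutoff
    lining <- 0L
    if (nrow(hpos)) {
      hd <- .min_image(cbind(hpos[, 1] - axis[1], hpos[, 2] - axis[2], 0), box)
      lining <- sum(hd[, 1]^2 + hd[, 2]^2 <= lining_radius^2)
    }
    list(frame_index = NA_integer_,
         member_water_ids = sort(unique(atoms$mol_id[io[rows]])),
         spans_slab = spans, axis_xy = axis,
         max_radius = max(sqrt(dxy[, 1]^2 + dxy[, 2]^2)),
         lining_headgroup_count = lining)
  })
  structure(defects, bilayer_intact = TRUE,
            slab = c(slab_lo, slab_hi))
}

#' Track spanning defects across frames into pore events
#'
#' Spanning defects in consecutive frames are linked when they share at
#' least `overlap_min` member waters (single-file columns exchange members
#' rapidly, so the default is 1); maximal chains become pore events with
#' `lifetime = (last - first + 1) * frame_interval`.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @param overlap_min minimum shared member waters for a link.
#' @param ... thresholds passed to [detect_defects()].
#' @return list of `pore_event`s: `defects`, `first_frame`, `last_frame`,
#'   `lifetime_ps`; attributes `per_frame_spanning` (count per frame) and
#'   `bilayer_intact` (logical per frame).
#' @export
track_defects <- function(traj, overlap_min = 1L, ...) {
  traj <- .as_traj(traj)
  nf <- n_frames(traj)
  span_count <- integer(nf)
  intact <- logical(nf)
  per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    d <- detect_defects(get_frame(traj, f), ...)
    intact[f] <- isTRUE(attr(d, "bilayer_intact"))
    d <- Filter(function(x) x$spans_slab, d)
    for (k in seq_along(d)) d[[k]]$frame_index <- f
    span_count[f] <- length(d)
    per_frame[[f]] <- d
  }
  events <- list()
  active <- list()   # each: list(defects, members)
  for (f in seq_len(nf)) {
    cur <- per_frame[[f]]
    taken <- rep(FALSE, length(cur))
    nxt <- list()
    for (a in active) {
      best <- 0L; best_ov <- overlap_min - 1L
      for (j in seq_along(cur)) {
        if (taken[j]) next
        ov <- length(intersect(a$members, cur[[j]]$member_water_ids))
        if (ov > best_ov) { best <- j; best_ov <- ov }
      }
      if (best > 0L) {
        taken[best] <- TRUE
        a$defects <- c(a$defects, cur[best])
        a$members <- cur[[best]]$member_water_ids
        nxt[[length(nxt) + 1L]] <- a
      } else {
        events[[length(events) + 1L]] <- a$defects
      }
    }
    for (j in seq_along(cur)) if (!taken[j])
      nxt[[length(nxt) + 1L]] <- list(defects = cur[j],
                                      members = cur[[j]]$member_water_ids)
    active <- nxt
  }
  for (a in active) events[[length(events) + 1L]] <- a$defects
  events <- lapply(events, function(dd) {
    ff <- vapply(dd, `[[`, integer(1), "frame_index")
    structure(list(defects = dd, first_frame = min(ff), last_frame = max(ff),
                   lifetime_ps = (max(ff) - min(ff) + 1) * traj$frame_interval),
              class = "pore_event")
  })
  structure(events, per_frame_spanning = span_count, bilayer_intact = intact,
            n_frames = nf, frame_interval = traj$frame_interval)
}

#' Classify a pore event as transient hydrophobic or stable hydrophilic
#'
#' Stable lifetime means lasting at least `stability_frames` frames or
#' persisting to the trajectory end; the lining criterion requires at least
#' `lining_min` headgroup atoms within the lining radius in at least half
#' the event's frames. STABLE_HYDROPHILIC needs both; TRANSIENT_HYDROPHOBIC
#' neither; anything else (e.g. a long-lived bare column) is INDETERMINATE
#' and flagged for inspection.
#'
#' @param event a `pore_event` from [track_defects()].
#' @param n_frames_total trajectory length in frames (for persistence).
#' @param stability_frames,lining_min thresholds (see defaults).
#' @return one of `"TRANSIENT_HYDROPHOBIC"`, `"STABLE_HYDROPHILIC"`,
#'   `"INDETERMINATE"`.
#' @export
classify_pore <- function(event, n_frames_total,
                          stability_frames = 10L, lining_min = 6L) {
  stopifnot(inherits(event, "pore_event"))
  nf <- event$last_frame - event$first_frame + 1L
  stable_life <- nf >= stability_frames || event$last_frame == n_frames_total
  lining <- vapply(event$defects, `[[`, integer(1), "lining_headgroup_count")
  lining_met <- mean(lining >= lining_min) >= 0.5
  if (stable_life && lining_met) return("STABLE_HYDROPHILIC")
  if (!stable_life && !lining_met) return("TRANSIENT_HYDROPHOBIC")
  "INDETERMINATE"
}

#' Label a trajectory with its DMSO-action regime
#'
#' Regime III: the bilayer loses its two phosphate planes in any frame, or
#' at least `multi_pore_min` defects span the slab simultaneously (membrane
#' destruction). Regime II: otherwise, at least one stable hydrophilic pore.
#' Regime I: otherwise (at most sporadic transient defects). A trajectory
#' shorter than the stability threshold cannot separate stable from
#' transient and returns UNDETERMINED.
#'
#' @param traj a roles-assigned `bilayer_trajectory`.
#' @param stability_frames,lining_min,multi_pore_min thresholds.
#' @param ... passed to [track_defects()] / [detect_defects()].
#' @return a `regime_report`: list with `regime` ("I", "II", "III" or
#'   "UNDETERMINED"), `n_transient`, `n_stable`, `n_indeterminate`,
#'   `max_simultaneous_spanning`, `bilayer_intact`, `evidence` (text) and
#'   `thresholds`.
#' @export
classify_regime <- function(traj, stability_frames = 10L, lining_min = 6L,
                            multi_pore_min = 3L, ...) {
  traj <- .as_traj(traj)
  nf <- n_frames(traj)
  events <- track_defects(traj, ...)
  intact <- all(attr(events, "bilayer_intact"))
  max_sim <- if (nf) max(attr(events, "per_frame_spanning")) else 0L
  thresholds <- c(.pore_defaults()[c("oo_cutoff", "slab_margin", "lining_radius")],
                  list(lining_min = lining_min, stability_frames = stability_frames,
                       multi_pore_min = multi_pore_min))
  if (nf < stability_frames) {
    return(structure(list(regime = "UNDETERMINED", n_transient = NA_integer_,
                          n_stable = NA_integer_, n_indeterminate = NA_integer_,
                          max_simultaneous_spanning = max_sim,
                          bilayer_intact = intact,
                          evidence = sprintf(paste0("trajectory of %d frames is ",
                              "shorter than the stability threshold (%d frames); ",
                              "stable and transient pores cannot be separated"),
                              nf, stability_frames),
                          thresholds = thresholds),
                     class = "regime_report"))
  }
  cls <- vapply(events, classify_pore, "", n_frames_total = nf,
                stability_frames = stability_frames, lining_min = lining_min)
  n_stable <- sum(cls == "STABLE_HYDROPHILIC")
  n_transient <- sum(cls == "TRANSIENT_HYDROPHOBIC")
  n_ind <- sum(cls == "INDETERMINATE")
  ev <- character(0)
  if (!intact)
    ev <- c(ev, sprintf("bilayer not intact in frame(s) %s",
                        paste(which(!attr(events, "bilayer_intact")), collapse = ",")))
  if (max_sim >= multi_pore_min)
    ev <- c(ev, sprintf("%d simultaneous spanning defects (threshold %d)",
                        max_sim, multi_pore_min))
  regime <- if (!intact || max_sim >= multi_pore_min) "III"
            else if (n_stable >= 1) "II" else "I"
  if (regime == "II")
    ev <- c(ev, sprintf("%d stable hydrophilic pore event(s): frames %s",
                        n_stable,
                        paste(vapply(events[cls == "STABLE_HYDROPHILIC"],
                                     function(e) sprintf("%d-%d", e$first_frame,
                                                         e$last_frame), ""),
                              collapse = "; ")))
  if (regime == "I")
    ev <- c(ev, sprintf("no stable pores; %d transient, %d indeterminate event(s)",
                        n_transient, n_ind))
  structure(list(regime = regime, n_transient = n_transient,
                 n_stable = n_stable, n_indeterminate = n_ind,
                 max_simultaneous_spanning = max_sim, bilayer_intact = intact,
                 evidence = paste(ev, collapse = "; "),
                 thresholds = thresholds),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("regime %s (stable: %s, transient: %s, max simultaneous: %d, intact: %s)\n%s\n",
              x$regime, x$n_stable, x$n_transient, x$max_simultaneous_spanning,
              x$bilayer_intact, x$evidence))
  invisible(x)
}

#' Tabulate pore events
#'
#' @param events result of [track_defects()].
#' @param n_frames_total trajectory length in frames.
#' @param stability_frames,lining_min thresholds for [classify_pore()].
#' @return data.frame with one row per event: first/last frame, lifetime,
#'   class, maximum radius and maximum lining count.
#' @export
pore_event_table <- function(events, n_frames_total,
                             stability_frames = 10L, lining_min = 6L) {
  if (!length(events))
    return(data.frame(first_frame = integer(0), last_frame = integer(0),
                      lifetime_ps = numeric(0), pore_class = character(0),
                      max_radius_nm = numeric(0), max_lining_count = integer(0)))
  do.call(rbind, lapply(events, function(e) {
    data.frame(first_frame = e$first_frame, last_frame = e$last_frame,
               lifetime_ps = e$lifetime_ps,
               pore_class = classify_pore(e, n_frames_total, stability_frames,
                                          lining_min),
               max_radius_nm = max(vapply(e$defects, `[[`, numeric(1), "max_radius")),
               max_lining_count = max(vapply(e$defects, `[[`, integer(1),
                                             "lining_headgroup_count")))
  }))
}
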