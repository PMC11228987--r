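# Interaction detectors: hydrophobic contacts, hydrogen bonds, cation-pi.
#
# All three share one persistence rule: the geometric criterion must hold in
# a run of at least `min_consecutive` saved frames (a single-frame gap
# terminates a run; no gap tolerance), and replica-level consensus keeps only
# residue/partner interactions present in every replica.  Criteria defaults:
# hydrophobic pair distance <= 3 A; H...A <= 2.4 A with donor-H-acceptor
# angle >= 130 degrees; choline nitrogen simultaneously < 7 A from every
# aromatic ring atom.

.res_key <- function(atoms, rows)
  paste0(atoms$segid[rows], ":", atoms$resname[rows], atoms$resid[rows])

.empty_events <- function() {
  data.frame(kind = character(0), atom_ids = character(0),
             key1 = character(0), key2 = character(0),
             start = integer(0), end = integer(0), length = integer(0),
             stringsAsFactors = FALSE)
}

# logical pair-by-frame criterion matrix -> persistence-filtered event rows
.runs_to_events <- function(mask, min_consecutive, kind, atom_ids, key1, key2) {
  out <- list()
  for (p in seq_len(nrow(mask))) {
    runs <- .true_runs(mask[p, ])
    runs <- runs[runs$length >= min_consecutive, , drop = FALSE]
    if (!nrow(runs)) next
    out[[length(out) + 1]] <- data.frame(
      kind = kind, atom_ids = atom_ids[p], key1 = key1[p], key2 = key2[p],
      start = runs$start, end = runs$end, length = runs$length,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_events())
  ev <- do.call(rbind, out)
  ev[order(ev$key1, ev$key2, ev$start), , drop = FALSE]
}

# per-frame distances for a fixed list of row-index pairs (xy minimum image)
.pair_dist_frame <- function(coords, box, ia, ib, f) {
  d <- .fm(coords, ib, f) - .fm(coords, ia, f)
  d[, 1] <- d[, 1] - box[f, 1] * round(d[, 1] / box[f, 1])
  d[, 2] <- d[, 2] - box[f, 2] * round(d[, 2] / box[f, 2])
  sqrt(rowSums(d^2))
}

# atoms excluded as partners: same residue, or 1-2 / 1-3 bonded
.excluded_pairs <- function(traj) {
  n <- n_atoms(traj)
  adj <- .adjacency(traj$bonds, n)
  ex <- traj$bonds + 1L          # 1-2
  three <- list()
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      three[[length(three) + 1]] <- t(cmb)
    }
  }
  if (length(three)) ex <- rbind(ex, do.call(rbind, three))
  key <- paste(pmin(ex[, 1], ex[, 2]), pmax(ex[, 1], ex[, 2]))
  unique(key)
}

#' Detect persistent hydrophobic contacts
#'
#' A contact exists when two unbound candidate atoms (not covalently 1-2 or
#' 1-3 connected, and never within one residue) are within the cutoff for at
#' least `min_consecutive` consecutive frames.  Events are reported per atom
#' pair with residue-level keys so they aggregate to amino-acid / lipid
#' pairs.
#'
#' @param traj an `mi_trajectory`.
#' @param candidates 0-based candidate atom ids; defaults to the
#'   `hydrophobic_candidate` role flag.
#' @param cutoff angstrom.
#' @param min_consecutive minimum run length in saved frames.
#' @return event table: kind, atom ids, residue keys, 0-based inclusive
#'   window, length.
#' @export
detect_hydrophobic <- function(traj, candidates = NULL, cutoff = 3.0,
                               min_consecutive = 2L) {
  if (is.null(candidates))
    candidates <- traj$atoms$atom_id[traj$atoms$hydrophobic_candidate]
  if (!length(candidates)) {
    warning("empty hydrophobic candidate list")
    return(.empty_events())
  }
  rows <- .ai(sort(candidates))
  at <- traj$atoms
  # candidate pairs across different residues
  pr <- t(utils::combn(rows, 2))
  rk <- paste(at$segid, at$resid)
  pr <- pr[rk[pr[, 1]] != rk[pr[, 2]], , drop = FALSE]
  if (nrow(pr)) {
    ex <- .excluded_pairs(traj)
    pr <- pr[!(paste(pr[, 1], pr[, 2]) %in% ex), , drop = FALSE]
  }
  if (!nrow(pr)) return(.empty_events())
  nf <- n_frames(traj)
  # coarse prefilter: drop pairs never within cutoff in any frame
  mask <- matrix(FALSE, nrow(pr), nf)
  # boundary inclusive; 1e-9 A guards rounding at the printed criterion
  for (f in seq_len(nf))
    mask[, f] <- .pair_dist_frame(traj$coords, traj$box, pr[, 1], pr[, 2],
                                  f) <= cutoff + 1e-9
  keep <- rowSums(mask) > 0
  pr <- pr[keep, , drop = FALSE]; mask <- mask[keep, , drop = FALSE]
  if (!nrow(pr)) return(.empty_events())
  .runs_to_events(mask, min_consecutive, "hydrophobic",
                  atom_ids = paste(at$atom_id[pr[, 1]], at$atom_id[pr[, 2]],
                                   sep = ","),
                  key1 = .res_key(at, pr[, 1]), key2 = .res_key(at, pr[, 2]))
}

#' Detect persistent hydrogen bonds
#'
#' Criterion per frame: acceptor-to-hydrogen distance <= `d_ha` and
#' donor-H-acceptor angle >= `angle_min`, both simultaneously, sustained for
#' at least `min_consecutive` consecutive frames.  Donor heavy atoms are
#' resolved through the bond list; a flagged hydrogen without a bonded donor
#' is a topology error.
#'
#' @param traj an `mi_trajectory`.
#' @param hydrogens,acceptors 0-based ids; default to the role flags.
#' @param d_ha angstrom.
#' @param angle_min degrees.
#' @param min_consecutive minimum run length in frames.
#' @return event table as for [detect_hydrophobic()]; `atom_ids` is
#'   `donor,hydrogen,acceptor`.
#' @export
detect_hbonds <- function(traj, hydrogens = NULL, acceptors = NULL,
                          d_ha = 2.4, angle_min = 130, min_consecutive = 2L) {
  at <- traj$atoms
  if (is.null(hydrogens)) hydrogens <- at$atom_id[at$hbond_hydrogen]
  if (is.null(acceptors)) acceptors <- at$atom_id[at$hbond_acceptor]
  if (!length(hydrogens) || !length(acceptors)) return(.empty_events())
  adj <- .adjacency(traj$bonds, n_atoms(traj))
  h_rows <- .ai(sort(hydrogens)); a_rows <- .ai(sort(acceptors))
  d_rows <- vapply(h_rows, function(h) {
    nb <- adj[[h]]
    heavy <- nb[at$element[nb] %in% c("N", "O", "S")]
    .assert(length(heavy) >= 1, "mi_topology_error",
            "hydrogen atom %d has no bonded donor heavy atom", at$atom_id[h])
    heavy[1]
  }, integer(1))
  # triples: every hydrogen x every acceptor outside the donor's residue
  rk <- paste(at$segid, at$resid)
  tri <- expand.grid(hi = seq_along(h_rows), ai = seq_along(a_rows))
  H <- h_rows[tri$hi]; D <- d_rows[tri$hi]; A <- a_rows[tri$ai]
  keep <- rk[D] != rk[A] & A != D
  H <- H[keep]; D <- D[keep]; A <- A[keep]
  if (!length(H)) return(.empty_events())
  nf <- n_frames(traj)
  mask <- matrix(FALSE, length(H), nf)
  cos_min <- cos(angle_min * pi / 180)
  for (f in seq_len(nf)) {
    box <- traj$box
    dHA <- .pair_dist_frame(traj$coords, box, H, A, f)
    # angle at H between D and A (minimum-image displacements)
    vd <- .fm(traj$coords, D, f) - .fm(traj$coords, H, f)
    va <- .fm(traj$coords, A, f) - .fm(traj$coords, H, f)
    vd[, 1:2] <- .mi_disp(vd, box[f, ])[, 1:2]
    va[, 1:2] <- .mi_disp(va, box[f, ])[, 1:2]
    cosang <- rowSums(vd * va) /
      pmax(sqrt(rowSums(vd^2)) * sqrt(rowSums(va^2)), 1e-12)
    # angle >= angle_min  <=>  cos(angle) <= cos(angle_min); criteria are
    # boundary inclusive, with tiny guards against rounding at equality
    mask[, f] <- dHA <= d_ha + 1e-9 & cosang <= cos_min + 1e-12
  }
  .runs_to_events(mask, min_consecutive, "hbond",
                  atom_ids = paste(at$atom_id[D], at$atom_id[H],
                                   at$atom_id[A], sep = ","),
                  key1 = .res_key(at, D), key2 = .res_key(at, A))
}

#' Detect persistent cation-pi interactions
#'
#' A cation-pi interaction exists in a frame when every atom of an aromatic
#' ring is strictly within the cutoff of a choline nitrogen; persistence as
#' for the other detectors.
#'
#' @param traj an `mi_trajectory`.
#' @param rings list of 0-based atom-id vectors (5 or 6 atoms each);
#'   defaults to `aromatic_ring_member` atoms grouped by residue.
#' @param cations 0-based choline nitrogen ids; defaults to the role flag.
#' @param cutoff angstrom.
#' @param min_consecutive minimum run length in frames.
#' @return event table; `atom_ids` is `ring...:nitrogen`.
#' @export
detect_cation_pi <- function(traj, rings = NULL, cations = NULL,
                             cutoff = 7.0, min_consecutive = 2L) {
  at <- traj$atoms
  if (is.null(rings)) {
    rr <- which(at$aromatic_ring_member)
    rings <- unname(split(at$atom_id[rr], paste(at$segid[rr], at$resid[rr])))
  }
  if (is.null(cations)) cations <- at$atom_id[at$choline_nitrogen]
  if (!length(rings) || !length(cations)) return(.empty_events())
  for (r in rings)
    .assert(length(r) %in% c(5, 6), "mi_topology_error",
            "aromatic ring must have 5 or 6 atoms, got %d", length(r))
  nf <- n_frames(traj)
  combo <- expand.grid(ri = seq_along(rings), ci = seq_along(cations))
  mask <- matrix(FALSE, nrow(combo), nf)
  for (k in seq_len(nrow(combo))) {
    rrows <- .ai(rings[[combo$ri[k]]])
    crow <- .ai(cations[combo$ci[k]])
    for (f in seq_len(nf)) {
      d <- .pair_dist_frame(traj$coords, traj$box, rrows,
                            rep(crow, length(rrows)), f)
      mask[k, f] <- all(d < cutoff)
    }
  }
  ring_first <- vapply(rings, function(r) .ai(r[1]), integer(1))
  .runs_to_events(mask, min_consecutive, "cation_pi",
                  atom_ids = vapply(seq_len(nrow(combo)), function(k)
                    paste0(paste(rings[[combo$ri[k]]], collapse = ","), ":",
                           cations[combo$ci[k]]), ""),
                  key1 = .res_key(at, ring_first[combo$ri]),
                  key2 = .res_key(at, .ai(cations[combo$ci])))
}

# union of event frames per residue pair -> logical vector over frames
.pair_presence <- function(events, n_frames) {
  keys <- paste(events$kind, events$key1, events$key2, sep = "|")
  lapply(split(seq_len(nrow(events)), keys), function(rows) {
    m <- logical(n_frames)
    for (r in rows) m[.fi(events$start[r]:events$end[r])] <- TRUE
    m
  })
}

#' Residue-level interaction inventory
#'
#' Aggregates atom-level events to residue/partner pairs: occupancy fraction
#' over the analysis window, event count, mean and maximum event duration.
#'
#' @param events event table from a detector.
#' @param n_frames total frames of the source trajectory.
#' @param frame_interval ns per frame (durations in ns).
#' @param window optional `mi_window` restricting the occupancy denominator.
#' @return data.frame: kind, key1, key2, occupancy, n_events, mean/max
#'   duration (ns).
#' @export
interaction_inventory <- function(events, n_frames, frame_interval = 1,
                                  window = NULL) {
  if (!nrow(events))
    return(data.frame(kind = character(0), key1 = character(0),
                      key2 = character(0), occupancy = numeric(0),
                      n_events = integer(0), mean_duration = numeric(0),
                      max_duration = numeric(0), stringsAsFactors = FALSE))
  if (is.null(window)) window <- frame_window(0, n_frames - 1L)
  wmask <- logical(n_frames); wmask[.fi(window$start:window$end)] <- TRUE
  pres <- .pair_presence(events, n_frames)
  keys <- do.call(rbind, strsplit(names(pres), "|", fixed = TRUE))
  evkey <- paste(events$kind, events$key1, events$key2, sep = "|")
  data.frame(
    kind = keys[, 1], key1 = keys[, 2], key2 = keys[, 3],
    occupancy = vapply(pres, function(m) sum(m & wmask) / sum(wmask), 0),
    n_events = as.integer(table(evkey)[names(pres)]),
    mean_duration = vapply(names(pres), function(k)
      mean(events$length[evkey == k]) * frame_interval, 0),
    max_duration = vapply(names(pres), function(k)
      max(events$length[evkey == k]) * frame_interval, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Replica consensus over interaction inventories
#'
#' Retains residue/partner interactions detected in every replica and
#' reports the per-replica occupancies alongside.  A single replica passes
#' through unchanged (with its occupancy as `occ_1`).
#'
#' @param inventories list of [interaction_inventory()] tables sharing one
#'   residue naming scheme.
#' @return consensus data.frame: kind, key1, key2, per-replica occupancy
#'   columns, `min_occupancy`, `n_replicas`.
#' @export
replica_consensus <- function(inventories) {
  .assert(length(inventories) >= 1, "mi_replica_error", "no inventories given")
  cols <- c("kind", "key1", "key2", "occupancy")
  for (inv in inventories)
    .assert(all(cols %in% names(inv)), "mi_replica_error",
            "inventory missing residue-key columns")
  keys <- lapply(inventories, function(inv)
    paste(inv$kind, inv$key1, inv$key2, sep = "|"))
  shared <- Reduce(intersect, keys)
  if (!length(shared))
    return(data.frame(kind = character(0), key1 = character(0),
                      key2 = character(0), min_occupancy = numeric(0),
                      n_replicas = integer(0), stringsAsFactors = FALSE))
  base <- inventories[[1]][match(shared, keys[[1]]), c("kind", "key1", "key2")]
  occ <- vapply(seq_along(inventories), function(r)
    inventories[[r]]$occupancy[match(shared, keys[[r]])],
    numeric(length(shared)))
  occ <- matrix(occ, nrow = length(shared))
  colnames(occ) <- paste0("occ_", seq_along(inventories))
  out <- cbind(base, as.data.frame(occ),
               data.frame(min_occupancy = apply(occ, 1, min),
                          n_replicas = length(inventories)))
  rownames(out) <- NULL
  out
}

#' Windowed mean contact count
#'
#' Splits the trajectory into fixed-width time windows and reports, per
#' window, the mean over its frames of the instantaneous number of
#' residue-level contacts involving the selected residues (the 20-ns-window
#' contact series used to follow individual anchoring residues).
#'
#' @param events event table.
#' @param n_frames total frames.
#' @param frame_interval ns per frame.
#' @param window_width ns; must be a positive multiple of `frame_interval`.
#' @param selection residue keys (matched against `key1` or `key2`); `NULL`
#'   keeps every contact.
#' @return data.frame: window index, start/end time (ns), mean contact count.
#' @export
windowed_contact_series <- function(events, n_frames, frame_interval = 1,
                                    window_width = 20, selection = NULL) {
  ratio <- window_width / frame_interval
  .assert(ratio > 0 && abs(ratio - round(ratio)) < 1e-9, "mi_config_error",
          "window_width must be a positive multiple of the frame interval")
  if (!is.null(selection)) {
    if (!nrow(events)) return(data.frame(window = integer(0),
                                         t_start = numeric(0),
                                         t_end = numeric(0),
                                         mean_contacts = numeric(0)))
    events <- events[events$key1 %in% selection |
                       events$key2 %in% selection, , drop = FALSE]
  }
  per_frame <- numeric(n_frames)
  if (nrow(events))
    for (m in .pair_presence(events, n_frames)) per_frame <- per_frame + m
  wof <- floor((seq_len(n_frames) - 1L) / round(ratio))
  agg <- tapply(per_frame, wof, mean)
  idx <- as.integer(names(agg))
  data.frame(window = idx,
             t_start = idx * window_width,
             t_end = (idx + 1) * window_width,
             mean_contacts = as.numeric(agg), row.names = NULL)
}
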