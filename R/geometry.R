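# Low-level geometric kernels: periodic minimum-image distances, superposition
# RMSD, axis angles, phosphorus-plane fitting.
#
# Minimum-image convention is applied in x and y only: slab systems are
# assumed aligned with the membrane normal along z, and the protein is
# assumed not wrapped across z, which avoids spurious cross-leaflet contacts.

# displacement matrix under xy minimum image; d is n x 3, box length-3
.mi_disp <- function(d, box) {
  d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
  d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
  d
}

#' Minimum-image distance
#'
#' Euclidean distance under the orthorhombic minimum-image convention in x
#' and y; z is left unwrapped (membrane normal).
#'
#' @param p1,p2 points (length-3) or n x 3 matrices, angstrom.
#' @param box box lengths `(Lx, Ly, Lz)`, angstrom.
#' @return distance(s), angstrom.
#' @export
min_image_distance <- function(p1, p2, box) {
  .assert(all(box > 0), "mi_format_error", "box lengths must be positive")
  p1 <- matrix(p1, ncol = 3); p2 <- matrix(p2, ncol = 3)
  d <- .mi_disp(p2 - p1[rep_len(seq_len(nrow(p1)), nrow(p2)), , drop = FALSE],
                box)
  sqrt(rowSums(d^2))
}

# cross distances group_a (n x 3) vs group_b (m x 3) -> n x m matrix
.cross_dist <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(a[, 2], b[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(a[, 3], b[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Atom pairs within a cutoff
#'
#' All unordered cross pairs between two atom groups with minimum-image
#' distance at or below the cutoff, symmetric in group order.
#'
#' @param traj an `mi_trajectory`.
#' @param group_a,group_b 0-based atom-id vectors (nonempty).
#' @param cutoff angstrom, > 0.
#' @param frame 0-based frame index.
#' @return 2-column matrix of 0-based id pairs (first column = smaller id).
#' @export
pairs_within <- function(traj, group_a, group_b, cutoff, frame = 0) {
  .assert(length(group_a) > 0 && length(group_b) > 0, "mi_format_error",
          "atom groups must be nonempty")
  .assert(cutoff > 0, "mi_format_error", "cutoff must be positive")
  xyz <- frame_coords(traj, frame)
  dm <- .cross_dist(xyz[.ai(group_a), , drop = FALSE],
                    xyz[.ai(group_b), , drop = FALSE], traj$box[.fi(frame), ])
  hit <- which(dm <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(matrix(integer(0), 0, 2))
  p <- cbind(group_a[hit[, 1]], group_b[hit[, 2]])
  p <- p[p[, 1] != p[, 2], , drop = FALSE]
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  unique(p[order(p[, 1], p[, 2]), , drop = FALSE])
}

#' Backbone RMSD series against a reference
#'
#' Per-frame root-mean-square deviation over the selected atoms after
#' least-squares rigid-body superposition onto the reference coordinates
#' (uniform weights; the atom selection itself restricts to backbone).
#'
#' @param traj an `mi_trajectory`.
#' @param reference `n x 3` matrix of reference coordinates for `atom_ids`,
#'   or a 0-based frame index of `traj` to use as reference.
#' @param atom_ids 0-based ids (at least 3; superposition is ill-posed below).
#' @param fit re-fit the superposition per frame (default).  With
#'   `fit = FALSE` the plain RMSD of already-superposed coordinates is
#'   returned, for which local displacements obey the closed form
#'   sqrt(sum d_i^2 / n) exactly.
#' @return numeric vector, one RMSD (angstrom) per frame.
#' @export
backbone_rmsd <- function(traj, reference, atom_ids, fit = TRUE) {
  .assert(length(atom_ids) >= 3, "mi_format_error",
          "need at least 3 atoms for superposition")
  rows <- .ai(atom_ids)
  if (is.numeric(reference) && length(reference) == 1)
    reference <- frame_coords(traj, reference)[rows, , drop = FALSE]
  .assert(nrow(reference) == length(atom_ids), "mi_atom_count_mismatch",
          "reference has %d atoms, selection has %d",
          nrow(reference), length(atom_ids))
  ref_vec <- as.numeric(t(reference))
  vapply(seq_len(n_frames(traj)) - 1L, function(f) {
    bio3d::rmsd(ref_vec, as.numeric(t(frame_coords(traj, f)[rows, ])),
                fit = fit)
  }, numeric(1))
}

#' Angle of an atom-pair axis to the membrane normal
#'
#' Angle between the vector a -> b and +z, folded to \[0, 90\] degrees (the
#' two orientations of a helix axis are equivalent for tilt).  Lipid tail
#' tilt deliberately does NOT use this folding; see [tail_tilt_series()].
#'
#' @param traj an `mi_trajectory` (or a Frame given as an `n x 3` matrix with
#'   atom ids indexing rows 0-based).
#' @param atom_a,atom_b distinct 0-based atom ids.
#' @param frame 0-based frame index (vectorised over all frames if `NULL`).
#' @return degrees in \[0, 90\]; vector over frames when `frame = NULL`.
#' @export
axis_angle_to_normal <- function(traj, atom_a, atom_b, frame = NULL) {
  .assert(atom_a != atom_b, "mi_format_error", "atoms must be distinct")
  frames <- if (is.null(frame)) seq_len(n_frames(traj)) - 1L else frame
  vapply(frames, function(f) {
    xyz <- frame_coords(traj, f)
    v <- xyz[.ai(atom_b), ] - xyz[.ai(atom_a), ]
    nv <- sqrt(sum(v^2))
    .assert(nv > 1e-12, "mi_format_error", "coincident atoms define no axis")
    ang <- acos(pmin(1, pmax(-1, abs(v[3]) / nv))) * 180 / pi
    ang
  }, numeric(1))
}

#' Fit the phosphorus plane of a leaflet
#'
#' The bilayer reference plane is the mean z of the leaflet's phosphorus
#' atoms: computed per frame, and time-averaged over the analysis window
#' (the window average is the default reference for depth and snorkeling,
#' matching a reference plane computed from binding to the end of the run).
#'
#' @param traj an `mi_trajectory`.
#' @param leaflet_ids 0-based ids of the leaflet phosphorus atoms.
#' @param window `mi_window`; defaults to all frames.
#' @return class `mi_bilayer_ref`: `plane_z` (per-frame, full trajectory),
#'   `mean_z` (window average), `window`, `leaflet_ids`.
#' @export
fit_phosphorus_plane <- function(traj, leaflet_ids, window = NULL) {
  .assert(length(leaflet_ids) > 0, "mi_format_error", "empty leaflet selection")
  if (is.null(window)) window <- frame_window(0, n_frames(traj) - 1L)
  fr <- .window_frames(window, traj)
  .assert(length(fr) > 0, "mi_window_error", "empty window")
  rows <- .ai(leaflet_ids)
  plane_z <- vapply(seq_len(n_frames(traj)),
                    function(f) mean(traj$coords[rows, 3, f]), numeric(1))
  structure(list(plane_z = plane_z, mean_z = mean(plane_z[.fi(fr)]),
                 window = window, leaflet_ids = leaflet_ids),
            class = "mi_bilayer_ref")
}

#' Assign lipids to leaflets
#'
#' A lipid belongs to the leaflet whose phosphorus sits above or below the
#' bilayer midplane (mean of all phosphorus z) in the first analysis frame;
#' the assignment is fixed thereafter (flip-flop is not tracked at these
#' timescales).
#'
#' @param traj an `mi_trajectory`.
#' @param frame 0-based frame used for the assignment.
#' @return list with `upper` and `lower` 0-based phosphorus atom ids.
#' @export
assign_leaflets <- function(traj, frame = 0) {
  p_ids <- traj$atoms$atom_id[traj$atoms$phosphorus]
  .assert(length(p_ids) > 0, "mi_topology_error", "no phosphorus atoms found")
  z <- frame_coords(traj, frame)[.ai(p_ids), 3]
  mid <- mean(z)
  list(upper = p_ids[z >= mid], lower = p_ids[z < mid])
}
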