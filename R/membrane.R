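# Membrane-referenced protein descriptors: binding detection, insertion
# depth, tilt series, density profiles, minimum-distance series.

#' Per-frame minimum heavy-atom distance between two groups
#'
#' Hydrogens are excluded; distances use the xy minimum image.
#'
#' @param traj an `mi_trajectory`.
#' @param group_a,group_b 0-based atom-id vectors (nonempty).
#' @param heavy_only drop hydrogens from both groups.
#' @return numeric vector of per-frame minima, angstrom.
#' @export
min_distance_series <- function(traj, group_a, group_b, heavy_only = TRUE) {
  .assert(length(group_a) > 0 && length(group_b) > 0, "mi_format_error",
          "atom groups must be nonempty")
  if (heavy_only) {
    group_a <- .heavy_ids(traj, group_a)
    group_b <- .heavy_ids(traj, group_b)
  }
  ra <- .ai(group_a); rb <- .ai(group_b)
  vapply(seq_len(n_frames(traj)), function(f) {
    min(.cross_dist(.fm(traj$coords, ra, f), .fm(traj$coords, rb, f),
                    traj$box[f, ]))
  }, numeric(1))
}

#' Detect the membrane binding event
#'
#' The binding frame is the first frame from which the minimum protein to
#' bilayer heavy-atom distance stays at or below `cutoff` continuously for
#' at least `dwell` ns (a run of k frames lasts k * frame_interval ns).  A
#' sustained-dwell requirement excludes grazing encounters; the defaults
#' (4 A, 10 ns) are a conservative contact criterion and both are
#' configurable.
#'
#' @param traj an `mi_trajectory`.
#' @param protein_ids,bilayer_ids 0-based atom ids (nonempty).
#' @param cutoff angstrom.
#' @param dwell ns; must be at least one frame interval.
#' @return 0-based frame index of binding, or `NA_integer_` if never bound.
#' @export
detect_binding_event <- function(traj, protein_ids = NULL, bilayer_ids = NULL,
                                 cutoff = 4.0, dwell = 10) {
  if (is.null(protein_ids))
    protein_ids <- select_atoms(traj, "protein")
  if (is.null(bilayer_ids))
    bilayer_ids <- select_atoms(traj, "lipid")
  .assert(dwell >= traj$frame_interval, "mi_config_error",
          "dwell (%g ns) shorter than the frame interval (%g ns)",
          dwell, traj$frame_interval)
  mind <- min_distance_series(traj, protein_ids, bilayer_ids)
  need <- ceiling(dwell / traj$frame_interval - 1e-9)
  runs <- .true_runs(mind <= cutoff)
  hit <- runs[runs$length >= need, , drop = FALSE]
  if (!nrow(hit)) return(NA_integer_)
  hit$start[1]
}

#' Bilayer reference for the protein-proximal leaflet
#'
#' Assigns leaflets from the first analysis frame, picks the leaflet whose
#' average phosphorus plane is nearer the protein centroid at the binding
#' frame, and fits the per-frame and window-averaged plane.
#'
#' @param traj an `mi_trajectory`.
#' @param protein_ids 0-based protein atom ids.
#' @param bound_window `mi_window` over which the plane is averaged
#'   (typically binding frame to the last frame).
#' @return `mi_bilayer_ref` with an extra `leaflets` element.
#' @export
proximal_bilayer_reference <- function(traj, protein_ids = NULL,
                                       bound_window = NULL) {
  if (is.null(protein_ids)) protein_ids <- select_atoms(traj, "protein")
  if (is.null(bound_window)) bound_window <- frame_window(0, n_frames(traj) - 1L)
  lf <- assign_leaflets(traj, frame = bound_window$start)
  cen <- mean(frame_coords(traj, bound_window$start)[.ai(protein_ids), 3])
  zu <- mean(frame_coords(traj, bound_window$start)[.ai(lf$upper), 3])
  zl <- mean(frame_coords(traj, bound_window$start)[.ai(lf$lower), 3])
  prox <- if (abs(cen - zu) <= abs(cen - zl)) lf$upper else lf$lower
  ref <- fit_phosphorus_plane(traj, prox, bound_window)
  ref$leaflets <- lf
  ref
}

#' Depth of insertion per residue
#'
#' For each protein residue, the signed z distance between its beta carbon
#' (alpha carbon for glycine) and the phosphorus plane of the engaged
#' leaflet, averaged over the bound window.  Positive depths lie above the
#' plane, negative below (inserted past the phosphates).
#'
#' @param traj an `mi_trajectory`.
#' @param ref bilayer reference from [proximal_bilayer_reference()] /
#'   [fit_phosphorus_plane()].
#' @param bound_window `mi_window`; depth is only meaningful from the
#'   binding event onward.
#' @param plane one of `"window"` (default: window-averaged plane, matching
#'   a reference computed from binding to the end of the run) or
#'   `"frame"` (per-frame plane).
#' @return data.frame: resid, resname, atom name used, mean depth, sd.
#' @export
depth_of_insertion <- function(traj, ref, bound_window, plane = c("window", "frame")) {
  plane <- match.arg(plane)
  at <- traj$atoms
  prot <- which(at$resname %in% .AMINO_ACIDS)
  .assert(length(prot) > 0, "mi_topology_error", "no protein residues found")
  res <- unique(at$resid[prot])
  rows <- vapply(res, function(r) {
    cand <- which(at$resid == r & at$resname %in% .AMINO_ACIDS &
                    at$name == if (at$resname[match(r, at$resid)] == "GLY")
                      "CA" else "CB")
    .assert(length(cand) >= 1, "mi_topology_error",
            "residue %d lacks a beta carbon (or glycine alpha carbon)", r)
    cand[1]
  }, integer(1))
  fr <- .window_frames(bound_window, traj)
  zs <- traj$coords[rows, 3, .fi(fr), drop = FALSE]
  zs <- matrix(zs, nrow = length(rows))
  pl <- if (plane == "window") rep(ref$mean_z, length(fr)) else
    ref$plane_z[.fi(fr)]
  depth <- sweep(zs, 2, pl)
  data.frame(resid = res, resname = at$resname[rows], atom = at$name[rows],
             depth_mean = rowMeans(depth),
             depth_sd = apply(depth, 1, sd), row.names = NULL)
}

#' Protein tilt-angle series
#'
#' Per-frame angle between the axis defined by two atoms (the alpha carbons
#' of the C-terminal helix ends) and the membrane normal, folded to
#' \[0, 90\] degrees.
#'
#' @param traj an `mi_trajectory`.
#' @param atom_a,atom_b 0-based atom ids defining the axis.
#' @param bound_window optional `mi_window` for the summary statistics.
#' @return list: `angle` (per-frame series, degrees), `mean`, `sd` (over the
#'   bound window, or all frames).
#' @export
tilt_series <- function(traj, atom_a, atom_b, bound_window = NULL) {
  ang <- axis_angle_to_normal(traj, atom_a, atom_b)
  fr <- if (is.null(bound_window)) seq_along(ang) else
    .fi(.window_frames(bound_window, traj))
  list(angle = ang, mean = mean(ang[fr]), sd = sd(ang[fr]))
}

#' Density profile along the membrane normal
#'
#' Per-group weighted number density in z bins, averaged over the window and
#' normalised per cubic angstrom using the box cross-section.  Weighting is
#' by atomic number (an electron-count approximation), mass, or unity.
#'
#' @param traj an `mi_trajectory`.
#' @param groups named list of 0-based atom-id vectors.
#' @param window `mi_window`; defaults to all frames.
#' @param bin bin width, angstrom (> 0).
#' @param weighting `"electron"`, `"mass"` or `"number"`.
#' @param z_range optional `c(zmin, zmax)`; defaults to the data range.
#' @return data.frame: group, bin centre z, density (weight per A^3), and
#'   the unnormalised mean weight per bin.
#' @export
density_profile <- function(traj, groups, window = NULL, bin = 1,
                            weighting = c("electron", "mass", "number"),
                            z_range = NULL) {
  weighting <- match.arg(weighting)
  .assert(bin > 0, "mi_config_error", "bin width must be positive")
  if (is.null(window)) window <- frame_window(0, n_frames(traj) - 1L)
  fr <- .window_frames(window, traj)
  at <- traj$atoms
  out <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (!length(ids)) next
    rows <- .ai(ids)
    w <- switch(weighting,
                electron = .element_z(at$element[rows]),
                mass = at$mass[rows],
                number = rep(1, length(rows)))
    z <- as.numeric(traj$coords[rows, 3, .fi(fr)])
    wts <- rep(w, times = length(fr))
    rng <- if (is.null(z_range)) range(z) else z_range
    edges <- seq(floor(rng[1] / bin) * bin, ceiling(rng[2] / bin) * bin,
                 by = bin)
    if (length(edges) < 2) edges <- c(edges, edges + bin)
    idx <- findInterval(z, edges, rightmost.closed = TRUE)
    idx[idx < 1] <- 1; idx[idx > length(edges) - 1] <- length(edges) - 1
    tot <- tapply(wts, factor(idx, levels = seq_len(length(edges) - 1)), sum)
    tot[is.na(tot)] <- 0
    area <- mean(traj$box[.fi(fr), 1] * traj$box[.fi(fr), 2])
    out[[g]] <- data.frame(
      group = g, z = (edges[-1] + edges[-length(edges)]) / 2,
      density = as.numeric(tot) / length(fr) / (area * bin),
      mean_weight = as.numeric(tot) / length(fr), row.names = NULL)
  }
  if (!length(out))
    return(data.frame(group = character(0), z = numeric(0),
                      density = numeric(0), mean_weight = numeric(0)))
  do.call(rbind, out)
}
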