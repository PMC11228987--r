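# Core domain types: atom table, trajectory, replica set, frame window.

# Role flags every atom table carries.
.FLAG_COLS <- c("hydrophobic_candidate", "hbond_donor_heavy", "hbond_hydrogen",
                "hbond_acceptor", "aromatic_ring_member", "choline_nitrogen",
                "phosphorus", "tail_terminal_carbon", "c2_carbon",
                "beta_carbon", "alpha_carbon", "backbone")

#' Build an atom table
#'
#' Creates the topology table used by all analyses: one row per atom with
#' identity columns and logical role flags (phosphorus, choline nitrogen,
#' hydrogen-bond donor/hydrogen/acceptor, aromatic-ring member, hydrophobic
#' candidate, tail terminal carbon, glycerol C2, alpha/beta carbon, backbone).
#' Missing flag columns are added as `FALSE`.
#'
#' @param name,element,resid,resname,segid,mass per-atom vectors (recycled
#'   scalars allowed). `resid` is an integer residue number, `segid`
#'   distinguishes protein / lipid species / solvent segments.
#' @param ... named logical flag vectors, e.g. `phosphorus = ...`.
#' @return A `data.frame` with 0-based `atom_id` and all role-flag columns.
#' @export
atom_table <- function(name, element = .guess_element(name), resid = 1L,
                       resname = "UNK", segid = "A",
                       mass = .element_mass(element), ...) {
  n <- length(name)
  at <- data.frame(atom_id = seq_len(n) - 1L, name = as.character(name),
                   element = as.character(element),
                   resid = as.integer(rep_len(resid, n)),
                   resname = as.character(rep_len(resname, n)),
                   segid = as.character(rep_len(segid, n)),
                   mass = as.numeric(rep_len(mass, n)),
                   stringsAsFactors = FALSE)
  flags <- list(...)
  for (f in .FLAG_COLS) {
    v <- if (!is.null(flags[[f]])) rep_len(as.logical(flags[[f]]), n) else FALSE
    at[[f]] <- rep_len(v, n)
  }
  at
}

.validate_atoms <- function(atoms) {
  .assert(!anyDuplicated(atoms$atom_id), "mi_topology_error",
          "duplicate atom_id in topology")
  .assert(all(.FLAG_COLS %in% names(atoms)), "mi_topology_error",
          "atom table missing role-flag columns")
  invisible(atoms)
}

#' Construct a trajectory
#'
#' A trajectory couples a topology (atom table + bonds) with an ordered set
#' of frames.  Coordinates are stored as an `n_atoms x 3 x n_frames` array in
#' angstrom; the orthorhombic box is per-frame; times are in ns with constant
#' spacing.
#'
#' @param atoms atom table from [atom_table()].
#' @param coords numeric array `c(n_atoms, 3, n_frames)` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param box per-frame box lengths: length-3 vector or `n_frames x 3` matrix.
#' @param bonds 2-column matrix of 0-based atom-id pairs (may have 0 rows).
#' @param frame_interval time between frames, ns.
#' @param start_time time of frame 0, ns.
#' @return An object of class `mi_trajectory`.
#' @export
trajectory <- function(atoms, coords, box, bonds = matrix(integer(0), 0, 2),
                       frame_interval = 1, start_time = 0) {
  .validate_atoms(atoms)
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  .assert(dim(coords)[1] == nrow(atoms), "mi_atom_count_mismatch",
          "topology has %d atoms but frames have %d",
          nrow(atoms), dim(coords)[1])
  .assert(dim(coords)[2] == 3, "mi_format_error", "coords must be N x 3 x F")
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  .assert(all(box > 0), "mi_format_error", "box lengths must be positive")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  .assert(nrow(bonds) == 0 || all(bonds %in% atoms$atom_id),
          "mi_topology_error", "bond references unknown atom id")
  structure(list(atoms = atoms, bonds = bonds, coords = coords, box = box,
                 times = start_time + (seq_len(nf) - 1) * frame_interval,
                 frame_interval = frame_interval),
            class = "mi_trajectory")
}

#' @export
print.mi_trajectory <- function(x, ...) {
  cat(sprintf("<mi_trajectory> %d atoms, %d frames, dt = %g ns, box %s A\n",
              n_atoms(x), n_frames(x), x$frame_interval,
              paste(signif(x$box[1, ], 4), collapse = " x ")))
  invisible(x)
}

#' Number of atoms / frames in a trajectory
#' @param traj an `mi_trajectory`.
#' @return integer count.
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' @rdname n_atoms
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame's coordinates
#' @param traj an `mi_trajectory`.
#' @param frame 0-based frame index.
#' @return `n_atoms x 3` matrix (angstrom).
#' @export
frame_coords <- function(traj, frame) traj$coords[, , .fi(frame), drop = TRUE]

#' Inclusive frame window
#'
#' Frame indices are 0-based and both ends are inclusive, the single
#' convention used by every analysis stage.
#'
#' @param start,end 0-based inclusive frame indices.
#' @return class `mi_window` with fields `start`, `end`.
#' @export
frame_window <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  .assert(start >= 0 && start <= end, "mi_window_error",
          "invalid window [%d, %d]", start, end)
  structure(list(start = start, end = end), class = "mi_window")
}

.window_frames <- function(window, traj = NULL) {
  if (!is.null(traj))
    .assert(window$end < n_frames(traj), "mi_window_error",
            "window end %d beyond last frame %d", window$end, n_frames(traj) - 1L)
  window$start:window$end
}

#' Group replica trajectories that share one topology schema
#'
#' Replica-consensus rules (an interaction must appear in all replicas)
#' require replicas with identical residue naming.
#'
#' @param label system label.
#' @param replicas list of `mi_trajectory` objects.
#' @return class `mi_replica_set`.
#' @export
replica_set <- function(label, replicas) {
  .assert(length(replicas) >= 1, "mi_replica_error", "need at least one replica")
  key <- function(t) paste(t$atoms$segid, t$atoms$resid, t$atoms$resname,
                           t$atoms$name, collapse = "|")
  keys <- vapply(replicas, key, "")
  .assert(all(keys == keys[1]), "mi_replica_error",
          "replica topologies differ in residue naming")
  structure(list(label = label, replicas = replicas), class = "mi_replica_set")
}

#' @export
print.mi_replica_set <- function(x, ...) {
  cat(sprintf("<mi_replica_set> '%s': %d replica(s) of %d atoms\n",
              x$label, length(x$replicas), n_atoms(x$replicas[[1]])))
  invisible(x)
}

#' Subsample a trajectory by stride
#'
#' Keeps every `stride`-th frame starting from frame 0.  Persistence rules in
#' the interaction detectors are counted in saved frames, so the stride used
#' should be reported alongside results.
#'
#' @param traj an `mi_trajectory`.
#' @param stride positive integer.
#' @return strided `mi_trajectory`.
#' @export
stride_trajectory <- function(traj, stride) {
  stride <- as.integer(stride)
  .assert(stride >= 1, "mi_format_error", "stride must be >= 1")
  keep <- seq(1L, n_frames(traj), by = stride)
  out <- traj
  out$coords <- traj$coords[, , keep, drop = FALSE]
  out$box <- traj$box[keep, , drop = FALSE]
  out$times <- traj$times[keep]
  out$frame_interval <- traj$frame_interval * stride
  out
}

# Heavy atoms = everything except hydrogen.
.heavy_ids <- function(traj, ids = traj$atoms$atom_id) {
  ids[traj$atoms$element[.ai(ids)] != "H"]
}
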