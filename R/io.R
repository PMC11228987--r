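# Topology / trajectory ingestion and the package plain-text frame format.

# Covalent radii (angstrom) for the fallback distance-based bond inference.
.COV_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05,
                 K = 2.03)

#' Load a trajectory from standard files
#'
#' Reads a topology (PDB with atom/residue names, optionally a PSF for
#' explicit bonds) and a coordinate source: a DCD trajectory, the package's
#' plain-text frame format (see [write_frames()]), or the PDB itself as a
#' single frame.  Bonds are taken from the PSF when given; otherwise they are
#' inferred with a covalent-radius heuristic (sum of radii + 0.4 angstrom)
#' and a message notes the fallback.  Atom role flags are assigned from
#' naming conventions by [assign_roles()].
#'
#' @param topology_path PDB file (atom records); required.
#' @param trajectory_path DCD file, plain-text `.frames` file, or `NULL` to
#'   use the PDB coordinates as one frame.
#' @param psf_path optional PSF file supplying explicit bonds.
#' @param frame_interval time between saved frames, ns (DCD and PDB carry no
#'   time axis).
#' @param box box lengths (angstrom) when the source carries none.
#' @param role_config optional role-assignment overrides, see [assign_roles()].
#' @return an `mi_trajectory`.
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL,
                            psf_path = NULL, frame_interval = 1,
                            box = NULL, role_config = NULL) {
  .assert(file.exists(topology_path), "mi_format_error",
          "topology file not found: %s", topology_path)
  pdb <- bio3d::read.pdb(topology_path, verbose = FALSE)
  a <- pdb$atom
  elem <- ifelse(!is.na(a$elesy) & nzchar(trimws(a$elesy)),
                 trimws(a$elesy), .guess_element(a$elety))
  atoms <- atom_table(name = a$elety, element = toupper(elem),
                      resid = a$resno, resname = a$resid,
                      segid = ifelse(is.na(a$segid) | !nzchar(a$segid),
                                     ifelse(is.na(a$chain), "A", a$chain),
                                     a$segid))
  pdb_xyz <- cbind(a$x, a$y, a$z)

  bonds <- NULL
  if (!is.null(psf_path)) bonds <- read_psf_bonds(psf_path, nrow(atoms))

  coords <- NULL; boxes <- NULL
  if (!is.null(trajectory_path)) {
    .assert(file.exists(trajectory_path), "mi_format_error",
            "trajectory file not found: %s", trajectory_path)
    ext <- tolower(tools::file_ext(trajectory_path))
    if (ext == "dcd") {
      trj <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      nat <- ncol(trj) / 3
      .assert(nat == nrow(atoms), "mi_atom_count_mismatch",
              "topology has %d atoms but frames have %d", nrow(atoms), nat)
      nf <- nrow(trj)
      coords <- array(0, c(nat, 3, nf))
      for (f in seq_len(nf))
        coords[, , f] <- matrix(trj[f, ], ncol = 3, byrow = TRUE)
    } else if (ext %in% c("frames", "txt", "miframes")) {
      fr <- read_frames(trajectory_path)
      .assert(dim(fr$coords)[1] == nrow(atoms), "mi_atom_count_mismatch",
              "topology has %d atoms but frames have %d",
              nrow(atoms), dim(fr$coords)[1])
      coords <- fr$coords; boxes <- fr$box
      if (length(fr$times) > 1)
        frame_interval <- fr$times[2] - fr$times[1]
    } else if (ext == "xtc") {
      .stop_mi("mi_format_error",
               "XTC trajectories are not supported; convert to DCD or the plain-text frame format")
    } else {
      .stop_mi("mi_format_error", "unrecognised trajectory format: .%s", ext)
    }
  } else {
    coords <- array(pdb_xyz, c(nrow(atoms), 3, 1))
  }
  if (is.null(boxes)) {
    if (is.null(box)) {
      span <- apply(coords[, , 1, drop = FALSE], 2, function(v) diff(range(v)))
      box <- pmax(span + 10, 10)  # generous box when none recorded
    }
    boxes <- matrix(box, dim(coords)[3], 3, byrow = TRUE)
  }
  traj <- trajectory(atoms, coords, boxes, bonds = if (is.null(bonds))
                       matrix(integer(0), 0, 2) else bonds,
                     frame_interval = frame_interval)
  if (is.null(bonds)) {
    traj$bonds <- infer_bonds(traj)
    message(sprintf("bonds inferred by covalent-radius heuristic (%d bonds)",
                    nrow(traj$bonds)))
  }
  traj$atoms <- assign_roles(traj, config = role_config)
  traj
}

#' Parse bonds from a PSF file
#'
#' Minimal X-PLOR/CHARMM PSF reader covering the `!NBOND` section only; atom
#' serial numbers are converted to 0-based ids.
#'
#' @param path PSF file.
#' @param n_atoms expected atom count (validated against `!NATOM`).
#' @return 2-column integer matrix of 0-based atom-id pairs.
#' @export
read_psf_bonds <- function(path, n_atoms = NULL) {
  lines <- readLines(path, warn = FALSE)
  natom_line <- grep("!NATOM", lines)
  .assert(length(natom_line) == 1, "mi_format_error", "PSF missing !NATOM")
  nat <- as.integer(strsplit(trimws(lines[natom_line]), "\\s+")[[1]][1])
  if (!is.null(n_atoms))
    .assert(nat == n_atoms, "mi_atom_count_mismatch",
            "topology has %d atoms but PSF has %d", n_atoms, nat)
  bond_line <- grep("!NBOND", lines)
  .assert(length(bond_line) == 1, "mi_format_error", "PSF missing !NBOND")
  nbond <- as.integer(strsplit(trimws(lines[bond_line]), "\\s+")[[1]][1])
  vals <- integer(0); i <- bond_line + 1
  while (length(vals) < 2 * nbond && i <= length(lines)) {
    vals <- c(vals, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  .assert(length(vals) >= 2 * nbond, "mi_format_error", "PSF bond list truncated")
  matrix(vals[seq_len(2 * nbond)] - 1L, ncol = 2, byrow = TRUE)
}

#' Infer covalent bonds from geometry
#'
#' Fallback used when no PSF is given: two atoms are bonded when their
#' first-frame distance is below the sum of covalent radii plus 0.4 angstrom.
#' Search is restricted to atoms of the same residue plus consecutive
#' residues of one segment, which covers polymer connectivity.
#'
#' @param traj an `mi_trajectory`.
#' @param slack added to the radius sum, angstrom.
#' @return 2-column matrix of 0-based atom-id pairs.
#' @export
infer_bonds <- function(traj, slack = 0.4) {
  at <- traj$atoms
  xyz <- frame_coords(traj, 0)
  rad <- .COV_RADIUS[at$element]
  rad[is.na(rad)] <- 0.77
  out <- vector("list", 64); k <- 0
  grp <- split(seq_len(nrow(at)), paste(at$segid, at$resid))
  key <- names(grp)
  # candidate atom pools: residue plus its successor in the same segment
  seg <- sub(" [^ ]+$", "", key); rid <- as.integer(sub("^.* ", "", key))
  for (g in seq_along(grp)) {
    nxt <- which(seg == seg[g] & rid == rid[g] + 1L)
    pool <- c(grp[[g]], if (length(nxt)) grp[[nxt[1]]])
    rows <- grp[[g]]
    for (i in rows) {
      js <- pool[pool > i]
      if (!length(js)) next
      d <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
      hit <- js[d <= rad[i] + rad[js] + slack]
      if (length(hit)) {
        k <- k + 1
        out[[k]] <- cbind(at$atom_id[i], at$atom_id[hit])
      }
    }
  }
  if (k == 0) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, out[seq_len(k)])
  matrix(as.integer(m), ncol = 2)
}

#' Write / read the package plain-text frame format
#'
#' A human-readable trajectory format used for synthetic fixtures:
#' a header line `MIFRAMES 1`, a line `NATOMS <n>`, then per frame a line
#' `FRAME <time_ns> <Lx> <Ly> <Lz>` followed by `n` lines
#' `<atom_id> <x> <y> <z>` (angstrom, 0-based ids, `%.4f` precision).
#'
#' @param traj an `mi_trajectory`.
#' @param path output / input file.
#' @return `write_frames`: the path, invisibly.  `read_frames`: a list with
#'   `coords` (N x 3 x F array), `box` (F x 3), `times` (ns).
#' @export
write_frames <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  nat <- n_atoms(traj)
  writeLines(c("MIFRAMES 1", paste("NATOMS", nat)), con)
  ids <- traj$atoms$atom_id
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("FRAME %.6f %.4f %.4f %.4f", traj$times[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    xyz <- traj$coords[, , f]
    writeLines(sprintf("%d %.4f %.4f %.4f", ids, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  .assert(length(lines) >= 2 && grepl("^MIFRAMES", lines[1]), "mi_format_error",
          "not a MIFRAMES file: %s", path)
  nat <- as.integer(strsplit(lines[2], "\\s+")[[1]][2])
  body <- lines[-(1:2)]
  per <- nat + 1L
  .assert(length(body) %% per == 0, "mi_format_error",
          "truncated frame block in %s", path)
  nf <- length(body) %/% per
  coords <- array(NA_real_, c(nat, 3, nf))
  box <- matrix(NA_real_, nf, 3); times <- numeric(nf)
  for (f in seq_len(nf)) {
    blk <- body[((f - 1L) * per + 1L):(f * per)]
    hdr <- as.numeric(strsplit(blk[1], "\\s+")[[1]][-1])
    times[f] <- hdr[1]; box[f, ] <- hdr[2:4]
    m <- matrix(scan(text = blk[-1], quiet = TRUE), ncol = 4, byrow = TRUE)
    .assert(nrow(m) == nat, "mi_atom_count_mismatch",
            "frame %d has %d atoms, expected %d", f - 1L, nrow(m), nat)
    coords[m[, 1] + 1L, , f] <- m[, 2:4]
  }
  list(coords = coords, box = box, times = times)
}

#' Write a minimal PDB topology for a trajectory
#'
#' Exports atom/residue/segment identity plus first-frame coordinates so that
#' synthetic systems round-trip through [load_trajectory()].
#'
#' @param traj an `mi_trajectory`.
#' @param path output PDB path.
#' @param frame 0-based frame to export.
#' @return the path, invisibly.
#' @export
write_topology_pdb <- function(traj, path, frame = 0) {
  at <- traj$atoms
  xyz <- frame_coords(traj, frame)
  # fixed-width ATOM records (columns per the PDB spec, 4-character residue
  # names in 18-21, chain 22, segid 73-76, element 77-78)
  name4 <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
    (at$atom_id %% 99999L) + 1L, name4, at$resname,
    substr(at$segid, 1, 1), at$resid %% 10000L,
    xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$segid, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
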