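# Independent brute-force oracles and toy-system builders used across the
# suite.  The oracles deliberately share no code with the package: distances
# enumerate the nine in-plane periodic images, detectors loop frame by frame
# over all pairs, and persistence is a hand-rolled run scan.

# minimum-image distance by exhaustive 9-image enumeration (x, y wrapped)
oracle_min_image <- function(p1, p2, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) {
    d <- p2 + c(ix * box[1], iy * box[2], 0) - p1
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# manual run scan: 0-based windows of runs of TRUE with length >= min_len
oracle_runs <- function(x, min_len) {
  out <- NULL; start <- NA
  for (i in seq_along(x)) {
    if (x[i] && is.na(start)) start <- i
    if ((!x[i] || i == length(x)) && !is.na(start)) {
      end <- if (x[i]) i else i - 1
      if (end - start + 1 >= min_len)
        out <- rbind(out, c(start - 1, end - 1))
      start <- NA
    }
  }
  out
}

# same-residue / 1-2 / 1-3 exclusion, recomputed from scratch
oracle_excluded <- function(traj, i, j) {
  at <- traj$atoms
  if (at$segid[i] == at$segid[j] && at$resid[i] == at$resid[j]) return(TRUE)
  b <- traj$bonds + 1
  bonded <- function(a, b2) any((b[, 1] == a & b[, 2] == b2) |
                                  (b[, 1] == b2 & b[, 2] == a))
  if (bonded(i, j)) return(TRUE)
  for (k in seq_len(nrow(at)))
    if (bonded(i, k) && bonded(k, j)) return(TRUE)
  FALSE
}

# frame-by-frame brute-force hydrophobic detector + run-length filter;
# returns a sorted key set "i,j:start:end" (0-based atom ids)
oracle_hydrophobic <- function(traj, cutoff = 3, min_len = 2) {
  cand <- which(traj$atoms$hydrophobic_candidate)
  nf <- dim(traj$coords)[3]
  keys <- character(0)
  for (a in seq_along(cand)) for (b in seq_len(a - 1)) {
    i <- cand[a]; j <- cand[b]
    if (oracle_excluded(traj, i, j)) next
    hit <- logical(nf)
    for (f in seq_len(nf))
      hit[f] <- oracle_min_image(traj$coords[i, , f], traj$coords[j, , f],
                                 traj$box[f, ]) <= cutoff + 1e-9
    runs <- oracle_runs(hit, min_len)
    if (!is.null(runs))
      keys <- c(keys, sprintf("%d,%d:%d:%d", min(i, j) - 1, max(i, j) - 1,
                              runs[, 1], runs[, 2]))
  }
  sort(keys)
}

oracle_hbond <- function(traj, d_ha = 2.4, angle_min = 130, min_len = 2) {
  at <- traj$atoms
  hs <- which(at$hbond_hydrogen); as_ <- which(at$hbond_acceptor)
  b <- traj$bonds + 1
  nf <- dim(traj$coords)[3]
  keys <- character(0)
  for (h in hs) {
    nb <- c(b[b[, 1] == h, 2], b[b[, 2] == h, 1])
    d <- nb[at$element[nb] %in% c("N", "O", "S")][1]
    for (a in as_) {
      if (a == d) next
      if (at$segid[a] == at$segid[d] && at$resid[a] == at$resid[d]) next
      hit <- logical(nf)
      for (f in seq_len(nf)) {
        dist <- oracle_min_image(traj$coords[h, , f], traj$coords[a, , f],
                                 traj$box[f, ])
        # angle via raw vectors (toy systems keep triples un-wrapped)
        v1 <- traj$coords[d, , f] - traj$coords[h, , f]
        v2 <- traj$coords[a, , f] - traj$coords[h, , f]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        hit[f] <- dist <= d_ha + 1e-9 && ang >= angle_min - 1e-9
      }
      runs <- oracle_runs(hit, min_len)
      if (!is.null(runs))
        keys <- c(keys, sprintf("%d,%d,%d:%d:%d", d - 1, h - 1, a - 1,
                                runs[, 1], runs[, 2]))
    }
  }
  sort(keys)
}

oracle_cation_pi <- function(traj, cutoff = 7, min_len = 2) {
  at <- traj$atoms
  rr <- which(at$aromatic_ring_member)
  rings <- split(rr, paste(at$segid[rr], at$resid[rr]))
  ns <- which(at$choline_nitrogen)
  nf <- dim(traj$coords)[3]
  keys <- character(0)
  for (rg in rings) for (n in ns) {
    hit <- logical(nf)
    for (f in seq_len(nf)) {
      ok <- TRUE
      for (i in rg)
        if (oracle_min_image(traj$coords[i, , f], traj$coords[n, , f],
                             traj$box[f, ]) >= cutoff) { ok <- FALSE; break }
      hit[f] <- ok
    }
    runs <- oracle_runs(hit, min_len)
    if (!is.null(runs))
      keys <- c(keys, sprintf("%s:%d:%d:%d",
                              paste(sort(rg) - 1, collapse = ","), n - 1,
                              runs[, 1], runs[, 2]))
  }
  sort(keys)
}

# package events -> comparable key sets
event_keys_hydrophobic <- function(ev)
  sort(sprintf("%s:%d:%d", ev$atom_ids, ev$start, ev$end))
event_keys_hbond <- event_keys_hydrophobic
event_keys_cation_pi <- function(ev)
  sort(sprintf("%s:%d:%d", ev$atom_ids, ev$start, ev$end))

# random toy system exercising all three detectors: random-walk coordinates
# so criteria toggle on and off across frames
random_toy_system <- function(seed, n_frames = 25) {
  set.seed(seed)
  atoms <- NULL; bonds <- NULL; base <- NULL
  add_res <- function(resid, names, elements, xyz, flags = list(),
                      res_bonds = NULL, segid = "X") {
    off <- if (is.null(atoms)) 0 else nrow(atoms)
    df <- do.call(atom_table,
                  c(list(name = names, element = elements, resid = resid,
                         resname = "TOY", segid = segid), flags))
    df$atom_id <- df$atom_id + off
    atoms <<- rbind(atoms, df)
    base <<- rbind(base, xyz)
    if (!is.null(res_bonds)) bonds <<- rbind(bonds, res_bonds + off)
  }
  ru <- function(n) cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10))
  for (r in 1:8)   # apolar 3-carbon chains
    add_res(r, c("CX1", "CX2", "CX3"), "C",
            ru(1)[rep(1, 3), ] + rbind(c(0, 0, 0), c(1.2, 0, 0), c(2.4, 0, 0)),
            flags = list(hydrophobic_candidate = TRUE),
            res_bonds = rbind(c(0, 1), c(1, 2)))
  for (r in 9:10) { # hydroxyl donors
    o <- ru(1)
    add_res(r, c("OD", "HD"), c("O", "H"),
            rbind(o, o + c(0, 0, 1)),
            flags = list(hbond_donor_heavy = c(TRUE, FALSE),
                         hbond_hydrogen = c(FALSE, TRUE),
                         hbond_acceptor = c(TRUE, FALSE)),
            res_bonds = rbind(c(0, 1)))
  }
  for (r in 11:14) # lone acceptors
    add_res(r, "OA", "O", ru(1), flags = list(hbond_acceptor = TRUE))
  th <- seq(0, 2 * pi, length.out = 7)[-7]  # aromatic 6-ring
  add_res(15, paste0("CR", 1:6), "C",
          sweep(cbind(1.4 * cos(th), 1.4 * sin(th), 0), 2, ru(1)[1, ], "+"),
          flags = list(aromatic_ring_member = TRUE),
          res_bonds = cbind(0:5, c(1:5, 0)))
  for (r in 16:17) # choline nitrogens
    add_res(r, "NC", "N", ru(1), flags = list(choline_nitrogen = TRUE))

  n <- nrow(atoms)
  coords <- array(0, c(n, 3, n_frames))
  coords[, , 1] <- base
  if (n_frames > 1)
    for (f in 2:n_frames)
      coords[, , f] <- coords[, , f - 1] + matrix(rnorm(n * 3, 0, 0.8), n, 3)
  trajectory(atoms, coords, c(20, 20, 100),
             bonds = if (is.null(bonds)) matrix(integer(0), 0, 2) else bonds,
             frame_interval = 1)
}

# trajectory from an explicit list of coordinate matrices
make_traj <- function(atoms, frames, box = c(50, 50, 100), bonds = NULL,
                      frame_interval = 1) {
  coords <- array(0, c(nrow(atoms), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectory(atoms, coords, box,
             bonds = if (is.null(bonds)) matrix(integer(0), 0, 2) else bonds,
             frame_interval = frame_interval)
}

# D-H...A triple with exact distance / angle geometry: D at origin,
# H at (0,0,1), A at the requested H-A distance and D-H-A angle
hbond_triple_traj <- function(d_ha, angle_deg, n_frames = 5) {
  atoms <- atom_table(name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
                      resid = c(1, 1, 2), resname = "TOY", segid = "X",
                      hbond_donor_heavy = c(TRUE, FALSE, FALSE),
                      hbond_hydrogen = c(FALSE, TRUE, FALSE),
                      hbond_acceptor = c(FALSE, FALSE, TRUE))
  th <- angle_deg * pi / 180
  H <- c(0, 0, 1)
  A <- H + d_ha * c(sin(th), 0, -cos(th))
  xyz <- rbind(c(0, 0, 0), H, A)
  make_traj(atoms, rep(list(xyz), n_frames), bonds = rbind(c(0, 1)))
}

full_scenario_config <- function(seed, noise_sigma, n_replicas = 1) {
  run_config(seed = seed, scenario = list(
    n_lipids_per_leaflet = 16, n_frames = 200, frame_interval = 1,
    noise_sigma = noise_sigma, n_replicas = n_replicas,
    events = list(list(kind = "binding", start = 20, end = 199),
                  list(kind = "gate_open", start = 60, end = 119),
                  list(kind = "contact_on", start = 70, end = 129),
                  list(kind = "hbond_on", start = 80, end = 139),
                  list(kind = "snorkel", start = 100, end = 159),
                  list(kind = "tail_insertion", start = 110, end = 189),
                  list(kind = "contact_off", start = 140, end = 199),
                  list(kind = "hbond_off", start = 150, end = 199))))
}
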