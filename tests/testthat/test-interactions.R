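# planted two-carbon system: within `near` distance over the given frames,
# far apart elsewhere
planted_pair_traj <- function(n_frames, near_frames, near = 2.8, far = 8) {
  atoms <- atom_table(name = c("CX", "CY"), element = "C", resid = 1:2,
                      resname = "TOY", segid = "X",
                      hydrophobic_candidate = TRUE)
  frames <- lapply(seq_len(n_frames) - 1L, function(f) {
    d <- if (f %in% near_frames) near else far
    rbind(c(0, 0, 0), c(d, 0, 0))
  })
  make_traj(atoms, frames)
}

test_that("hydrophobic events are maximal runs surviving the two-frame rule", {
  traj <- planted_pair_traj(30, 10:20)
  ev <- detect_hydrophobic(traj)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(10, 20))
  expect_equal(ev$key1, "X:TOY1")
  expect_equal(ev$key2, "X:TOY2")
  # a single-frame contact does not count
  expect_equal(nrow(detect_hydrophobic(planted_pair_traj(30, 15))), 0)
  # ... unless persistence is relaxed to the frame-wise criterion
  ev1 <- detect_hydrophobic(planted_pair_traj(30, 15), min_consecutive = 1)
  expect_equal(c(ev1$start, ev1$end), c(15, 15))
  # two separated runs stay two events
  ev2 <- detect_hydrophobic(planted_pair_traj(30, c(2:5, 9:12)))
  expect_equal(ev2$start, c(2, 9))
  expect_equal(ev2$end, c(5, 12))
})

test_that("bonded, 1-3 connected and intra-residue pairs are never contacts", {
  atoms <- atom_table(name = c("CA1", "CB1", "CC1", "CD2"), element = "C",
                      resid = c(1, 1, 2, 3), resname = "TOY", segid = "X",
                      hydrophobic_candidate = TRUE)
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0), c(4.5, 0, 0))
  traj <- make_traj(atoms, rep(list(xyz), 3),
                    bonds = rbind(c(0, 1), c(1, 2), c(2, 3)))
  ev <- detect_hydrophobic(traj, cutoff = 5)
  # 0-1 intra-residue & bonded; 1-2 bonded; 0-2 1-3; 2-3 bonded; 1-3 1-3;
  # only 0-3 (4.5 A apart, unbonded, different residues) survives
  expect_equal(nrow(ev), 1)
  expect_equal(ev$atom_ids, "0,3")
})

test_that("hydrogen bonds require both criteria, inclusive at the boundary", {
  accept <- list(c(2.4, 130), c(1.9, 165), c(2.4, 178), c(1.0, 130))
  reject <- list(c(2.41, 130), c(2.4, 129.9), c(2.5, 170), c(1.9, 120),
                 c(3.0, 90))
  for (g in accept) {
    ev <- detect_hbonds(hbond_triple_traj(g[1], g[2], n_frames = 20))
    expect_equal(nrow(ev), 1, info = sprintf("%.2f A %.1f deg", g[1], g[2]))
    expect_equal(c(ev$start, ev$end), c(0, 19))
  }
  for (g in reject)
    expect_equal(nrow(detect_hbonds(hbond_triple_traj(g[1], g[2]))), 0,
                 info = sprintf("%.2f A %.1f deg", g[1], g[2]))
})

test_that("hydrogens without a bonded donor raise a topology error", {
  traj <- hbond_triple_traj(1.9, 165)
  traj$bonds <- matrix(integer(0), 0, 2)
  expect_error(detect_hbonds(traj), class = "mi_topology_error")
})

test_that("cation-pi needs every ring atom inside the cutoff", {
  ring_n_traj <- function(n_pos) {
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    ring <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
    atoms <- atom_table(name = c(paste0("CR", 1:6), "NC"),
                        element = c(rep("C", 6), "N"),
                        resid = c(rep(1, 6), 2), resname = "TOY", segid = "X",
                        aromatic_ring_member = c(rep(TRUE, 6), FALSE),
                        choline_nitrogen = c(rep(FALSE, 6), TRUE))
    make_traj(atoms, rep(list(rbind(ring, n_pos)), 4))
  }
  # 4 A above the centroid: every ring atom within sqrt(16 + 1.96) < 7
  ev <- detect_cation_pi(ring_n_traj(c(0, 0, 4)))
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(0, 3))
  # N placed so exactly one ring atom exceeds 7 A: ring atom at (-1.4, 0, 0),
  # N at (5.81, 0, 0): near side within 7, far side at 7.21
  expect_equal(nrow(detect_cation_pi(ring_n_traj(c(5.81, 0, 0)))), 0)
  # wrong ring size is a topology error
  expect_error(detect_cation_pi(ring_n_traj(c(0, 0, 4)),
                                rings = list(0:3), cations = 6L),
               class = "mi_topology_error")
})

test_that("grid scan of N positions reproduces the max-distance criterion", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  atoms <- atom_table(name = c(paste0("CR", 1:6), "NC"),
                      element = c(rep("C", 6), "N"),
                      resid = c(rep(1, 6), 2), resname = "TOY", segid = "X",
                      aromatic_ring_member = c(rep(TRUE, 6), FALSE),
                      choline_nitrogen = c(rep(FALSE, 6), TRUE))
  for (x in seq(3, 9, by = 0.75)) for (z in c(0, 3, 6)) {
    traj <- make_traj(atoms, rep(list(rbind(ring, c(x, 0, z))), 2))
    expected <- max(sqrt(colSums((t(ring) - c(x, 0, z))^2))) < 7
    expect_equal(nrow(detect_cation_pi(traj)) == 1, expected,
                 info = sprintf("x=%g z=%g", x, z))
  }
})

test_that("raising the cutoff only ever enlarges the frame-wise event set", {
  for (sd in c(2, 5)) {
    traj <- random_toy_system(seed = sd, n_frames = 20)
    frames_of <- function(ev) {
      if (!nrow(ev)) return(character(0))
      unlist(lapply(seq_len(nrow(ev)), function(r)
        sprintf("%s@%d", ev$atom_ids[r], ev$start[r]:ev$end[r])))
    }
    small <- frames_of(detect_hydrophobic(traj, cutoff = 3,
                                          min_consecutive = 1))
    big <- frames_of(detect_hydrophobic(traj, cutoff = 4.5,
                                        min_consecutive = 1))
    expect_true(all(small %in% big))
  }
})

test_that("replica consensus keeps only interactions present in all replicas", {
  inv <- function(keys, occ) data.frame(
    kind = "hydrophobic", key1 = keys, key2 = "MEMB:TOYL1",
    occupancy = occ, n_events = 1L, mean_duration = 1, max_duration = 1,
    stringsAsFactors = FALSE)
  a <- inv(c("PROT:TRP473", "PROT:ALA565"), c(0.8, 0.2))
  b <- inv(c("PROT:TRP473", "PROT:PRO564"), c(0.6, 0.9))
  cons <- replica_consensus(list(a, b))
  expect_equal(cons$key1, "PROT:TRP473")      # 2/2 kept, 1/2 dropped
  expect_equal(cons$occ_1, 0.8)
  expect_equal(cons$occ_2, 0.6)
  expect_equal(cons$min_occupancy, 0.6)
  single <- replica_consensus(list(a))
  expect_equal(single$key1, a$key1)           # single replica: identity
  expect_equal(single$occ_1, a$occupancy)
  expect_error(replica_consensus(list(a, data.frame(x = 1))),
               class = "mi_replica_error")
})

test_that("occupancy inventories integrate event windows correctly", {
  traj <- planted_pair_traj(40, c(0:9, 20:29))
  ev <- detect_hydrophobic(traj)
  inv <- interaction_inventory(ev, 40, frame_interval = 2)
  expect_equal(inv$occupancy, 0.5)
  expect_equal(inv$n_events, 2L)
  expect_equal(inv$mean_duration, 20)    # 10 frames x 2 ns
  expect_equal(inv$max_duration, 20)
  half <- interaction_inventory(ev, 40, window = frame_window(0, 9))
  expect_equal(half$occupancy, 1.0)
})

test_that("windowed contact series equal a per-frame recount oracle", {
  traj <- planted_pair_traj(40, 0:19)
  ev <- detect_hydrophobic(traj)
  ws <- windowed_contact_series(ev, 40, frame_interval = 1, window_width = 10)
  expect_equal(ws$mean_contacts, c(1, 1, 0, 0))
  ws5 <- windowed_contact_series(ev, 40, frame_interval = 1, window_width = 8)
  expect_equal(ws5$mean_contacts, c(1, 1, 0.5, 0, 0))
  # multi-event recount on a random system
  traj <- random_toy_system(seed = 17, n_frames = 24)
  ev <- detect_hydrophobic(traj, min_consecutive = 1)
  per_frame <- numeric(24)
  if (nrow(ev)) {
    pair_key <- paste(ev$key1, ev$key2)
    for (k in unique(pair_key)) {
      m <- logical(24)
      for (r in which(pair_key == k))
        m[(ev$start[r]:ev$end[r]) + 1] <- TRUE
      per_frame <- per_frame + m
    }
  }
  ws <- windowed_contact_series(ev, 24, frame_interval = 1, window_width = 6)
  expect_equal(ws$mean_contacts,
               as.numeric(tapply(per_frame, rep(0:3, each = 6), mean)))
  expect_error(windowed_contact_series(ev, 24, frame_interval = 1,
                                       window_width = 2.5),
               class = "mi_config_error")
})
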