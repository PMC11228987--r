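test_that("binding detection finds the first sustained-contact frame", {
  spec <- scenario_spec(n_lipids_per_leaflet = 16, n_frames = 100, seed = 2,
                        events = list(scenario_event("binding", 50, 99)))
  traj <- build_scenario(spec)$replicas$replicas[[1]]
  expect_equal(detect_binding_event(traj, cutoff = 4, dwell = 10), 50L)
  # a transient touch shorter than the dwell is not binding
  spec2 <- scenario_spec(n_lipids_per_leaflet = 16, n_frames = 100, seed = 2,
                         events = list(scenario_event("binding", 50, 51)))
  traj2 <- build_scenario(spec2)$replicas$replicas[[1]]
  expect_true(is.na(detect_binding_event(traj2, cutoff = 4, dwell = 10)))
  # a dwell below the frame interval is ill-posed
  expect_error(detect_binding_event(traj, dwell = 0.5),
               class = "mi_config_error")
})

test_that("binding frame is monotone non-increasing in the cutoff", {
  spec <- scenario_spec(n_lipids_per_leaflet = 16, n_frames = 80, seed = 6,
                        noise_sigma = 0.2,
                        events = list(scenario_event("binding", 30, 79)))
  traj <- build_scenario(spec)$replicas$replicas[[1]]
  frames <- vapply(c(3.5, 4, 6, 10, 25),
                   function(cc) detect_binding_event(traj, cutoff = cc,
                                                     dwell = 5), integer(1))
  expect_true(all(diff(frames) <= 0))
})

test_that("insertion depths are signed against the phosphorus plane", {
  scn <- build_scenario(scenario_spec(
    n_lipids_per_leaflet = 16, n_frames = 10, seed = 3,
    events = list(scenario_event("binding", 0, 9))))
  traj <- scn$replicas$replicas[[1]]
  w <- frame_window(0, 9)
  ref <- proximal_bilayer_reference(traj, bound_window = w)
  expect_equal(ref$mean_z, 20)          # engaged (upper) leaflet
  # move the SER476 CB to known heights; GLY470 uses its CA
  at <- traj$atoms
  cb <- which(at$resid == 476 & at$name == "CB" & at$segid == "PROT")
  gly_ca <- which(at$resid == 470 & at$name == "CA" & at$segid == "PROT")
  traj$coords[cb, 3, ] <- 18            # 2 A below the phosphates
  traj$coords[gly_ca, 3, ] <- 21        # 1 A above
  dp <- depth_of_insertion(traj, ref, w)
  expect_equal(dp$depth_mean[dp$resid == 476], -2)
  expect_equal(dp$atom[dp$resid == 470], "CA")
  expect_equal(dp$depth_mean[dp$resid == 470], 1)
  expect_equal(dp$atom[dp$resid == 473], "CB")
  # a residue's CB exactly at the plane has depth zero
  traj$coords[cb, 3, ] <- 20
  expect_equal(depth_of_insertion(traj, ref, w)$depth_mean[dp$resid == 476], 0)
})

test_that("depth profiles are invariant under joint rigid z-translation", {
  scn <- build_scenario(scenario_spec(
    n_lipids_per_leaflet = 16, n_frames = 6, seed = 5, noise_sigma = 0.2,
    events = list(scenario_event("binding", 0, 5))))
  traj <- scn$replicas$replicas[[1]]
  w <- frame_window(0, 5)
  d1 <- depth_of_insertion(traj, proximal_bilayer_reference(traj,
                                                            bound_window = w), w)
  shifted <- traj
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 7.3
  d2 <- depth_of_insertion(shifted,
                           proximal_bilayer_reference(shifted,
                                                      bound_window = w), w)
  expect_equal(d2$depth_mean, d1$depth_mean, tolerance = 1e-9)
})

test_that("the scripted helix axis reports its planted 40 degree tilt", {
  scn <- build_scenario(scenario_spec(
    n_lipids_per_leaflet = 16, n_frames = 8, seed = 1,
    events = list(scenario_event("binding", 0, 7))))
  traj <- scn$replicas$replicas[[1]]
  ca <- function(r) select_atoms(traj, sprintf("resid %d and name CA and protein", r))
  ts <- tilt_series(traj, ca(565), ca(591))
  expect_equal(ts$mean, 40, tolerance = 1e-6)
  expect_equal(ts$sd, 0, tolerance = 1e-9)
})

test_that("density profiles conserve weight and respect slab symmetry", {
  # 100 atoms fixed at z = 0, unit weights: everything in one bin
  atoms <- atom_table(name = sprintf("C%d", 1:100), element = "C",
                      resid = 1:100)
  xyz <- cbind(runif(100, 0, 10), runif(100, 0, 10), 0)
  traj <- make_traj(atoms, rep(list(xyz), 4), box = c(10, 10, 50))
  dp <- density_profile(traj, list(all = atoms$atom_id), bin = 1,
                        weighting = "number", z_range = c(-5, 5))
  expect_equal(sum(dp$mean_weight), 100)
  expect_equal(max(dp$mean_weight), 100)      # single occupied bin
  expect_equal(dp$density[which.max(dp$mean_weight)], 100 / (10 * 10 * 1))
  # integral is conserved exactly under bin refinement
  slab <- build_bilayer_slab(scenario_spec(n_lipids_per_leaflet = 16,
                                           n_frames = 3, noise_sigma = 0.3,
                                           seed = 9))
  ids <- select_atoms(slab, "all")
  for (b in c(2, 1, 0.5)) {
    dp <- density_profile(slab, list(m = ids), bin = b, weighting = "electron",
                          z_range = c(-40, 40))
    expect_equal(sum(dp$mean_weight),
                 sum(membint:::.element_z(slab$atoms$element)),
                 tolerance = 1e-9, info = sprintf("bin=%g", b))
  }
  # noiseless slab is symmetric about the midplane (z0 chosen off the bin
  # edges so mirrored atoms land in mirrored bins)
  slab0 <- build_bilayer_slab(scenario_spec(n_lipids_per_leaflet = 16,
                                            n_frames = 1, noise_sigma = 0,
                                            z0 = 19.77, seed = 1))
  ids <- select_atoms(slab0, "all")
  dp <- density_profile(slab0, list(m = ids), bin = 1, weighting = "mass",
                        z_range = c(-30, 30))
  expect_equal(dp$mean_weight, rev(dp$mean_weight), tolerance = 1e-9)
})

test_that("minimum-distance series match brute force on random systems", {
  traj <- random_toy_system(seed = 23, n_frames = 6)
  ga <- traj$atoms$atom_id[1:12]; gb <- traj$atoms$atom_id[25:40]
  got <- min_distance_series(traj, ga, gb, heavy_only = FALSE)
  for (f in 1:6) {
    brute <- Inf
    for (i in ga) for (j in gb)
      brute <- min(brute, oracle_min_image(traj$coords[i + 1, , f],
                                           traj$coords[j + 1, , f],
                                           traj$box[f, ]))
    expect_equal(got[f], brute)
  }
  # coincident members of disjoint groups give zero
  atoms <- atom_table(name = c("C1", "C2", "C3"), element = "C", resid = 1:3)
  t0 <- make_traj(atoms, list(rbind(c(1, 1, 1), c(1, 1, 1), c(9, 9, 9))))
  expect_equal(min_distance_series(t0, 0L, c(1L, 2L)), 0)
  # planted closest pair
  t1 <- make_traj(atoms, list(rbind(c(0, 0, 0), c(4.2, 0, 0), c(30, 0, 0))))
  expect_equal(min_distance_series(t1, 0L, c(1L, 2L)), 4.2)
})
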