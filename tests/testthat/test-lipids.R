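# slab plus one controllable lipid tail: returns the trajectory and the
# target lipid id (an upper-leaflet lipid)
slab_fixture <- function(n_frames = 20, noise = 0, seed = 1)
  build_bilayer_slab(scenario_spec(n_lipids_per_leaflet = 9,
                                   n_frames = n_frames, noise_sigma = noise,
                                   seed = seed))

test_that("tail tilt angles are unfolded over [0, 180] degrees", {
  traj <- slab_fixture(n_frames = 1)
  # sn-2 points straight down from the glycerol C2: exactly 180 degrees;
  # sn-1 shares the C2 origin but its terminal carbon is offset 1.2 A in x
  expect_equal(tail_tilt_series(traj, 1, "sn2"), 180, tolerance = 1e-9)
  expect_equal(tail_tilt_series(traj, 1, "sn1"),
               acos(-12 / sqrt(12^2 + 1.2^2)) * 180 / pi, tolerance = 1e-9)
  # lower-leaflet mirror: 180 - upper value
  lower <- sort(unique(traj$atoms$resid[assign_leaflets(traj)$lower + 1]))[1]
  expect_equal(tail_tilt_series(traj, lower, "sn2"), 0, tolerance = 1e-9)
  # planted 45 and straight-up vectors on the target lipid
  rows <- membint:::.tail_rows(traj$atoms, 1, "sn2")
  c2 <- traj$coords[rows["c2"], , 1]
  for (ang in c(0, 45, 90, 135)) {
    traj$coords[rows["term"], , 1] <-
      c2 + 10 * c(sin(ang * pi / 180), 0, cos(ang * pi / 180))
    expect_equal(tail_tilt_series(traj, 1, "sn2"), ang, tolerance = 1e-9)
  }
})

test_that("mirrored lower-leaflet tails report 180 minus the upper tilt", {
  traj <- slab_fixture(n_frames = 5, noise = 0.3, seed = 8)
  rows <- membint:::.tail_rows(traj$atoms, 1, "sn2")
  up <- tail_tilt_series(traj, 1, "sn2")
  mirrored <- traj
  mirrored$coords[, 3, ] <- -mirrored$coords[, 3, ]
  expect_equal(tail_tilt_series(mirrored, 1, "sn2"), 180 - up,
               tolerance = 1e-9)
})

test_that("snorkeling uses a strict more-than-1-percent threshold", {
  mk <- function(frac, n = 200) {
    h <- rep(-9, n)                    # deep in the bilayer
    if (frac > 0) h[seq_len(round(frac * n))] <- -4.5   # above plane - 5
    h
  }
  expect_true(classify_snorkeling(mk(0.015))$snorkeling)   # 1.5 percent
  expect_false(classify_snorkeling(mk(0.005))$snorkeling)  # 0.5 percent
  expect_false(classify_snorkeling(mk(0.01))$snorkeling)   # exactly 1 percent
  expect_equal(classify_snorkeling(mk(0.015))$snorkel_fraction, 0.015)
  # lower leaflet mirrors in sign
  expect_true(classify_snorkeling(-mk(0.02), leaflet = "lower")$snorkeling)
})

test_that("snorkel fraction is monotone in the height criterion", {
  set.seed(4)
  h <- runif(500, -12, 2)
  offs <- c(-8, -5, -3, -1)
  fr <- vapply(offs, function(o)
    classify_snorkeling(h, z_offset = o)$snorkel_fraction, numeric(1))
  # a lower bar (more negative offset) admits at least as many frames
  expect_true(all(diff(fr) <= 0))
})

test_that("insertion states follow the 45/150 degree thresholds and dwell", {
  cls <- classify_insertion(rep(30, 12), frame_interval = 2)
  expect_true(all(cls$states == "inserted"))
  expect_equal(cls$longest_inserted_dwell, 24)
  expect_true(all(classify_insertion(rep(160, 5))$states == "bilayer"))
  expect_equal(classify_insertion(c(160, 100, 30))$states,
               c("bilayer", "intermediate", "inserted"))
  # boundary: exactly 45 inserted, exactly 150 bilayer
  expect_equal(classify_insertion(c(45, 150))$states,
               c("inserted", "bilayer"))
  # scripted switch at frame k: dwell is (n_frames - k) * frame_interval
  n <- 40; k <- 12
  tilt <- c(rep(160, k), rep(30, n - k))
  cls <- classify_insertion(tilt, frame_interval = 0.5)
  expect_equal(cls$longest_inserted_dwell, (n - k) * 0.5)
  expect_equal(cls$inserted_fraction, (n - k) / n)
})

test_that("a planted insertion scenario yields the scripted dwell", {
  spec <- scenario_spec(n_lipids_per_leaflet = 16, n_frames = 60, seed = 2,
                        events = list(scenario_event("tail_insertion", 25, 59)))
  scn <- build_scenario(spec)
  traj <- scn$replicas$replicas[[1]]
  lip <- scn$log$lipid[1]
  cls <- classify_insertion(tail_tilt_series(traj, lip, "sn2"),
                            traj$frame_interval)
  expect_equal(cls$longest_inserted_dwell, 35 * traj$frame_interval)
  expect_equal(which(cls$states == "inserted") - 1L, 25:59)
})

test_that("counting deviant lipids under the footprint matches a recount", {
  spec <- scenario_spec(n_lipids_per_leaflet = 16, n_frames = 40, seed = 7,
                        events = list(scenario_event("binding", 0, 39),
                                      scenario_event("snorkel", 0, 39),
                                      scenario_event("tail_insertion", 0, 39)))
  scn <- build_scenario(spec)
  traj <- scn$replicas$replicas[[1]]
  ref <- proximal_bilayer_reference(traj,
                                    bound_window = frame_window(0, 39))
  tab <- lipid_conformation_table(traj, ref)
  deviant <- tab$lipid[tab$classification != "bilayer"]
  expect_setequal(deviant, scn$log$lipid[!is.na(scn$log$lipid)])
  fp <- select_atoms(traj, "protein and resid 473 476 562 564")
  res <- count_lipids_under_gate(traj, fp, deviant, ref$leaflet_ids,
                                 radius = 15)
  # recount oracle: static footprint, so count the qualifying lipids directly
  cen <- colMeans(frame_coords(traj, 0)[fp + 1, 1:2, drop = FALSE])
  pz <- frame_coords(traj, 0)[ref$leaflet_ids + 1, 1:2, drop = FALSE]
  within <- sqrt((pz[, 1] - cen[1])^2 + (pz[, 2] - cen[2])^2) <= 15
  lip_in <- traj$atoms$resid[ref$leaflet_ids + 1][within]
  expect_equal(res$counts, rep(sum(deviant %in% lip_in), 40))
  # no deviant lipids means zero everywhere
  expect_equal(count_lipids_under_gate(traj, fp, integer(0),
                                       ref$leaflet_ids)$mean_count, 0)
})

test_that("three planted deviant lipids under the footprint count as three", {
  spec <- scenario_spec(
    n_lipids_per_leaflet = 16, n_frames = 200, seed = 12,
    events = list(scenario_event("binding", 0, 199),
                  scenario_event("snorkel", 0, 199),
                  scenario_event("tail_insertion", 0, 199),
                  scenario_event("snorkel", 5, 195)))
  # second snorkel overlaps the first in time but targets another lipid
  scn <- build_scenario(spec)
  traj <- scn$replicas$replicas[[1]]
  ref <- proximal_bilayer_reference(traj, bound_window = frame_window(0, 199))
  tab <- lipid_conformation_table(traj, ref)
  deviant <- tab$lipid[tab$classification != "bilayer"]
  expect_length(deviant, 3)
  fp <- select_atoms(traj, "protein and resid 473 476 562 564")
  res <- count_lipids_under_gate(traj, fp, deviant, ref$leaflet_ids,
                                 radius = 15, window = frame_window(10, 190))
  expect_equal(res$mean_count, 3)
})
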