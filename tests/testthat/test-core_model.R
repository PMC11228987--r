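test_that("plain-text frames round-trip through write/read within format precision", {
  spec <- scenario_spec(n_lipids_per_leaflet = 4, n_frames = 5,
                        noise_sigma = 0.3, seed = 7)
  traj <- build_bilayer_slab(spec)
  tf <- tempfile(fileext = ".frames")
  write_frames(traj, tf)
  back <- read_frames(tf)
  expect_equal(dim(back$coords), dim(traj$coords))
  expect_true(max(abs(back$coords - traj$coords)) <= 1e-3)
  expect_equal(back$box, traj$box, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$times, traj$times, tolerance = 1e-6)
})

test_that("a scenario round-trips through PDB topology + frames loading", {
  spec <- scenario_spec(n_lipids_per_leaflet = 4, n_frames = 3, seed = 2)
  traj <- build_bilayer_slab(spec)
  dir <- tempfile(); dir.create(dir)
  pdb <- file.path(dir, "top.pdb"); frm <- file.path(dir, "traj.frames")
  write_topology_pdb(traj, pdb)
  write_frames(traj, frm)
  re <- suppressMessages(load_trajectory(pdb, frm))
  expect_equal(n_atoms(re), n_atoms(traj))
  expect_equal(n_frames(re), 3)
  expect_true(max(abs(re$coords - traj$coords)) <= 1e-3)
  # roles recovered from CHARMM-style names on reload
  expect_equal(select_atoms(re, "flag:phosphorus"),
               select_atoms(traj, "flag:phosphorus"))
  expect_equal(select_atoms(re, "flag:tail_terminal_carbon"),
               select_atoms(traj, "flag:tail_terminal_carbon"))
})

test_that("atom-count mismatches raise structured errors naming both counts", {
  spec <- scenario_spec(n_lipids_per_leaflet = 4, n_frames = 2, seed = 1)
  traj <- build_bilayer_slab(spec)
  dir <- tempfile(); dir.create(dir)
  pdb <- file.path(dir, "top.pdb")
  write_topology_pdb(traj, pdb)
  small <- trajectory(traj$atoms[1:10, ], traj$coords[1:10, , , drop = FALSE],
                      traj$box)
  frm <- file.path(dir, "small.frames")
  write_frames(small, frm)
  err <- tryCatch(suppressMessages(load_trajectory(pdb, frm)),
                  error = function(e) e)
  expect_s3_class(err, "mi_atom_count_mismatch")
  expect_match(conditionMessage(err), as.character(n_atoms(traj)))
  expect_match(conditionMessage(err), "10")
  expect_error(trajectory(traj$atoms, traj$coords[1:10, , , drop = FALSE],
                          traj$box),
               class = "mi_atom_count_mismatch")
})

test_that("selection expressions match a brute-force filter over all atoms", {
  spec <- scenario_spec(n_lipids_per_leaflet = 9, n_frames = 1, seed = 5)
  traj <- build_scenario(spec)$replicas$replicas[[1]]
  at <- traj$atoms
  cases <- list(
    list(expr = "flag:phosphorus", mask = at$phosphorus),
    list(expr = "resname TRP and name CA",
         mask = at$resname == "TRP" & at$name == "CA"),
    list(expr = "segid MEMB and resid 3:7",
         mask = at$segid == "MEMB" & at$resid >= 3 & at$resid <= 7),
    list(expr = "protein and not name CA",
         mask = at$resname %in% c("GLY", "TRP", "SER", "PRO", "ALA", "THR") &
           at$name != "CA"),
    list(expr = "( name P or name N ) and segid MEMB",
         mask = at$name %in% c("P", "N") & at$segid == "MEMB"),
    list(expr = "element O and not lipid",
         mask = at$element == "O" & at$segid != "MEMB"))
  for (cs in cases)
    expect_equal(select_atoms(traj, cs$expr), sort(at$atom_id[cs$mask]),
                 info = cs$expr)
  # no-match selections are empty, not errors
  expect_identical(select_atoms(traj, "resname PHE and name CA"), integer(0))
})

test_that("malformed selections raise parse errors that carry a position", {
  spec <- scenario_spec(n_lipids_per_leaflet = 4, n_frames = 1, seed = 1)
  traj <- build_bilayer_slab(spec)
  for (bad in c("name", "resid CA", "flag:bogus", "(name P", "froop P",
                "name P and"))
    expect_error(select_atoms(traj, bad), class = "mi_parse_error", info = bad)
  err <- tryCatch(select_atoms(traj, "name P and froop"),
                  error = function(e) e)
  expect_match(conditionMessage(err), "position \\d+")
})

test_that("selection is deterministic, sorted and idempotent", {
  spec <- scenario_spec(n_lipids_per_leaflet = 9, n_frames = 1, seed = 5)
  traj <- build_scenario(spec)$replicas$replicas[[1]]
  ids <- select_atoms(traj, "lipid and element C")
  expect_false(is.unsorted(ids))
  sub <- traj$atoms[.subset2(traj$atoms, "atom_id") %in% ids, ]
  expect_identical(select_atoms(sub, "lipid and element C"), ids)
})

test_that("loading with a stride matches striding the full trajectory", {
  spec <- scenario_spec(n_lipids_per_leaflet = 4, n_frames = 12,
                        noise_sigma = 0.2, seed = 3)
  traj <- build_bilayer_slab(spec)
  s3 <- stride_trajectory(traj, 3)
  expect_equal(n_frames(s3), 4)
  expect_equal(s3$coords[, , 2], traj$coords[, , 4])
  expect_equal(s3$frame_interval, 3 * traj$frame_interval)
  expect_identical(stride_trajectory(traj, 1)$coords, traj$coords)
})

test_that("PSF bonds override the covalent-radius fallback", {
  # two atoms 2 A apart: too far for inferred bonds, but listed in the PSF
  atoms <- atom_table(name = c("C1", "C2"), element = "C", resid = 1,
                      resname = "TOY", segid = "X")
  psf <- tempfile(fileext = ".psf")
  writeLines(c("PSF", "", "       2 !NATOM",
               "       1 X    1    TOY  C1   C    0.0  12.011",
               "       2 X    1    TOY  C2   C    0.0  12.011", "",
               "       1 !NBOND: bonds", "       1       2"), psf)
  bonds <- read_psf_bonds(psf, 2)
  expect_equal(bonds, rbind(c(0L, 1L)))
  expect_error(read_psf_bonds(psf, 5), class = "mi_atom_count_mismatch")
})
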