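# membint — protein–membrane interaction analysis for MD trajectories

`membint` quantifies how a peripheral lipid-transfer domain (the motivating
system is a START-like ceramide carrier) engages a bilayer in
molecular-dynamics trajectories.  It is aimed at simulators who have
microsecond trajectories of a protein docked on a membrane and need the
standard battery of interface descriptors as tested, scriptable code rather
than one-off analysis scripts.

## What it computes

**Interaction inventories.**  Hydrophobic contacts (two apolar, non-bonded
atoms of different residues within 3 Å for ≥ 2 consecutive frames),
hydrogen bonds (H···A ≤ 2.4 Å and ∠D–H–A ≥ 130°, ≥ 2 frames) and cation–π
interactions (a choline nitrogen simultaneously < 7 Å from every atom of an
aromatic ring), aggregated to residue/lipid pairs with occupancy,
durations, and a replica-consensus rule that keeps only interactions
present in *all* replicas.

**Membrane-referenced descriptors.**  Binding-event detection (sustained
minimum heavy-atom distance), per-residue depth of insertion — the signed
distance of each Cβ (Cα for glycine) to the time-averaged phosphorus plane
of the engaged leaflet — the tilt of the C-terminal helix axis to the
membrane normal, density profiles along z, and superposition RMSD.

**Per-lipid classification.**  Tail tilt from the C2 → C218/C316 vector,
unfolded on [0°, 180°] (≥ 150° = bilayer, ≤ 45° = inserted in the cavity);
snorkeling when the terminal carbon sits above (plane − 5 Å) for more than
1 % of frames; counts of such perturbed lipids under the protein footprint
versus the opposite-leaflet baseline.

**Gate state.**  The two diagnostic distances (P564↔W473 and S476↔W562
analogues), Gaussian-kernel density estimates of their populations
(Scott's-rule bandwidth), and open/closed segmentation with dwell merging.

A synthetic-trajectory generator plants all of these behaviours as
scripted, logged events (binding, gate opening, bond formation/breakage,
snorkeling, insertion) so every detector is validated against frame-exact
ground truth — no downloaded trajectory needed.

## Worked example

Build a scenario in which a 568-atom toy system binds at frame 20, opens
its gate over frames 60–119, forms a hydrogen bond over 80–139 and snorkels
a lipid tail over 100–159, under 0.2 Å positional noise — then run the full
pipeline and check every planted event is recovered:

```r
library(membint)
cfg <- run_config(seed = 1, scenario = list(
  n_lipids_per_leaflet = 16, n_frames = 200, frame_interval = 1,
  noise_sigma = 0.2, n_replicas = 1,
  events = list(list(kind = "binding",   start = 20,  end = 199),
                list(kind = "gate_open", start = 60,  end = 119),
                list(kind = "hbond_on",  start = 80,  end = 139),
                list(kind = "snorkel",   start = 100, end = 159))))
rep <- run_pipeline(cfg, verbose = TRUE)
#> [load] scenario: 1 replicas, 568 atoms, 200 frames
#> [binding] cutoff=4 A dwell=10 ns -> frame 20
#> [membrane] plane z=20.01 A, tilt 40.0 +/- 0.0 deg, density over [0,199]
#> [interactions] 0 hydrophobic, 1 hbond, 3 cation-pi events (replica 1); 3 consensus pairs
#> [lipids] 1 deviant lipids; mean 1.00 under the gate; 0 deviant in opposite leaflet
#> [gate] open fraction 0.300 at threshold 8.72 A

validate_against_eventlog(rep, rep$scenario_log, tol_frames = 1)
#> <0 rows> (or 0-length row.names)
```

Reading the output: binding is detected exactly at the planted frame 20;
the phosphorus plane of the engaged leaflet sits at 20.01 Å (planted at
20 Å, noise included); the planted 40° helix tilt is recovered; the
hydrogen bond and the persistent cation–π anchors of the two tryptophan
analogues appear in the inventory and survive replica consensus; the
snorkeling lipid is the one deviant lipid under the gate; and the gate is
segmented as open for 30 % of frames — exactly the planted 60/200 — at a
threshold placed by the KDE minimum between the closed (~7 Å) and open
(~15 Å) distance populations.  The empty validation table means every
planted event was recovered within one frame.

Analyses compose equally well outside the pipeline: `detect_hbonds()`,
`depth_of_insertion()`, `tail_tilt_series()`, `segment_states()` and
friends all operate on a plain trajectory object, and
`inst/cli/membint.R` wraps the pipeline for shell use
(`simulate` / `analyze` / `validate` / `report` subcommands).

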