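---
title: "Quantifying protein–membrane engagement in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein–membrane engagement in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membint)
```

## The scientific problem

Lipid-transfer proteins such as the START domain of CERT extract a single
ceramide from a membrane through a transient, peripheral engagement: the
domain docks on the bilayer, two loops flanking its hydrophobic cavity (the
Ω1 and Ω4 "gate") separate, nearby lipid tails leave their usual bilayer
orientation — snorkeling their terminal carbons up toward the head groups or
inserting into the cavity itself — and the cargo is exchanged.  None of
these steps is directly observable in an experiment; they are inferred from
long molecular-dynamics trajectories through a battery of geometric
descriptors.  `membint` implements that battery as a reusable, tested
package:

* **interaction inventories** — hydrophobic contacts, hydrogen bonds and
  cation–π interactions between protein residues and lipids, with
  persistence and replica-consensus rules;
* **membrane-referenced descriptors** — binding-event detection, per-residue
  depth of insertion against the phosphorus plane, helix tilt, density
  profiles along the membrane normal;
* **per-lipid conformational classification** — tail tilt, snorkeling,
  cavity insertion, and counts of perturbed lipids under the protein
  footprint;
* **gate-state quantification** — the two diagnostic inter-residue
  distances, kernel density estimates of their populations, and open/closed
  segmentation.

## Detection criteria and their defaults

All thresholds live in one configuration object (`run_config()`), are
serialised to YAML, and are stamped (via an MD5 hash) into every output
file.  The defaults are the standard printed criteria for this kind of
analysis:

| criterion | default | meaning |
|---|---|---|
| hydrophobic contact | ≤ 3 Å, ≥ 2 consecutive frames | two apolar, non-bonded atoms of different residues |
| hydrogen bond | H···A ≤ 2.4 Å and D–H–A ≥ 130°, ≥ 2 frames | donor resolved through the bond list |
| cation–π | every ring atom < 7 Å from the choline N | simultaneous, strict inequality |
| snorkeling | terminal tail carbon above plane − 5 Å for **more than** 1 % of frames | strict at exactly 1 % |
| tail insertion | tilt ≤ 45° inserted, ≥ 150° bilayer | tilt is *not* folded: the C2→terminal vector direction matters |
| helix tilt | folded to [0°, 90°] | axis orientation is equivalent under reversal |
| binding | min. heavy-atom distance ≤ 4 Å sustained ≥ 10 ns | sustained dwell excludes grazing encounters |
| contact series | 20 ns windows | mean instantaneous contact count per window |
| density profile | trailing 500 ns, 1 Å bins | atomic-number (electron-count) weighting by default |

Persistence is counted in **saved frames** with no gap tolerance: a
single-frame interruption terminates a run.  Because the paper trail of any
analysis depends on the saving stride, `stride_trajectory()` records the
stride and the pipeline logs the thresholds used at every stage.

Two genuinely open choices deserve a note.  First, the set of candidate
atoms for hydrophobic contacts: we default to carbons bonded to no N/O/S/P
plus the sulfurs of Cys/Met — a standard apolarity proxy — and accept a
curated table through the role-assignment config when one is available.
Second, replica consensus can be applied before or after occupancy
statistics; we compute per-replica inventories first and intersect them
(`replica_consensus()`), which keeps the per-replica occupancies available
alongside the consensus list.

## Units and conventions

Ångström, nanosecond, degree, dalton.  Atom ids and frame indices are
0-based; every window is inclusive on both ends.  A run of *k* frames at
interval *dt* lasts *k·dt* ns; this one convention defines binding dwell,
insertion dwell and segmentation minimum dwell.  The membrane normal is +z;
periodic minimum-image wrapping applies in x and y only, which assumes a
slab geometry with the protein never wrapped across z — the standard setup
for peripheral-protein simulations and the reason cross-leaflet artefact
contacts cannot occur.  Leaflets are assigned once, from the first analysis
frame, by the sign of each phosphorus z relative to the midplane; flip-flop
is not tracked at these time scales.  The depth reference is the
phosphorus plane of the protein-proximal leaflet averaged over the bound
window (a per-frame-plane mode exists for sensitivity checks).

## The synthetic generator: what it emulates and what it does not

`build_scenario()` produces a toy slab bilayer (two leaflets of template
lipids on a square grid; each lipid has a choline N with methyls, a
phosphate with two oxygens, glycerol carbons including the C2, and two acyl
tails ending in C218/C316 under CHARMM naming) plus a rigid pseudo-protein
carrying analogues of the residues the analysis keys on: TRP473/SER476
(Ω1), TRP562/PRO564 (Ω4), ALA565–THR591 (the α4 helix axis, planted at
40°), and a glycine to exercise the α-carbon rule.  Scheduled events are
realised geometrically and logged exactly:

* `binding` — the protein occupies its bound pose inside the window, 30 Å
  up the normal outside it;
* `gate_open` — the Ω4 analogues displace so the TRP473–PRO564 distance
  steps from ~7 to ~15 Å;
* `hbond_on`/`hbond_off` — a lipid phosphate oxygen is placed 1.4 Å from
  the SER476 hydroxyl hydrogen at 178°;
* `contact_on`/`contact_off` — a lipid tail carbon is placed 2.0 Å from a
  TRP473 ring carbon;
* `snorkel` — a terminal tail carbon rises to 3 Å below the phosphorus
  plane;
* `tail_insertion` — a tail straightens to a 30° tilt.

The planted geometries deliberately sit far from the detection thresholds
(e.g. 2.0 Å against a 3 Å cutoff, 178° against a 130° minimum) so that the
0.2 Å positional noise used in validation almost never flips a single
frame, and frame-accurate recovery is a property of the detectors rather
than luck.  Noise is applied as a rigid-body Gaussian translation per
molecule (the protein is one rigid body): the generator's purpose is to
validate *detectors*, and rigid-molecule noise isolates their behaviour
from conformational noise while still exercising every distance criterion.
All randomness flows from one integer seed through R's default
Mersenne–Twister generator; the same seed reproduces trajectories and event
logs bit for bit.

What the toy does **not** emulate: force-field physics, realistic lipid
packing or mole fractions, side-chain conformational dynamics, water, and
curvature.  Passing the planted-recovery suite therefore demonstrates that
the detectors measure what they claim on known geometry — not that any
biological conclusion transfers to real trajectories, whose descriptors
must be computed from deposited simulation data.

## Numerical choices

* Distance and angle criteria are boundary-inclusive; comparisons carry a
  1 × 10⁻⁹ Å (and the cosine equivalent) guard so that geometry constructed
  exactly at a printed criterion is accepted regardless of rounding.  The
  cation–π cutoff and the 1 % snorkeling threshold are strict inequalities.
* RMSD uses per-frame least-squares superposition with uniform weights
  (the atom selection already restricts to backbone); `fit = FALSE` returns
  the plain RMSD of already-superposed coordinates, for which local
  displacements obey the closed form √(Σdᵢ²/n) exactly.  Both the
  N-terminus-included and excluded selections are expressible via
  `select_atoms()` ranges.
* The state KDE uses a Gaussian kernel with Scott's-rule bandwidth
  (overridable), renormalised so the trapezoidal grid integral is 1; a
  near-constant sample falls back to a small fixed bandwidth instead of
  failing.  The default open/closed threshold is the density minimum
  between the two largest modes, falling back to the series midrange for
  unimodal data.
* Segmentation merges sub-dwell intervals into their neighbours shortest
  first, so the result always tiles the trajectory with alternating states.
* Bond inference (used only when no PSF is given) bonds atoms within the
  sum of covalent radii + 0.4 Å, searching within a residue and its
  successor; a message records that the fallback ran.

## Problem sizes used in the test suite

The suite validates on systems of a few hundred atoms: random 40-atom
systems over 25 frames for the brute-force oracle comparisons (20 seeds),
and 16-lipid-per-leaflet scenarios (≈570 atoms) over 200 frames for
planted-event recovery, chosen so that an exhaustive O(N²) frame-by-frame
oracle is itself fast enough to trust.  The detectors scale to real systems
by the same code path; only the pair enumeration grows.

## Known limitations

XTC trajectories are not read (DCD, PDB and a documented plain-text frame
format are); triclinic boxes are unsupported; π–π stacking and
water-mediated hydrogen bonds are out of scope (salt bridges appear through
the hydrogen-bond machinery on charged donors/acceptors); electron density
is approximated by atomic-number weighting rather than a true electron
density; and the "under the gate" footprint is a configurable radius
(default 15 Å) around the gate-residue centroid, since a footprint is not
otherwise defined by geometry alone.

## A worked run

```{r pipeline}
cfg <- run_config(seed = 7, scenario = list(
  n_lipids_per_leaflet = 16, n_frames = 200, frame_interval = 1,
  noise_sigma = 0.2, n_replicas = 2,
  events = list(list(kind = "binding", start = 20, end = 199),
                list(kind = "gate_open", start = 60, end = 119),
                list(kind = "hbond_on", start = 80, end = 139),
                list(kind = "snorkel", start = 100, end = 159))))
rep <- run_pipeline(cfg, verbose = TRUE)
str(rep$summary, give.attr = FALSE)
validate_against_eventlog(rep, rep$scenario_log, tol_frames = 1)
```

The empty discrepancy table is the package's acceptance condition: every
planted event recovered within one frame under noise.
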