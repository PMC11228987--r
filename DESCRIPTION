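Package: membint
Title: Protein-Membrane Interaction Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of peripheral membrane protein simulations: persistent
    hydrophobic-contact, hydrogen-bond and cation-pi inventories with
    replica-consensus rules, membrane binding-event detection, per-residue
    insertion depth against the phosphorus plane, protein tilt and density
    profiles, lipid tail tilt / snorkeling / cavity-insertion classification,
    and gate-opening quantification with kernel density estimation of
    conformational states. Includes a synthetic trajectory generator that
    plants scripted events (binding, gate opening, hydrogen bonds, contacts,
    snorkeling, tail insertion) with a ground-truth event log for validating
    every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
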