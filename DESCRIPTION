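Package: helixnet
Title: Helix Geometry and Residue Interaction-Energy Networks for Membrane-Protein Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for seven-transmembrane (7TM) receptor trajectories:
    helix tilt angles against the membrane normal, per-segment no-fit RMSD and
    per-residue RMSF, residue-pairwise interaction-energy decomposition
    (Coulomb, Lennard-Jones and a pairwise generalized-Born polar term with
    OBC-II effective radii), sequence-neighbour exclusion, helix/loop group
    matrices, wildtype-versus-mutant difference networks, significant-residue
    selection, and geometric hydrogen-bond and salt-bridge detection. Includes
    Ballesteros-Weinstein generic numbering, pivot-proline helix splitting,
    in-silico alanine truncation, and a synthetic-data generator (ideal helices,
    7TM bundles, noisy trajectories, planted energy systems) with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
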