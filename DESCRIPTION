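Package: icebindr
Title: Analysis of Ice-Binding Peptide Simulations and Ice Recrystallization Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how short cyclic peptides recognise and bind
    ice. Implements local bond-order (CHILL+-style) classification of water
    molecules into hexagonal ice, cubic ice, interfacial ice, clathrate and
    liquid phases; ice-front tracking and growth-rate estimation in slab
    geometries; solvation-shell census and desolvation-based binding
    detection; disulfide torsion analysis and torsion-hydration coupling;
    hydrogen-bond and residue-pair distance statistics; cysteine C-beta
    chemical-shift redox classification with disulfide-pair inference;
    energy/RMSD conformer-ensemble ranking; and quantification of ice
    recrystallization inhibition from grain label maps. Ships synthetic-system
    generators (proton-disordered ice Ih lattices, liquid boxes, scripted
    growth-and-binding trajectories, conformer ensembles, Voronoi grain maps)
    with known ground truth so every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    bio3d,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
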