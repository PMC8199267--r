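Package: acodock
Title: Ant Colony Optimization for Protein-Ligand Docking and Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for stochastic protein-ligand docking
    driven by ant colony optimization. Ligand degrees of freedom (translation,
    orientation, rotatable-bond torsions) are discretized into intervals; ants
    sample poses with probabilities proportional to per-interval pheromone
    trails, refine them with Nelder-Mead simplex local search, and reinforce
    the trails of good solutions under a MAX-MIN evaporation/deposit scheme.
    Poses are scored with piece-wise linear steric potentials (plp, plp95)
    optionally augmented with angle-dependent hydrogen-bond terms (chemplp),
    a ligand-internal clash penalty, and a Tripos-style torsional potential.
    The package reads and writes Tripos MOL2, converts AutoDock PDBQT ligands
    to MOL2 on the fly, orchestrates hierarchical library screens with
    consensus scoring across docking scenarios, and ships synthetic fixture
    generators (toy receptor-ligand complexes, library hierarchies) together
    with brute-force oracles and a desk-scale parameter-variation benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
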