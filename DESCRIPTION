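Package: hblattice
Title: Directional Cubic-Lattice Protein Model with Explicit Backbone
    Hydrogen Bonds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A coarse-grained cubic-lattice protein model in which every
    residue carries, besides its position and amino-acid type, a side-chain
    direction and a strand/coil secondary-structure state.  Backbone hydrogen
    bonds form between laterally adjacent strand residues with aligned side
    chains, which lets the model capture folding into specific structures,
    amorphous aggregation, and the growth of cross-beta amyloid fibrils.
    The package provides the full potential-energy function, a reversible
    Monte Carlo move set, canonical, parallel-tempering and grand-canonical
    samplers, a composition-biased sequence-design algorithm, trajectory
    observables (heat capacity, native contacts, hydrogen bonds,
    intermolecular contacts), structure fixtures, text/PDB structure export
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
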