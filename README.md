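# hblattice

A cubic-lattice protein model with explicit backbone hydrogen bonds and
directional side chains, for studying how the same physics produces
**specific folding**, **amorphous aggregation** and **cross-beta amyloid
fibrils** — and why all three are so strongly sequence dependent.

Classic lattice models assign each residue only a position and an
amino-acid type, which is enough for folding studies but says nothing
about backbone hydrogen bonding, the interaction behind intermolecular
beta sheets and amyloid fibrils.  Here every residue *i* carries four
variables: type $a_i$, position $\mathbf r_i$ (a self-avoiding walk on
$\mathbb Z^3$), a side-chain direction $\mathbf d_i$ (a lattice unit
vector, never along a backbone bond), and a secondary-structure state
$s_i \in \{\text{coil}, \text{strand}\}$.  The energy is

$$E \;=\; \epsilon_{hb}\sum_{i<j} H_{ij} \;+\; \sum_{i<j} C_{ij}\,D_{ij}\,M_{a_i a_j}
\;+\; \epsilon_s \sum_i S_i \;+\; \sum_i W_i\, M_{sol,a_i} \;+\; \epsilon_{state}\sum_i s_i,$$

where $C_{ij}$ marks lattice contacts, $H_{ij}$ marks hydrogen bonds
(both residues strand, side chains aligned, lateral geometry),
$D_{ij}$ gates pair interactions on side-chain directions (facing or
parallel), $S_i$ penalises consecutive parallel side chains
($\epsilon_s = +55$), and $W_i$ marks solvent-exposed side chains.
Defaults: $\epsilon_{hb} = -50$, $\epsilon_{state} = 0$, $k_B = 1$,
reduced units.  Strand residues are conformationally frozen, so beta
structure trades entropy for hydrogen bonds and favourable side-chain
contacts — which is why only the right sequences form it.

The package provides the energy function with exact incremental
bookkeeping (Rcpp engine), a reversible Monte Carlo move set
(end/corner/crankshaft/rigid moves, state flips, side-chain rotations),
canonical, parallel-tempering and grand-canonical samplers, a
composition-biased fixed-backbone sequence-design algorithm, observables
(heat capacity, native contacts, hydrogen-bond and intermolecular-contact
counts), structure fixtures (compact design targets, idealised cross-beta
seeds, dispersed monomers), text/PDB exporters and a small CLI
(`exec/hblattice`: `fold`, `fibril`, `grow`, `design`, `analyze`).

## Worked example: stability of a cross-beta fibril

```r
library(hblattice)
M <- default_interaction_matrix()

sys <- seed_fibril(10, "TFTFTFT", box = 30)   # in-register 10-strand seed
print(total_energy(sys, M))
#> E = -3950  (hb -2250 | aa -1800 | state 0 | solvent 100 | steric 0; 45 H-bonds)
intermolecular_contact_count(sys)
#> [1] 63

tr <- run_canonical(sys, M, energy_params(),
                    mc_schedule(2e5, sample_interval = 5000, seed = 1),
                    temperature = 18)
print(tr)
#> canonical run at T = 18: 41 samples (final E = -3597, 43 H-bonds)
round(summary(tr), 2)
#>   temperature mean_energy heat_capacity mean_hb mean_contacts mean_external
#> 1          18    -3661.81         75.35   42.29         61.67         61.57
```

The 10-peptide seed holds 45 backbone hydrogen bonds (9 strand
interfaces × 5 internal residues; terminal residues have a single
backbone bond and stay coil) worth −2250, plus −1800 of side-chain
interactions from the phenylalanine core.  At `T = 18` — just below the
folding transition of designed 36-mers under the bundled matrix — the
fibril keeps essentially all of its intermolecular contacts (61.6 of 63
on average) and hydrogen bonds (42.3 of 45).  Running the same scan for
`TTTTTTT`, whose threonine contacts are nearly neutral, dissolves the
fibril at this temperature: hydrogen bonding alone is not strong enough,
which is exactly the sequence dependence the model is built to capture.

Other entry points: `compact_cuboid_structure(3, 3, 4)` +
`design_sequence()` + `run_parallel_tempering()` reproduce the
designed-versus-random folding comparison; `dispersed_peptides()` +
`run_canonical()` probe spontaneous fibril formation;
`run_grand_canonical()` grows a seeded fibril at fixed activity.  The
vignette (`vignettes/hblattice-model.Rmd`) documents the model, the move
set's reversibility argument, the calibration of the bundled interaction
matrix and the scaled-down experiment sizes used in the test suite.

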