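# Example run configuration for the hblattice CLI.
box: 30
periodic: true
temperature: [4, 5.4, 7.3, 9.9, 13.4, 18.1, 24.5, 33.2, 44.9, 60]
n_iterations: 1000000
p_global: 0.2
sample_interval: 2000
swap_interval: 500
seed: 1
matrix: default      # or a path to a 21x21 matrix file
eps_hb: -50
eps_steric: 55
eps_state: 0
hb_strict_perpendicular: true
# grand-canonical extras
activity: 1.0e-9
insertion_attempt_rate: 0.1
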