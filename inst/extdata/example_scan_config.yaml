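# Example scan configuration for fibrilthread.
#
# The bounds_b entries below are ILLUSTRATIVE repeat boundaries for a
# CsgA-like five-repeat protein; they are an example layout only. Repeat
# boundaries differ between organisms and must be supplied by the user for
# the actual protein under study.
template: template.pdb        # path to the fibril template PDB
potential: potential.tsv      # path to the potential table TSV
threshold_cross: -5.0         # calibrated ndope threshold (this potential's scale)
n_models: 10
sigma: 0.3
seed: 1
width: 20                     # sliding-window width for protein A
step: 1                       # window step (1 = finest scan)
bounds_b:                     # explicit fragments (R1..R5) for protein B
- [1, 22]
- [23, 44]
- [45, 66]
- [67, 88]
- [89, 110]
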