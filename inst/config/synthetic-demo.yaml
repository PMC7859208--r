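# Desk-scale synthetic demonstration: simulates the queen-removal study
# design (26 queens + 12 control workers for training, 58 QR individuals)
# at a reduced gene count so the full pipeline runs in about a minute.
# gamma "auto" = 1/p on the standardized matrix, appropriate at this scale.
outdir: results-demo
seed: 1
simulation:
  n_genes: 200
  n_informative: 25
  n_age_genes: 25
kernel: radial
gamma: auto
cost: 32
epsilon: 0.1
k: 3
repeats: 5
stop_size: 60
grid_search: false
filter_threshold: 20
pseudocount: 1
lfc_threshold: 0.5849625007211562  # log2(1.5)
alpha: 0.05
lambda: 0
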