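# Default operating point for transcriptome-scale data (~10^4 genes):
# radial kernel with gamma = 1e-6 and cost C = 2^5, assessed by threefold
# cross-validation repeated 20 times, eliminating down to 100 genes.
# Point to your own count/metadata TSVs with `counts:` and `samples:`.
outdir: results
seed: 1
kernel: radial
gamma: 1.0e-6
cost: 32
epsilon: 0.1
k: 3
repeats: 20
stop_size: 100
grid_search: false
filter_threshold: 20
pseudocount: 1
lfc_threshold: 0.5849625007211562  # log2(1.5)
alpha: 0.05
lambda: 0
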