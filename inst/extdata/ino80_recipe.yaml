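# Deletion-network case study: correlation metric, metric SVD lenses,
# base cover 30 / 3.0x eq., fragmenting cover 45 / 3.0x eq.
mode: deletion
simulate: true
seed: 1
metric: correlation
lens: metric_svd
base:
  resolution: 30
  gain: 3.0
  equalized: true
fragment:
  resolution: 45
  gain: 3.0
  equalized: true
filters:
  min_fold: 4
  log2fc_cutoff: -2
  fdr_cutoff: 0.05
out_dir: ino80_out
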