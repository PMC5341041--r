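# Drug-perturbation case study: norm correlation metric, neighborhood
# lenses, base cover 20 / 3.0x eq., fragmenting cover 30 / 3.0x eq.
# Six treated baits with paired control purifications.
mode: drug
simulate: true
seed: 1
sim:
  baits: [BAIT1, BAIT2, BAIT3, BAIT4, BAIT5, BAIT6]
  perturbations:
    - {name: BAIT1, ablated_modules: M1, depletion_factor: 8}
    - {name: BAIT2, ablated_modules: M1, depletion_factor: 8}
    - {name: BAIT3, ablated_modules: M2, depletion_factor: 8}
    - {name: BAIT4, ablated_modules: M2, depletion_factor: 8}
    - {name: BAIT5, ablated_modules: M3, depletion_factor: 8}
    - {name: BAIT6, ablated_modules: M3, depletion_factor: 8}
  n_replicates: 2
metric: norm_correlation
lens: neighborhood
base:
  resolution: 20
  gain: 3.0
  equalized: true
fragment:
  resolution: 30
  gain: 3.0
  equalized: true
filters:
  z_cutoff: 2
  fdr_cutoff: 0.05
out_dir: sin3_out
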