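# Default end-to-end run on a synthetic cohort matching the study design:
# 1605 cases / 1064 controls, discovery meta-analysis of 7615/7931, nine
# p-value thresholds, clumping at p1 0.5 / p2 0.1 / r2 0.25 / 300 kb.
seed: 1
stages: [simulate, clump, score, prepare, gxe]
simulation:
  n_cases: 1605
  n_controls: 1064
  n_snps: 400
  n_blocks: 40
  n_causal: 100
  or_g: 1.22
  or_e: 1.82
  or_gxe: 1.0
clump:
  p1: 0.5
  p2: 0.1
  r2: 0.25
  kb: 300
plan:
  B: 29
  alpha: 0.05
  m: 10
pcs_k: 2
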