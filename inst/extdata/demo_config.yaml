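# Synthetic demonstration study: height-like variance explained with
# 50 planted deviators, classified by all four methods at two thresholds.
seed: 1
simulation:
  "n": 10000
  m: 200
  target_r2: 0.316
  B: 2000
  plant:
    n_low: 25
    n_high: 25
    shift_sd: 4
methods:
  - method: mahalanobis
    alpha: 0.001
  - method: mahalanobis
    bonferroni: true
  - method: residual
    k: 2
  - method: residual
    k: 3
  - method: grs_rank
    alpha: 0.001
  - method: grs_rank
    alpha: 0.0005
  - method: centile
    k_iqr: 1.5
  - method: centile
    k_iqr: 3
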