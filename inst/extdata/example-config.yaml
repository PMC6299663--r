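# Example run configuration: nonparametric engine on built-in scenario 1
# with fixed DP precision and base distribution.
scenario: 1
design:
  n_total: 60
  m: 3
  c_e: 0.70
  c_d: 0.35
  engine: ncrm
prior:
  alpha: 5
sampler:
  n_burnin: 700
  n_keep: 1000
n_trials: 1000
seed: 1
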