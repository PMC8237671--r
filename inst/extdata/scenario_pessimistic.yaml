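# Demo scenario: voluntary uptake stalls; enforcement is needed to reach the target.
curves:
  voluntary: {family: gaussian_threshold, p0: 0.10, p1: 0.80, mu: 0.50, sigma: 0.15}
  enforced:  {family: gaussian_threshold, p0: 0.05, p1: 0.65, mu: 0.55, sigma: 0.18}
target: 0.6
plan: {capacity: 0.05, horizon: 10000, f0: 0.0}
plot: false
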