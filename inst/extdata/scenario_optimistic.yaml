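# Demo scenario: voluntary uptake alone surpasses the target.
curves:
  voluntary: {family: gaussian_threshold, p0: 0.20, p1: 1.00, mu: 0.35, sigma: 0.18}
  enforced:  {family: gaussian_threshold, p0: 0.10, p1: 0.90, mu: 0.35, sigma: 0.20}
target: 0.5
plan: {capacity: 1.0, horizon: 10000, f0: 0.0}
plot: false
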