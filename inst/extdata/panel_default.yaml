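# Default synthetic-panel configuration: generator defaults, small n for demos.
panel:
  n: 2653
  seed: 1
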