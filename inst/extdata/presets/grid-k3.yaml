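kind: spatial
eta: 0.65
years: 35
grid: {Lx: 4, Ly: 4, h: 0.05}
probes: [[1, 1]]
release:
  mode: initial-only
  layout_k: 3
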