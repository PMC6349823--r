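attractors:
- pos:
  - 0.7
  - 0.18
  strength: 4.0
repellers:
- pos:
  - 0.2
  - 0.7
  strength: 4.0
- pos:
  - 0.55
  - 0.85
  strength: 4.0
- pos:
  - 0.85
  - 0.7
  strength: 4.0
sigma_f: 0.35
force_scale: 1.0
dt: 0.05
damping: 0.0
initial_position:
- 0.65
- 0.15
boundary: slide
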