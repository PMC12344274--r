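hsv:
  lower:
  - 115
  - 29
  - 0
  upper:
  - 221
  - 144
  - 0
blur_size: 15
kernel:
  shape: ellipse
  size:
  - 9
  - 7
min_size:
- 6
- 7
reference_height_mm: 43.2
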