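hsv:
  lower:
  - 117
  - 9
  - 0
  upper:
  - 230
  - 200
  - 0
blur_size: 15
kernel:
  shape: ellipse
  size:
  - 9
  - 7
min_size:
- 15
- 15
reference_height_mm: 43.2
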