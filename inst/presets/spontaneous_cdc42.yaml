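# Spontaneous Cdc42 dynamics: hotspot/protruding sections at 1.061x and
# non-protruding (retracting) sections at 0.938x the stalling level, plus a
# retrograde traveling activity wave (period 110 s) in the interior, sampled
# by a 4 um^2 square ROI. Long record (>10 wave cycles).
name: spontaneous_cdc42
grid: [192, 192]
pixel_size: 0.5
frame_interval: 1.0
n_frames: 1280
seed: 12
noise: true
cell:
  center: [48.0, 48.0]
  radius: 40.0
  n_sections: 24
edge_schedule:
  - {section: 1, velocity: 0.005, start: 0, stop: 1279}
  - {section: 2, velocity: 0.005, start: 0, stop: 1279}
  - {section: 3, velocity: 0.005, start: 0, stop: 1279}
  - {section: 4, velocity: 0.005, start: 0, stop: 1279}
  - {section: 5, velocity: 0.005, start: 0, stop: 1279}
  - {section: 6, velocity: 0.005, start: 0, stop: 1279}
  - {section: 7, velocity: -0.005, start: 0, stop: 1279}
  - {section: 8, velocity: -0.005, start: 0, stop: 1279}
  - {section: 9, velocity: -0.005, start: 0, stop: 1279}
  - {section: 10, velocity: -0.005, start: 0, stop: 1279}
  - {section: 11, velocity: -0.005, start: 0, stop: 1279}
  - {section: 12, velocity: -0.005, start: 0, stop: 1279}
activity:
  baseline: 1.0
  class_bands:
    depth: 5.0
    factors:
      - {section: 1, factor: 1.061}
      - {section: 2, factor: 1.061}
      - {section: 3, factor: 1.061}
      - {section: 4, factor: 1.061}
      - {section: 5, factor: 1.061}
      - {section: 6, factor: 1.061}
      - {section: 7, factor: 0.938}
      - {section: 8, factor: 0.938}
      - {section: 9, factor: 0.938}
      - {section: 10, factor: 0.938}
      - {section: 11, factor: 0.938}
      - {section: 12, factor: 0.938}
  wave:
    period: 110.0
    wavelength: 5.0
    amplitude: 0.2
    direction: [-1.0, 0.0]
    start: 0.0
    region:
      center: [48.0, 48.0]
      radius: 20.0
rois:
  v0: 0.002
  section_rects: true
  rect_width: 10.0
  rect_length: 20.0
  squares:
    - {id: wave, center: [58.0, 48.0]}
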