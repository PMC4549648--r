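# Spontaneous RhoA dynamics: 24 edge sections (6 protruding, 6 retracting,
# 12 stalling); retracting-edge activity 1.109x and protruding 0.831x the
# stalling level in a 5 um band hugging the edge.
name: spontaneous_rhoa
grid: [192, 192]
pixel_size: 0.5
frame_interval: 1.0
n_frames: 300
seed: 11
noise: true
cell:
  center: [48.0, 48.0]
  radius: 40.0
  n_sections: 24
edge_schedule:
  - {section: 1, velocity: 0.02, start: 0, stop: 299}
  - {section: 2, velocity: 0.02, start: 0, stop: 299}
  - {section: 3, velocity: 0.02, start: 0, stop: 299}
  - {section: 4, velocity: 0.02, start: 0, stop: 299}
  - {section: 5, velocity: 0.02, start: 0, stop: 299}
  - {section: 6, velocity: 0.02, start: 0, stop: 299}
  - {section: 7, velocity: -0.02, start: 0, stop: 299}
  - {section: 8, velocity: -0.02, start: 0, stop: 299}
  - {section: 9, velocity: -0.02, start: 0, stop: 299}
  - {section: 10, velocity: -0.02, start: 0, stop: 299}
  - {section: 11, velocity: -0.02, start: 0, stop: 299}
  - {section: 12, velocity: -0.02, start: 0, stop: 299}
activity:
  baseline: 1.0
  class_bands:
    depth: 5.0
    factors:
      - {section: 1, factor: 0.831}
      - {section: 2, factor: 0.831}
      - {section: 3, factor: 0.831}
      - {section: 4, factor: 0.831}
      - {section: 5, factor: 0.831}
      - {section: 6, factor: 0.831}
      - {section: 7, factor: 1.109}
      - {section: 8, factor: 1.109}
      - {section: 9, factor: 1.109}
      - {section: 10, factor: 1.109}
      - {section: 11, factor: 1.109}
      - {section: 12, factor: 1.109}
rois:
  section_rects: true
  rect_width: 10.0
  rect_length: 20.0
  squares:
    - {id: center, center: [48.0, 48.0]}
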