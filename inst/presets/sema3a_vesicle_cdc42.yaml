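# Vesicle-stimulated Cdc42: slow retrograde activity waves (155 s period)
# with retraction of the edge facing the vesicle. Long record (>11 cycles).
name: sema3a_vesicle_cdc42
grid: [96, 96]
pixel_size: 0.5
frame_interval: 1.0
n_frames: 1800
seed: 14
noise: true
cell:
  center: [24.0, 24.0]
  radius: 16.0
  n_sections: 12
edge_schedule:
  - {section: 1, velocity: -0.004, start: 120, stop: 1800}
  - {section: 2, velocity: -0.004, start: 120, stop: 1800}
  - {section: 3, velocity: -0.004, start: 120, stop: 1800}
activity:
  baseline: 1.0
  wave:
    period: 155.0
    wavelength: 5.0
    amplitude: 0.2
    direction: [-1.0, 0.0]
    start: 0.0
    region:
      center: [24.0, 24.0]
      radius: 10.0
rois:
  v0: 0.002
  section_rects: true
  rect_width: 10.0
  rect_length: 20.0
  squares:
    - {id: wave, center: [30.0, 24.0]}
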