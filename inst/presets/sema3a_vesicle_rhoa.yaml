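# Vesicle-stimulated RhoA: activity ramp in the central growth-cone region
# beginning 10 s after the stimulus at t = 60 s, followed by retraction of
# the stimulated edge from 100 s post-stimulus.
name: sema3a_vesicle_rhoa
grid: [96, 96]
pixel_size: 0.5
frame_interval: 1.0
n_frames: 300
seed: 15
noise: true
cell:
  center: [24.0, 24.0]
  radius: 16.0
  n_sections: 12
edge_schedule:
  - {section: 1, velocity: -0.03, start: 160, stop: 299}
  - {section: 2, velocity: -0.03, start: 160, stop: 299}
  - {section: 3, velocity: -0.03, start: 160, stop: 299}
activity:
  baseline: 1.0
stimulus:
  time: 60.0
  center: [24.0, 24.0]
  radius: 5.0
  ramp_rate: 0.02
  ramp_delay: 10.0
  ramp_max: 1.0
rois:
  section_rects: true
  rect_width: 10.0
  rect_length: 20.0
  squares:
    - {id: center, center: [24.0, 24.0]}
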