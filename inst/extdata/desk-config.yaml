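n_subjects: 6.0
protocol:
  plateau_ranges:
  - - 93.0
    - 100.0
  - - 89.0
    - 93.0
  - - 80.0
    - 88.0
  - - 70.0
    - 79.0
  plateau_hold_s: 15.0
  step_interval_s: 55.0
  total_duration_s: 240.0
  transition_time_constant_s: 8.0
  resting_spo2: 98.0
  seed: 1
camera:
  fps: 30.0
  resolution:
  - 176
  - 144
  gains:
  - 1.0
  - 3.0
  - 18.0
  bit_depth: 8
  spatial_noise_sd: 2.0
  max_value: 255.0
window_seconds: 3.0
label_floor: 70.0
model:
  conv_channels:
  - 16
  - 32
  - 64
  conv_kernel: 3
  fc_width: 64
  input_len: 90
  n_colors: 3
train:
  learning_rate: 0.003
  lr_decay_factor: 0.1
  lr_decay_epoch: 80.0
  l2_strength: 0.1
  max_epochs: 25
  batch_size: 64
  upsample_minority: no
  minority_range:
  - 70.0
  - 85.0
  grad_clip: 10.0
  seed: 1
ror:
  eps_hbo2:
  - 319.6
  - 39956.8
  eps_hb:
  - 3226.6
  - 39036.4
  min_beats_per_window: 2.0
  nominal_hr_bpm: 70.0
  dc_scope: beats
thresholds:
- 92.0
- 90.0
- 88.0
boundaries:
- 70.0
- 70.5
- 71.0
- 71.5
- 72.0
- 72.5
- 73.0
- 73.5
- 74.0
- 74.5
- 75.0
- 75.5
- 76.0
- 76.5
- 77.0
- 77.5
- 78.0
- 78.5
- 79.0
- 79.5
- 80.0
- 80.5
- 81.0
- 81.5
- 82.0
- 82.5
- 83.0
- 83.5
- 84.0
- 84.5
- 85.0
- 85.5
- 86.0
- 86.5
- 87.0
- 87.5
- 88.0
- 88.5
- 89.0
- 89.5
- 90.0
- 90.5
- 91.0
- 91.5
- 92.0
- 92.5
- 93.0
- 93.5
- 94.0
- 94.5
- 95.0
- 95.5
- 96.0
- 96.5
- 97.0
- 97.5
- 98.0
- 98.5
- 99.0
- 99.5
- 100.0
floors: ~
reference_noise: no
reference_arms: 2.0
seed: 1
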