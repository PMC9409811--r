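case_id: reference-constant_voltage
seed: 1
pi_value: 3.14
phantom:
  layers:
  - label: 1
    region:
      type: all
  spacing: 1.5
  extent:
    r: 50.0
    z:
    - -50.0
    - 50.0
  fine_window:
    r:
    - 0.0
    - 12.0
    z:
    - -14.0
    - 12.0
  h_fine: 0.25
  growth: 1.2
electrode:
  type: needle
  shaft_diameter: 1.6
  tip_length: 3.0
  tip_position: -1.5
  radius: 1.0
  center: 0.0
  k_metal: 15.0
  rho_metal: 7900.0
  c_metal: 500.0
protocol:
  mode: constant_voltage
  voltage: 34.0
  power_min: 2.0
  power_max: 6.0
  target_temp: 80.0
  target_band: 2.0
  ramp_window:
  - 10.0
  - 15.0
  setpoint_ramp: 10.0
  duration: 90.0
  baseline_temp: 37.0
  frequency: 100000.0
  sensor: electrode
  control_gain: 0.5
  control_interval: 0.5
plan:
  entry:
  - - 0.0
    - 0.0
    - 40.0
  target:
  - - 0.0
    - 0.0
    - 0.0
  n_pullbacks: 5
  pullback_step: 3.0
solver:
  dt: 0.1
  electrode_thermal: auto
imaging:
  voxel_size: 1.0
  contrast: 100.0
  noise_sd: 5.0
  background: 100.0
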