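# Shipped kV-CBCT acquisition protocols (125 kV on-board imager).
# total mAs per acquisition = tube_current_mA x acquisition_time_s x
#                             frame_rate_fps x pulse_duration_s
# thorax: 360 mAs, pelvis: 1440 mAs, fourD: 672 mAs.
thorax:
  n_acquisitions: 1
  tube_current_mA: 20
  acquisition_time_s: 60
  frame_rate_fps: 15
  pulse_duration_s: 0.020
  tube_voltage_kV: 125
  gantry_start_deg: -180
  gantry_stop_deg: 180
  gantry_step_deg: 2
pelvis:
  n_acquisitions: 1
  tube_current_mA: 80
  acquisition_time_s: 60
  frame_rate_fps: 15
  pulse_duration_s: 0.020
  tube_voltage_kV: 125
  gantry_start_deg: -180
  gantry_stop_deg: 180
  gantry_step_deg: 2
fourD:
  n_acquisitions: 1
  tube_current_mA: 40
  acquisition_time_s: 120
  frame_rate_fps: 7
  pulse_duration_s: 0.020
  tube_voltage_kV: 125
  gantry_start_deg: -180
  gantry_stop_deg: 180
  gantry_step_deg: 2
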