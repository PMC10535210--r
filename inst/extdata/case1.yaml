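# Reconstructed crossing case: running pedestrian struck by a sedan.
schema_version: 1
pedestrian:
  stature_m: 1.74
  mass_kg: 68
  speed_mps: 4.5
  heading_deg: 0
vehicle:
  preset: sedan
  speed_mps: 18.5
  angle_deg: 2.7
friction:
  car_ground: 0.7
  ped_ground: 0.6
  car_ped: 0.3
mode: running_dynamic
simulation:
  dt_s: 1.0e-4
  max_time_s: 4.5
  t_lead_s: 0.06
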