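# 5 um polystyrene beads in PBS, 1 ml glass syringe, 10 ul/min
particle:
  radius_um: 5
  density_g_cm3: 1.07
buffer:
  density_g_cm3: 1.00
  viscosity_mPa_s: 1.0
syringe:
  barrel_radius_mm: 2.3
  barrel_length_mm: 40
  outlet_radius_mm: 0.5
  outlet_length_mm: 5
flow:
  rate_ul_min: 10
sim:
  n_particles: 2000
  dt_s: 0.05
  max_time_s: 1200
  seed: 1
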