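# Wild-type-like synthetic colonization scenario: biased DEP accumulation
# (retention ratio ramping to 2.5 over 12 h) with a QS activation front.
scenario: wt_like
seed: 7
geometry:
  domain_size_px: [300, 400]
  pixel_size: 2.6
flow:
  u_m_target: 20.0
tracer:
  t_end_pv: 2.5
  dt: 2.0
biomass:
  n_frames: 13
  interval_s: 3600
  ratio_from: 1.0
  ratio_to: 2.5
  amplitude_max: 400
  noise_sd: 5
reporter:
  front_depth_mm: 0.1
  steepness: 200
model:
  c_B: 0.02
  t_end: 1800
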