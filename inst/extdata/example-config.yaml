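# Example experiment configuration: double-5'SS panel probed with labeled U2.
seed: 1
schedule:
  frame_duration: 1.0
  green_block_length: 100
  red_interleave_length: 1
  total_duration: 2400.0
panel:
  constructs:
    - {name: 5i3e5, upstream_5ss: true,  downstream_5ss: true,  bs_3ss: true, spliceable: true,  count: 100}
    - {name: 5i3eX, upstream_5ss: true,  downstream_5ss: false, bs_3ss: true, spliceable: true,  count: 100}
    - {name: Xi3e5, upstream_5ss: false, downstream_5ss: true,  bs_3ss: true, spliceable: false, count: 100}
    - {name: Xi3eX, upstream_5ss: false, downstream_5ss: false, bs_3ss: true, spliceable: false, count: 100}
  n_controls: 100
  field_size_um: [100.0, 100.0]
  density_bounds: [0, 0.5]
params:
  subcomplex: U2
  k_assoc_specific: 5.0e-4
  dwell_mixture:
    - {weight: 0.7, mean_s: 5.0}
    - {weight: 0.3, mean_s: 60.0}
  k_assoc_nonspecific: 2.0e-4
  nonspecific_mean_dwell: 2.5
  labeling_fraction: 0.6
  bleach_rate: 2.0e-4
  synergy_factor: 3.0
  frac_active: 0.75
analysis:
  duration_threshold_s: 50.0
  bootstrap_B: 2000
  per_second: false
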