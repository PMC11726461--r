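# Example end-to-end run on a simulated flow-chamber time series:
# a lattice-packed hemispherical colony imaged in a constitutive channel
# and a depth-dependent ratiometric reporter, over three timepoints.
seed: 42
scene:
  mode: colony
  fill: lattice
  colony_radius_um: 4.0
  arena_um: [12.0, 12.0, 6.0]
  pitch_um: [0.2, 0.2, 0.5]
  background: 100.0
  amplitude: 300.0
  channels:
    constitutive:
      type: constitutive
    reporter:
      type: reporter
      profile: [1.0, 0.3]
timeseries:
  times: [0.0, 0.5, 1.0]
  growth_rate_um_h: 0.5
roles:
  constitutive: constitutive
  numerator: reporter
  denominator: constitutive
cutoff_um: 3.0
cube_side_um: 1.0
bin_width_um: 1.0
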