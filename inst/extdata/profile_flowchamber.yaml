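# Segmentation profile for flow-chamber confocal acquisitions:
# 63.2 nm xy / 0.5 um z voxels, constitutive-channel segmentation with a
# 5x5x3 voxel mean filter, 5.5 um top-hat disk, 0.2-discounted Otsu
# threshold, and suppression of detached objects below one cell volume.
pitch_um: [0.0632, 0.0632, 0.5]
cutoff_um: 3.0
cube_side_um: 1.0
bin_width_um: 1.0
seg:
  kernel: [5, 5, 3]
  tophat_radius_um: 5.5
  discount: 0.2
  bins: 256
  suppress: true
  min_volume_um3: 1.3
  connectivity: 26
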