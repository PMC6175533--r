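# Versioned defaults for the vesisort pipeline. Editing this file (or a
# copy passed via --config) is the supported way to adapt the classifier
# weights or any other constant to a new dataset.
model:
  features: [r, gv, distAZ, GVSD]
  mu: [10.4, 129.1, 259.1, 5.9]
  sigma: [3.1, 4.7, 118.5, 1.7]
  w: [-1.69, 1.65, -0.76, 1.21]
  b: -4.36
  gv_offset_threshold: .na
features:
  membrane_nm: 4.5
  blur_sigma: 3.45
  gv_polarity: as_stored
criteria:
  min_volume: 300
  max_volume: 300000
  min_sphericity: 0.8
  max_ellipsoid_residual: 0.15
preprocess:
  mean_radius: 3.45
  bilateral_sigma_s: 3
  bilateral_sigma_r: 0.1
analyze:
  bandwidth_factor: 0.07
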