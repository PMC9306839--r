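phantom:
  shape: [191, 191]
  structure_count: 12
  vessel_width_range: [2.0, 5.0]
  intensity_max: 65536.0
  noise_mean: 256.0
  noise_model: scaled-poisson
  angles: [0.0, 90.0]
  max_view_shift: 8
  seed: 0
psf_sigma: [2.7, 1.0]
schedule:
  object_iters: 50
  psf_iters: 50
  cycles: 2000
  checkpoint_every: 50
initial_psf:
  type: gaussian
  sigma: 4.0
rl_iterations: 4000
background_size: 15
output_dir: ''
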