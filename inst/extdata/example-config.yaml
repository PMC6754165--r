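# Example hilomfm configuration: nine focal planes at 0.4 um spacing
# multiplexed onto a 3x3 tile grid, with the central plane carried by the
# unmodulated zero order. Lengths in micrometres.
seed: 1
optics:
  f_fourier: 200000        # Fourier lens focal length (200 mm)
  magnification: 60
  slm_pitch: 8
  slm_shape: [512, 512]
  aperture_radius: 1800
  camera_pitch: 6.5
  camera_shape: [2048, 2048]
plan:
  spacings: [0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4]
  anchor: center
  tile_layout: [3, 3]
  tile_px: 64              # simulation tile size; the instrument uses 501
  zero_order_plane: 5
tiles:
  rows: 3
  cols: 3
  tile_px: 64
hilo:
  lp_sigma: 0.0625         # cycles/pixel; ~1/8 sampling-frequency cutoff
  eta_mode: spectral_norm
gs:
  max_iter: 31
  wavelength: 0.55
acquisition:
  depth: 16
  dz: 0.4
  n_planes: 9
  frames_per_position: 2
  camera_rate: 200
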