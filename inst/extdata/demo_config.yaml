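# Demo run configuration: a hyperechoic (+15 dB) contrast disk at the FUS
# focus inside a speckle background. All units SI (meters, Hz).
# Note: exponents need an explicit sign (YAML 1.1), e.g. 5.0e+06.
probe:
  n_elements: 128
  pitch: 3.048e-04
  f0: 5.0e+06
  fs: 2.0e+07
scene:
  c: 1540
  x_range: [-4.0e-03, 4.0e-03]
  z_range: [2.6e-02, 3.4e-02]
  density_per_cell: 15
  sigma: 1.0
  noise_rms: 0.0
  regions:
    - type: disk
      center: [0.0, 3.0e-02]
      radius: 2.5e-03
      offset_db: 15
recon:
  fus_focus: [0.0, 3.0e-02]
  pw_angles_deg: [-18, -12, -6, 0, 6, 12, 18]
  rx_f_number: 1
  gate_db: -60
  overlay_threshold: -20
run:
  seed: 7
  out_dir: demo_out
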