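# Example experiment configuration: a small 2-cycle sequential run.
# Paths are resolved relative to this file.
task: him_full
sample_name: demo-embryo
save_root: him_output
imaging:
  exposure_ms: 50
  n_planes: 60
  dz_nm: 250
  format: tiff
  channels:
    - {laser_nm: 561, intensity_pct: 30}   # fiducial channel
    - {laser_nm: 640, intensity_pct: 50}   # probe readout channel
roi_file: rois_demo.yml
sequences:
  cycle0: sequence_cycle0.yml
  hybridization: sequence_hybridization.yml
  bleaching: sequence_bleaching.yml
probes:
  - {cycle: 1, name: RT01, tray_slot: [1, 1, 1]}
  - {cycle: 2, name: RT02, tray_slot: [1, 1, 2]}
n_cycles: 2
seed: 42
below_offset_um: 1.5
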