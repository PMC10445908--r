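name: hybridization
steps:
- product: probe           # needle position supplied per cycle from the tray
  valve: 5
  volume_ul: 1500.0
  flow_ul_min: 200.0
  incubation_s: 900.0
- product: wash-buffer
  valve: 3
  volume_ul: 2000.0
  flow_ul_min: 300.0
  incubation_s: 0.0
- product: imaging-buffer
  valve: 6
  volume_ul: 1200.0
  flow_ul_min: 250.0
  incubation_s: 0.0
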