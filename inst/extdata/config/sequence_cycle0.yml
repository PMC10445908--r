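# Cycle-0 injection procedure: nuclear stain plus fiducial probes,
# volumes and flow rates in the usual 1-2 ml at 150-300 ul/min envelope.
name: cycle0
steps:
- product: DAPI-dye
  valve: 2
  volume_ul: 1000.0
  flow_ul_min: 250.0
  incubation_s: 600.0
- product: fiducial-probe
  valve: 5
  volume_ul: 1500.0
  flow_ul_min: 200.0
  incubation_s: 900.0
  tray_slot: [1, 1, 0]
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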