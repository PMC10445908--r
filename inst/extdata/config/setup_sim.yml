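# Example setup configuration: a fully simulated sequential-imaging
# microscope. Devices are declared under a role name and wired to logic
# modules by role; swapping a device model only touches this file.
global:
  field_size_um: 200
  pixel_size_um: 0.1
  seed: 42
  sample:
    n_emitters: 40
    n_probes: 3
    drift_nm_s: 2
    diffusion_nm2_s: 0
devices:
  cam:
    model: sim_camera_emccd
  stage:
    model: sim_stage
  piezo:
    model: sim_piezo
  lasers:
    model: sim_lasers
  qpd:
    model: sim_qpd
    options:
      gain_v_per_um: 0.5
      noise_v: 0.005
  valve:
    model: sim_valve
    options:
      n_ports: 8
  pump:
    model: sim_pump
  flow:
    model: sim_flowsensor
  needle:
    model: sim_needle
logic:
  focus:
    logic: focus_logic
    connect: {qpd: qpd, piezo: piezo, lasers: lasers}
  acquisition:
    logic: acquisition_logic
    connect: {camera: cam, piezo: piezo, lasers: lasers, stage: stage}
  fluidics:
    logic: fluidics_logic
    connect: {pump: pump, valve: valve, flow: flow, needle: needle}
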