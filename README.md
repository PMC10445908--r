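# himsim

Headless acquisition control for sequential multiplexed imaging (Hi-M),
backed entirely by physically modeled simulated hardware.

## The problem

Hi-M and related sequential/combinatorial imaging methods (merFISH,
seqFISH, …) detect hundreds of distinct RNA or DNA species in the same
cells by interleaving rounds of probe **hybridization**, multicolor **3D
image acquisition**, and chemical **bleaching** over a fixed set of stage
positions (ROIs), for 20–60 cycles and several days of unattended
operation. The control software must therefore coordinate a camera, a
laser bank, an XY stage and a z piezo with a liquid-handling robot
(valve positioner, pump, flow sensor, needle stage), keep the sample in
focus against thermal drift, and name and annotate thousands of image
stacks so downstream registration can reassemble them.

`himsim` implements that acquisition-control layer in R — device
abstraction, autofocus and flow-rate PID control, ROI/mosaic planning,
synchronized z-stack acquisition, and a task state machine — with every
hardware interface backed by a **simulated device** that models the
instrument's physical response and elapses on a **virtual clock**. A
multi-hour experiment runs (and is tested) in seconds, deterministically,
from a single seed. The abstract device interfaces are the contract real
vendor drivers would implement; the simulators are selected by model name
in a setup YAML file, so the logic layer never knows the difference.

## The models at the core

- **Autofocus.** A quadrant photodiode reads the reflection of a 785 nm
  infrared laser; near focus its signal is linear in the objective–sample
  distance, `V(z) = g·(z − z_s) + V₀ + ε`. Calibration sweeps a quick 2 µm
  piezo ramp (21 steps), fits signal vs z by least squares, and reports a
  **precision** `RMS(residuals)/|g|` in nm. The calibration is **valid**
  iff the response is monotonic and the precision is below 30 nm; only
  then will the focus lock (a discrete PID on the QPD error, default
  kp = 0.6, ki = 0.2 s⁻¹) or the per-ROI focus search run. The 3D-stack
  reference position is set 1–2 µm below the focal plane (default 1.5 µm).
- **Image formation.** Emitters render as isotropic Gaussian spots whose
  width grows with defocus, `σ(dz) = σ₀·√(1 + (dz/z_R)²)`; pixel counts
  are `offset + gain·Poisson(photons) + read noise`, 16-bit.
- **Fluidics.** The pump/flow plant is first order
  (`flow → k·pressure`, τ = 2 s); a PID loop (kp = 0.8, ki = 0.5 s⁻¹,
  100 ms period) tracks the target flow rate and each injection step ends
  when the trapezoid-integrated volume reaches its target, followed by a
  zero-flow incubation. A line that never reaches 10 % of the target flow
  within 30 s faults as a blockage.
- **Stacks and files.** The default stack is 60 planes, 250 nm apart,
  50 ms exposure, channels interleaved at each plane. Each channel is
  written as a multipage 16-bit TIFF (or FITS, or raw + header) named
  `scan_SSS_PROBE_RRR_ROI_chCC.tif`, with a YAML metadata sidecar carrying
  sample name, exposure, laser lines and intensities, autofocus
  parameters, stage XY, scan step and total z range, cycle/probe, ROI id,
  seed and virtual timestamp.

## Worked example

```r
library(himsim)

graph <- load_setup(system.file("extdata/config/setup_sim.yml",
                                package = "himsim"))
graph$device("lasers")$set_ir(TRUE)           # 785 nm autofocus laser on

focus <- graph$logic_module("focus")
cal <- focus$calibrate(ramp_um = 2, n_steps = 21)
cat(sprintf("slope: %.4f V/um  precision: %.2f nm  valid: %s\n",
            cal$slope_v_per_um, cal$precision_nm, cal$valid))
#> slope: 0.5040 V/um  precision: 8.14 nm  valid: TRUE

sp_v <- focus$mark_focus()                    # store the focus setpoint
sp <- focus$find_focus(below_offset_um = 1.5)
cat(sprintf("focal z: %.3f um  stack reference: %.3f um\n",
            sp$focal_z_um, sp$reference_z_um))
#> focal z: 50.000 um  stack reference: 48.500 um

fluidics <- graph$logic_module("fluidics")
r <- fluidics$run_step(injection_step("hybridization-mix", valve = 5,
                                      volume_ul = 1000, flow_ul_min = 250))
cat(sprintf("delivered: %.1f ul  mean flow: %.1f ul/min  duration: %.1f s\n",
            r$delivered_ul, r$mean_flow_ul_min, r$duration_s))
#> delivered: 1000.1 ul  mean flow: 250.0 ul/min  duration: 241.0 s
```

The calibration slope recovers the configured QPD gain (0.5 V/µm); the
8 nm precision reflects the configured sensor noise (10 nm RMS
equivalent) and sits well inside the 30 nm validity bound. The injection
report shows the PID holding 250 µl/min and stopping on the 1000 µl
volume trigger — 241 s of pump time that elapsed on the virtual clock, in
milliseconds of wall time.

A complete multi-cycle experiment (cycle 0 dye/fiducial injection and
reference stacks, then hybridize → image every ROI → bleach, per cycle)
runs from two YAML files:

```r
config <- experiment_config_load(system.file(
  "extdata/config/experiment_him.yml", package = "himsim"))
report <- run_him_task(config, graph, status_path = "status.yml")
```

or from the shell via the bundled CLI
(`inst/cli/himsim run --setup setup.yml --config experiment.yml`).

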