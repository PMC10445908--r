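---
title: "Simulation and control models behind himsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation and control models behind himsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(himsim)
```

`himsim` is an acquisition-control framework for sequential multiplexed
imaging in which every hardware interface is implemented by a simulated
device with an explicit physical-response model. This vignette is the
package's own account of those models: what is being simulated, which
parameters matter, which design decisions were genuinely open, and what
the passing test suite does — and does not — demonstrate about real
instruments.

## The virtual clock and determinism

All timed behavior (stage settling, camera exposure, fluidics dynamics,
incubations, focal-surface drift) elapses on a shared virtual clock
(`SimClock`), never on wall time. Devices with time-dependent state
register hooks that the clock invokes on every advance, in registration
order, so a 4-minute injection or a 15-minute incubation costs
microseconds of wall time and any schedule of device calls is exactly
reproducible.

Randomness is organized as one root seed per setup from which every
device derives an independent substream keyed by its role name
(`derive_seed(seed, role)`). Consequences worth stating: (i) a fixed
seed gives bit-identical sensor output, file hashes and status sequences
across runs, which the test suite asserts; (ii) adding or removing a
device never perturbs another device's noise stream.

## The virtual sample

`generate_sample()` places `n_emitters` point emitters uniformly in a
square field (default 200 µm, centered on the stage origin), with axial
positions drawn from a thin Gaussian slab (SD 0.3 µm) around the focal
surface and exponentially distributed brightness (mean 100 photons/ms).
Each emitter hybridizes with exactly one of `n_probes` sequential probes
(read out at 640 nm once that probe is active) and carries, with
probability 0.5, a fiducial label visible at 561 nm in every cycle —
mirroring the fiducial/readout channel split of deposited Hi-M data.
Which probe is currently hybridized is simulation-side state set by the
task engine after a hybridization sequence and cleared after bleaching.

The focal surface drifts as `dz = v·dt + N(0, D·dt)` with a linear rate
`v` (nm/s) and random-walk diffusion `D` (nm²/s); this is the
disturbance the focus lock has to reject. Defaults are gentle
(`v = 2 nm/s` in the shipped example setup) — representative of thermal
drift on a stabilized instrument.

What the sample deliberately does **not** emulate: extended or aberrated
PSFs, autofluorescent background structure, photobleaching within a
cycle, emitter blinking, chromatic offsets between channels, or stage
repeatability errors. Tests passing against this sample therefore
demonstrate the correctness of the *control and bookkeeping* layer
(synchronization, focus servo behavior, volume triggering, file
integrity), not the photophysics of a real specimen.

## Image formation

`render_frame()` draws each visible emitter as an isotropic Gaussian
spot whose width grows with defocus:

$$\sigma(dz) = \sigma_0 \sqrt{1 + (dz/z_R)^2}, \qquad
  dz = z_\text{piezo} - (z_\text{surface} + z_\text{emitter})$$

with defaults $\sigma_0 = 1.3$ px and $z_R = 0.4$ µm, a standard
Gaussian-beam approximation of a widefield PSF. Expected photons are
`brightness × exposure × intensity/100`; counts are
`offset + gain·Poisson(photons) + N(0, read noise)`, rounded and clamped
to 16 bits. A noiseless mode returns the expectation image, which the
tests use for moment analysis of the defocus law.

## Autofocus: calibration, validity, lock

The QPD responds linearly to defocus, `V = g·(z − z_s) + V_0 + ε`, and
is only valid while the 785 nm laser is on. Calibration sweeps a 2 µm
ramp (default 21 steps, centered on the current position, moving upward)
and fits signal vs z by least squares.

**Precision** is defined here as the RMS of the fit residuals divided by
|slope|, expressed in nm. This was the central interpretation decision
of the focus module: "precision" could plausibly mean the fit residual,
the repeatability of the setpoint, or a step-response noise floor; the
residual definition is used because it is computable from the
calibration ramp alone and reduces to the sensor's z-equivalent noise
for an ideal ramp. Validity is exactly `monotonic AND precision < 30 nm`
— with a 10 nm-equivalent sensor the default calibration reports
≈ 9.5 nm and passes with a wide margin, while any sign reversal in the
ramp invalidates it regardless of precision.

The focus lock is a positional-form discrete PID on the QPD error
converted to nm through the calibrated slope (defaults kp = 0.6,
ki = 0.2 s⁻¹, kd = 0, 100 ms period, output limited to ±1000 nm per
iteration, integral frozen while the output saturates). No tuning
prescription existed for this loop; these gains were chosen once as a
conservative setting that rejects nm/s-scale drift with zero
steady-state error (the integral term) and cannot slew the objective
across its travel on a spurious reading (the output limit). The per-ROI
focus search reuses the calibration: it steps the piezo by
`(V_set − V)/g` until the error is below 10 nm (averaging 5 readings per
iteration), then places the stack reference `below_offset_um` (default
1.5 µm, within the customary 1–2 µm band) below the focal plane so
axial variability of the sample never truncates a stack.

The QPD is the only autofocus modality modeled; camera-based sharpness
autofocus exists on some instruments but is out of scope here.

## Fluidics: plant, PID, volume trigger

The pump/flow plant is first order — `flow → k·pressure` with time
constant τ = 2 s and gain k = 2 (µl/min)/mbar — stepped by its exact
exponential discretization on every clock advance, which is the simplest
plant that makes PID tuning meaningful. Delivered volume integrates the
true (noise-free) flow trapezoidally at the loop period; the flow sensor
reports the true flow plus Gaussian noise (1 µl/min RMS).

The flow PID (kp = 0.8, ki = 0.5 s⁻¹, 100 ms period, output clamped to
the pump's 0–1000 mbar range) tracks the target flow; a step advances
when the integrated volume reaches its target — so overshoot is bounded
by one control tick of flow — then switches the pump off and lets the
incubation elapse at zero flow. A step whose flow never reaches 10 % of
target within 30 s (virtual) is reported as a blockage fault with the
pump stopped; fault handling is not described for the original
instrument and was added as necessary engineering for unattended runs.
Injection steps execute strictly sequentially — incubations do not
overlap with imaging of other ROIs; whether a real instrument overlaps
them is left open, and the sequential reading keeps the event schedule
unambiguous.

## ROI planning

Mosaics are grids with pitch `fov·(1 − overlap)` visited in a snake
(boustrophedon) order. Two details were unspecified and fixed here by
decision: the snake starts at the **top-left tile moving rightward**,
and "number of tiles" is interpreted as **rows × cols** rather than a
total count. Region interpolation computes the minimal covering grid,
`max(1, ceil((span − fov)/pitch) + 1)` tiles per axis, starting flush
with the low edge of the region; coverage is property-tested against an
exhaustive 1 µm raster oracle. The FOV is square (one number);
rectangular sensors would extend the spec with a second value. ROI ids
are 3-digit zero-padded ordinals to match the filename convention.

## Acquisition and files

A stack plan enumerates (plane, channel) events with the plane as the
outer loop: all channels are exposed at each z before the piezo steps.
The alternative reading — full z-stack per channel — was rejected
because per-plane interleaving minimizes z-drift between channels of the
same plane; "acquired simultaneously in two or three colors" is taken to
mean within-plane interleaving, not literally simultaneous exposure.
During execution the logic enforces, and the event log records, the
synchronization contract: piezo settled before every trigger, exactly
one visible laser during each exposure, laser off before the next move.
An independent audit function re-checks the log after every acquisition.

Files follow `scan_SSS_PROBE_RRR_ROI_chCC.<ext>`, one file per channel
(matching the `ch00/ch01/ch02` convention of deposited datasets). The
scan index carries the cycle number and the probe token the cycle label;
the parser additionally tolerates extra underscore-delimited processing
tokens (e.g. `converted_decon`) that downstream pipelines insert. Three
formats are supported: multipage 16-bit TIFF (via the `tiff` package),
FITS (a minimal single-HDU 16-bit writer/reader implemented in the
package, using the standard BZERO = 32768 unsigned convention), and a
flat little-endian raw dump with a YAML shape header. Pixel data
round-trip bit-exactly through all three.

## Task engine

The runner is a table-driven state machine over {stopped, starting,
running, pausing, paused, resuming, finishing}; a `paused` state is
included although the original state list is open-ended, since pausing
is meaningless without a state to rest in. Emergency stop is legal from
every non-stopped state, reaches `stopped` in one transition, and forces
the safe state (all lasers 0 %, pump pressure 0). Smooth stop completes
the current **cycle**; pause takes effect at the next **ROI** boundary
(the paper fixes the smooth-stop granularity but not pause; the ROI
boundary was chosen as the finest point at which the hardware is idle).
A resumed run restarts at the next ROI rather than mid-stack. While a
task runs it holds an exclusive hardware lock; concurrent commands from
other callers are rejected as busy.

Status snapshots (virtual timestamp, state, cycle, ROI, fluidics
figures, last pre-analysis) are written as YAML via write-to-temp +
atomic rename, so an external tracker polling the file always parses a
complete document. Pre-analysis content is a deliberate minimal choice:
per-plane variance as the sharpness trace, its argmax (ties to the
lowest plane) as best focus, and a max-intensity projection.

## Problem sizes and numerical choices

The test suite and acceptance script run, by choice, at desk scale:
sensors of 16–48 px, 10–40 emitters, stacks of 4–9 planes for unit
tests, the default 60-plane geometry where the stack contract itself is
under test, and a toy end-to-end experiment of 2 cycles × 3 ROIs ×
2 channels × 5 planes. These sizes exercise every code path (the frame
count, census and metadata laws are size-independent) while keeping the
whole suite in the tens of seconds. Monte-Carlo checks use 50–300
replicates, with tolerances set from the corresponding standard errors.

Other numerical conventions: image arrays are `height × width` with
pixel (1,1) top-left and the stage position mapped to the sensor
center; stage XY in µm with ±10 000 µm travel; piezo z in µm, travel
0–100 µm, increasing toward the sample; YAML serialization of doubles
is finite-precision, so re-fitting a calibration from its exported ramp
agrees to ~10⁻⁴ nm rather than machine precision.

## Known limitations

- Optical realism stops at the Gaussian-PSF level; no aberrations,
  background structure, or bleaching kinetics.
- Only the QPD autofocus modality is modeled.
- One pump, one valve bank; multi-pump coordination and
  pressure-vs-syringe distinctions are out of scope.
- The GUI layer of the original three-tier architecture is intentionally
  absent: the logic APIs, the CLI and the status file are the public
  surface, and the dashboard consumer of the status file is not built.
- Real vendor drivers are not included; the abstract interfaces define
  the contract they would implement.
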