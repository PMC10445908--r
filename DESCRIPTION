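Package: himsim
Title: Headless Acquisition Control for Sequential Multiplexed Imaging with Simulated Hardware
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A headless, simulator-backed control framework for sequential
    multiplexed fluorescence imaging (Hi-M) experiments. Provides abstract
    hardware interfaces with physically modeled mock devices (camera, stage,
    piezo, laser bank, quadrant-photodiode autofocus sensor, microfluidics
    valve/pump/flow sensor), PID control loops for autofocus stabilization and
    flow-rate regulation, ROI and mosaic planning with snake-ordered tiling,
    synchronized multicolor z-stack acquisition with TIFF/FITS/raw output and
    YAML metadata sidecars, injection-sequence execution, and a state-machine
    task engine that runs complete multi-cycle experiments on a virtual clock,
    so multi-hour acquisitions simulate in seconds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    R6,
    yaml,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
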