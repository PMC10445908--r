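# Fixture builders: setup configs, graphs and toy experiments are
# constructed in code so every test starts from a fresh, seeded simulator.

him_test_setup <- function(seed = 42, sensor_px = 32, qpd_noise_v = 0,
                           drift_nm_s = 0, diffusion_nm2_s = 0,
                           n_emitters = 20, camera_model = "sim_camera",
                           camera_options = NULL, pump_options = list(),
                           sample = list()) {
  cam_opts <- camera_options %||% list(width_px = sensor_px,
                                       height_px = sensor_px)
  sample_cfg <- utils::modifyList(
    list(n_emitters = n_emitters, n_probes = 2,
         drift_nm_s = drift_nm_s, diffusion_nm2_s = diffusion_nm2_s),
    sample)
  list(
    global = list(field_size_um = 200, pixel_size_um = 0.1, seed = seed,
                  sample = sample_cfg),
    devices = list(
      cam = list(model = camera_model, options = cam_opts),
      stage = list(model = "sim_stage"),
      piezo = list(model = "sim_piezo"),
      lasers = list(model = "sim_lasers"),
      qpd = list(model = "sim_qpd", options = list(noise_v = qpd_noise_v)),
      valve = list(model = "sim_valve"),
      pump = list(model = "sim_pump", options = pump_options),
      flow = list(model = "sim_flowsensor"),
      needle = list(model = "sim_needle")
    ),
    logic = list(
      focus = list(logic = "focus_logic",
                   connect = list(qpd = "qpd", piezo = "piezo",
                                  lasers = "lasers")),
      acquisition = list(logic = "acquisition_logic",
                         connect = list(camera = "cam", piezo = "piezo",
                                        lasers = "lasers", stage = "stage")),
      fluidics = list(logic = "fluidics_logic",
                      connect = list(pump = "pump", valve = "valve",
                                     flow = "flow", needle = "needle"))
    )
  )
}

him_test_graph <- function(...) load_setup(him_test_setup(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write the ROI list, injection sequences and experiment config of a small
# multi-cycle experiment into `dir`; returns the experiment_config.
him_toy_experiment <- function(dir, seed = 7, n_cycles = 2, n_rois = 3,
                               n_planes = 5, format = "tiff") {
  seq0 <- injection_sequence("cycle0", list(
    injection_step("DAPI-dye", 2, 50, 250, incubation_s = 5),
    injection_step("fiducial-probe", 5, 40, 250, incubation_s = 5,
                   tray_slot = c(1, 1, 0)),
    injection_step("wash", 3, 50, 250)))
  hyb <- injection_sequence("hybridization", list(
    injection_step("probe", 5, 40, 250, incubation_s = 10),
    injection_step("wash", 3, 30, 250)))
  bl <- injection_sequence("bleaching", list(
    injection_step("bleach", 4, 40, 250, incubation_s = 5),
    injection_step("wash", 3, 30, 250)))
  sequence_save(seq0, file.path(dir, "cycle0.yml"))
  sequence_save(hyb, file.path(dir, "hybridization.yml"))
  sequence_save(bl, file.path(dir, "bleaching.yml"))
  rois <- build_mosaic(0, 0, 1, n_rois, 50, overlap = 0.1)
  roi_save(rois, file.path(dir, "rois.yml"))
  probes <- lapply(seq_len(n_cycles), function(i) {
    list(cycle = i, name = sprintf("RT%02d", i), tray_slot = c(1, 1, i))
  })
  experiment_config(
    task = "him_full", sample_name = "toy-embryo",
    save_root = file.path(dir, "out"),
    imaging = imaging_settings(
      n_planes = n_planes,
      channels = list(list(laser_nm = 561, intensity_pct = 30),
                      list(laser_nm = 640, intensity_pct = 50)),
      format = format),
    roi_file = file.path(dir, "rois.yml"),
    sequences = list(cycle0 = file.path(dir, "cycle0.yml"),
                     hybridization = file.path(dir, "hybridization.yml"),
                     bleaching = file.path(dir, "bleaching.yml")),
    probes = probes, n_cycles = n_cycles, seed = seed)
}

# Exhaustive 1 um raster coverage oracle: every point of the rectangle
# [lo, hi] must lie inside at least one square tile of side fov.
raster_covered <- function(rois, lo, hi, fov) {
  gx <- seq(lo[1], hi[1], by = 1)
  gy <- seq(lo[2], hi[2], by = 1)
  for (y in gy) {
    inside_x <- rep(FALSE, length(gx))
    for (i in seq_len(nrow(rois))) {
      if (abs(y - rois$y_um[i]) <= fov / 2) {
        inside_x <- inside_x | (abs(gx - rois$x_um[i]) <= fov / 2)
      }
    }
    if (!all(inside_x)) return(FALSE)
  }
  TRUE
}

# Independent snake-path oracle: brute-force enumeration of tile centers
# in boustrophedon order, written without reference to the implementation.
oracle_snake <- function(xs, ys) {
  out <- NULL
  for (r in seq_along(ys)) {
    cols <- seq_along(xs)
    if (r %% 2 == 0) cols <- rev(cols)
    for (cc in cols) out <- rbind(out, c(xs[cc], ys[r]))
  }
  out
}
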