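# Synchronized multicolor z-stack acquisition: plan the frame schedule,
# execute it against the hardware (camera exposure <-> laser switching <->
# piezo stepping), and audit the recorded event log.

#' Imaging settings for a multicolor z-stack
#'
#' Defaults follow standard sequential-imaging practice: 60 planes
#' separated by 250 nm with 50 ms exposure, two or three color channels.
#'
#' @param exposure_ms Camera exposure per frame (ms, > 0).
#' @param channels Ordered list of channels, each a list/vector with
#'   `laser_nm` and `intensity_pct`.
#' @param n_planes Number of z planes (>= 1).
#' @param dz_nm Plane separation (nm, > 0).
#' @param z_start_um Axial start of the stack (the stack reference
#'   position); may be NA until the focus logic supplies it.
#' @param format Save format: "tiff", "fits" or "raw".
#' @return List of class `imaging_settings`.
#' @export
imaging_settings <- function(exposure_ms = 50,
                             channels = list(
                               list(laser_nm = 561, intensity_pct = 30),
                               list(laser_nm = 640, intensity_pct = 50)),
                             n_planes = 60, dz_nm = 250, z_start_um = NA,
                             format = "tiff") {
  if (exposure_ms <= 0) stop("imaging_settings: exposure must be > 0 ms")
  if (n_planes < 1) stop("imaging_settings: n_planes must be >= 1")
  if (dz_nm <= 0) stop("imaging_settings: dz must be > 0 nm")
  if (length(channels) == 0) {
    stop("imaging_settings: at least one channel required")
  }
  if (!format %in% c("tiff", "fits", "raw")) {
    stop("imaging_settings: format must be tiff, fits or raw")
  }
  channels <- lapply(channels, function(ch) {
    ch <- as.list(ch)
    if (is.null(ch$laser_nm) || is.null(ch$intensity_pct)) {
      stop("imaging_settings: each channel needs laser_nm and intensity_pct")
    }
    ch
  })
  structure(list(exposure_ms = exposure_ms, channels = channels,
                 n_planes = as.integer(n_planes), dz_nm = dz_nm,
                 z_start_um = z_start_um, format = format),
            class = "imaging_settings")
}

#' Plan the frame schedule of a z-stack
#'
#' One event per (plane, channel) in lexicographic order: channels are
#' interleaved at each plane before the piezo steps, so the piezo moves
#' exactly `n_planes - 1` times and channels stay registered in z.
#'
#' @param settings An [imaging_settings()] with a defined `z_start_um`.
#' @param travel_um Piezo travel `c(min, max)` for range validation.
#' @return Data frame of FrameEvents: order (1-based), plane (0-based),
#'   channel (0-based), z_um, laser_nm, intensity_pct.
#' @export
plan_stack <- function(settings, travel_um = c(0, 100)) {
  stopifnot(inherits(settings, "imaging_settings"))
  z0 <- settings$z_start_um
  if (is.na(z0)) stop("plan_stack: z_start_um is undefined")
  n_p <- settings$n_planes
  n_c <- length(settings$channels)
  z_top <- z0 + (n_p - 1) * settings$dz_nm / 1000
  if (z0 < travel_um[1] || z_top > travel_um[2]) {
    stop(sprintf("stack z range [%.2f, %.2f] um exceeds piezo travel [%g, %g]",
                 z0, z_top, travel_um[1], travel_um[2]))
  }
  plane <- rep(seq_len(n_p) - 1L, each = n_c)
  channel <- rep(seq_len(n_c) - 1L, times = n_p)
  data.frame(
    order = seq_len(n_p * n_c),
    plane = plane,
    channel = channel,
    z_um = z0 + plane * settings$dz_nm / 1000,
    laser_nm = vapply(settings$channels[channel + 1L],
                      function(ch) as.numeric(ch$laser_nm), numeric(1)),
    intensity_pct = vapply(settings$channels[channel + 1L],
                           function(ch) as.numeric(ch$intensity_pct),
                           numeric(1))
  )
}

#' Acquisition logic module
#'
#' Executes a frame plan with full synchronization: the piezo settles
#' before every trigger, exactly one visible laser is on during each
#' exposure, and the laser is switched off before the next move. Every
#' hardware action is appended to an event log that [audit_events()] can
#' check independently.
#'
#' @export
AcquisitionLogic <- R6::R6Class("AcquisitionLogic",
  public = list(
    #' @field role Role name assigned by the registry.
    role = NULL,
    #' @field devices Named list: camera, piezo, lasers, stage.
    devices = NULL,
    #' @field graph Owning [HimGraph].
    graph = NULL,

    #' @description Wired by the registry.
    #' @param devices,graph See fields.
    initialize = function(devices, graph) {
      self$devices <- devices
      self$graph <- graph
    },

    #' @description Acquire a planned z-stack.
    #' @param plan Frame schedule from [plan_stack()].
    #' @param settings The [imaging_settings()] the plan was built from.
    #' @param .owner Arbiter token.
    #' @return List: `stack` (integer array height x width x planes x
    #'   channels), `events` (data frame log), `metadata_stub` (acquisition
    #'   fields for the sidecar).
    acquire = function(plan, settings, .owner = NULL) {
      self$graph$check_available(.owner)
      cam <- self$devices$camera
      piezo <- self$devices$piezo
      lasers <- self$devices$lasers
      stage <- self$devices$stage
      clock <- self$graph$clock
      if (!stage$settled()) stop("acquisition start with unsettled stage")
      cam$set_exposure(settings$exposure_ms)
      n_c <- length(settings$channels)
      n_p <- if (nrow(plan) > 0) max(plan$plane) + 1L else 0L
      h <- cam$settings$height_px
      w <- cam$settings$width_px
      stack <- array(0L, dim = c(h, w, n_p, n_c))
      ev <- list()
      emit <- function(action, detail = "", plane = NA, channel = NA) {
        ev[[length(ev) + 1L]] <<- data.frame(
          t_s = clock$now, action = action, detail = as.character(detail),
          plane = plane, channel = channel,
          n_lasers_on = length(lasers$active_lines()),
          piezo_settled = piezo$settled(), stage_settled = stage$settled(),
          z_um = piezo$z_um, stringsAsFactors = FALSE)
      }
      if (nrow(plan) > 0) {
        for (i in seq_len(nrow(plan))) {
          e <- plan[i, ]
          if (piezo$z_um != e$z_um) {
            piezo$move_to(e$z_um)
            emit("piezo_move", sprintf("%.4f um", e$z_um), e$plane)
            piezo$wait_settled()
          }
          lasers$set_intensity(e$laser_nm, e$intensity_pct)
          emit("laser_on", sprintf("%g nm @ %g%%", e$laser_nm,
                                   e$intensity_pct), e$plane, e$channel)
          img <- tryCatch(
            cam$snap(stage, piezo, lasers),
            error = function(err) {
              emit("abort", conditionMessage(err), e$plane, e$channel)
              lasers$set_intensity(e$laser_nm, 0)
              stop("acquisition aborted: ", conditionMessage(err))
            })
          emit("exposure", sprintf("%g ms", settings$exposure_ms),
               e$plane, e$channel)
          stack[, , e$plane + 1L, e$channel + 1L] <- img
          lasers$set_intensity(e$laser_nm, 0)
          emit("laser_off", sprintf("%g nm", e$laser_nm), e$plane, e$channel)
        }
      }
      events <- if (length(ev) > 0) do.call(rbind, ev) else
        data.frame(t_s = numeric(0), action = character(0),
                   detail = character(0), plane = integer(0),
                   channel = integer(0), n_lasers_on = integer(0),
                   piezo_settled = logical(0), stage_settled = logical(0),
                   z_um = numeric(0))
      list(stack = stack, events = events,
           metadata_stub = list(
             exposure_ms = settings$exposure_ms,
             channels = settings$channels,
             stage_x_um = stage$x_um, stage_y_um = stage$y_um,
             dz_nm = settings$dz_nm, n_planes = n_p,
             z_range_um = if (n_p > 0) (n_p - 1) * settings$dz_nm / 1000 else 0,
             t_s = clock$now))
    }
  )
)

#' Audit an acquisition event log
#'
#' Independent synchronization check over the recorded events: every
#' exposure must have exactly one visible laser line on and settled piezo
#' and stage, and exposure z positions must be monotonically nondecreasing.
#'
#' @param events Event data frame from `AcquisitionLogic$acquire()`.
#' @return List: `ok` (logical), `problems` (character vector).
#' @export
audit_events <- function(events) {
  problems <- character(0)
  exp_rows <- events[events$action == "exposure", , drop = FALSE]
  bad_lasers <- exp_rows$n_lasers_on != 1
  if (any(bad_lasers)) {
    problems <- c(problems, sprintf(
      "exposure at t=%.3f s with %d visible lasers on",
      exp_rows$t_s[bad_lasers], exp_rows$n_lasers_on[bad_lasers]))
  }
  unsettled <- !exp_rows$piezo_settled | !exp_rows$stage_settled
  if (any(unsettled)) {
    problems <- c(problems, sprintf(
      "exposure at t=%.3f s with unsettled hardware", exp_rows$t_s[unsettled]))
  }
  if (nrow(exp_rows) > 1 && any(diff(exp_rows$z_um) < -1e-9)) {
    problems <- c(problems, "exposure z positions not nondecreasing")
  }
  if (any(events$action == "abort")) {
    problems <- c(problems, "acquisition recorded an abort event")
  }
  list(ok = length(problems) == 0, problems = problems)
}

#' Assemble the metadata sidecar content for a saved stack
#'
#' Carries the full acquisition context: sample name, exposure, laser
#' lines and intensities, autofocus parameters, stage position, scan step
#' size and total z range, cycle/probe, ROI id, seed and virtual
#' timestamp.
#'
#' @param sample_name Sample name.
#' @param stub `metadata_stub` from `AcquisitionLogic$acquire()`.
#' @param autofocus List: setpoint_v, kp, ki, kd, slope_v_per_um,
#'   precision_nm.
#' @param cycle Cycle number (0 for the reference cycle).
#' @param probe Probe (cycle) name.
#' @param roi_id ROI id string.
#' @param seed Root seed of the run.
#' @return List of class `StackMetadata`.
#' @export
stack_metadata <- function(sample_name, stub, autofocus, cycle, probe,
                           roi_id, seed) {
  structure(list(
    sample_name = sample_name,
    exposure_ms = stub$exposure_ms,
    channels = stub$channels,
    autofocus = autofocus,
    stage_x_um = stub$stage_x_um,
    stage_y_um = stub$stage_y_um,
    scan_step_nm = stub$dz_nm,
    n_planes = stub$n_planes,
    z_range_um = stub$z_range_um,
    cycle = cycle,
    probe = probe,
    roi_id = roi_id,
    seed = seed,
    timestamp_s = stub$t_s
  ), class = "StackMetadata")
}

# ---- filename convention ---------------------------------------------------

#' Compose a stack filename
#'
#' Convention: `scan_SSS_PROBE_RRR_ROI_chCC.<ext>` with 3-digit scan and
#' ROI ordinals and a 2-digit channel index, e.g.
#' `scan_001_RT27_001_ROI_ch00.tif`.
#'
#' @param scan Scan (acquisition) index >= 0.
#' @param probe Probe name token; must not contain underscores.
#' @param roi ROI ordinal (integer) or 3-digit id string.
#' @param channel Channel index >= 0.
#' @param ext File extension without dot.
#' @return Filename string.
#' @export
him_filename <- function(scan, probe, roi, channel, ext = "tif") {
  if (grepl("_", probe)) {
    stop("probe token must not contain underscores: ", probe)
  }
  if (scan < 0 || channel < 0) stop("scan and channel indices must be >= 0")
  roi_i <- if (is.character(roi)) as.integer(roi) else as.integer(roi)
  sprintf("scan_%03d_%s_%03d_ROI_ch%02d.%s",
          as.integer(scan), probe, roi_i, as.integer(channel), ext)
}

#' Parse a stack filename
#'
#' Inverts [him_filename()] and tolerates extra underscore-delimited
#' processing tokens between `ROI` and `chCC` (e.g. the `converted_decon`
#' markers added by downstream pipelines). Never throws on a bad name.
#'
#' @param name Filename (with or without directory part).
#' @return On success, a list with `valid = TRUE`, scan, probe, roi
#'   (3-digit string), roi_index, channel, extra_tokens, ext. On failure,
#'   `list(valid = FALSE, reason = ...)`.
#' @export
parse_him_filename <- function(name) {
  base <- basename(name)
  pat <- "^scan_([0-9]{3})_([^_]+)_([0-9]{3})_ROI((?:_[^_.]+)*)_ch([0-9]{2})\\.([A-Za-z0-9]+)$"
  m <- regmatches(base, regexec(pat, base))[[1]]
  if (length(m) == 0) {
    return(list(valid = FALSE,
                reason = paste0("filename does not match scan_SSS_PROBE_",
                                "RRR_ROI[_tokens]_chCC.ext: ", base)))
  }
  extra <- m[5]
  extra_tokens <- if (nzchar(extra)) {
    strsplit(sub("^_", "", extra), "_", fixed = TRUE)[[1]]
  } else {
    character(0)
  }
  list(valid = TRUE,
       scan = as.integer(m[2]),
       probe = m[3],
       roi = m[4],
       roi_index = as.integer(m[4]),
       channel = as.integer(m[6]),
       extra_tokens = extra_tokens,
       ext = m[7])
}
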