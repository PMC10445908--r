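# Setup registry: parse the setup YAML, instantiate hardware and logic
# modules by role, wire their connections, and provide structured logging.
#
# The setup file plays the part of a manager configuration: it declares
# which device model fills each hardware role and which logic modules
# consume which roles. Swapping a device model (e.g. one camera technology
# for another) only touches the file; the logic layer is unchanged.

# ---- model registry --------------------------------------------------------

.camera_options <- c("exposure_ms", "gain", "width_px", "height_px",
                     "read_noise", "offset", "pixel_size_um", "sigma0_px",
                     "z_r_um")

#' Registry of simulated device models
#'
#' Maps model names usable in the setup file's `devices` section to their
#' implementing class, abstract interface, allowed option keys, and preset
#' defaults. The two camera presets model an EMCCD (small chip, high gain)
#' and an sCMOS (large chip, low gain) behind the identical interface.
#'
#' @return Named list of model descriptors.
#' @export
device_models <- function() {
  list(
    sim_camera = list(class = SimCamera, interface = "camera",
                      options = .camera_options, presets = list()),
    sim_camera_emccd = list(class = SimCamera, interface = "camera",
                            options = .camera_options,
                            presets = list(width_px = 512, height_px = 512,
                                           gain = 20)),
    sim_camera_scmos = list(class = SimCamera, interface = "camera",
                            options = .camera_options,
                            presets = list(width_px = 2048, height_px = 2048,
                                           gain = 0.5)),
    sim_stage = list(class = SimStage, interface = "stage_xy",
                     options = c("settle_s", "travel_um"), presets = list()),
    sim_piezo = list(class = SimPiezo, interface = "piezo_z",
                     options = c("settle_s", "z_um"), presets = list()),
    sim_lasers = list(class = SimLaserBank, interface = "lasers",
                      options = character(0), presets = list()),
    sim_filterwheel = list(class = SimFilterWheel, interface = "filter_wheel",
                           options = "n_positions", presets = list()),
    sim_qpd = list(class = SimQPD, interface = "qpd",
                   options = c("gain_v_per_um", "offset_v", "noise_v"),
                   presets = list()),
    sim_pump = list(class = SimPump, interface = "pump",
                    options = c("k_flow", "tau_s", "p_max_mbar"),
                    presets = list()),
    sim_flowsensor = list(class = SimFlowSensor, interface = "flow_sensor",
                          options = "noise_ul_min", presets = list()),
    sim_valve = list(class = SimValve, interface = "valve",
                     options = "n_ports", presets = list()),
    sim_needle = list(class = SimNeedle, interface = "needle",
                      options = character(0), presets = list())
  )
}

# logic name -> required connectors (connector name -> required interface)
.logic_registry <- function() {
  list(
    focus_logic = list(
      connectors = c(qpd = "qpd", piezo = "piezo_z", lasers = "lasers"),
      make = function(devs, graph) FocusLogic$new(devs, graph)
    ),
    acquisition_logic = list(
      connectors = c(camera = "camera", piezo = "piezo_z",
                     lasers = "lasers", stage = "stage_xy"),
      make = function(devs, graph) AcquisitionLogic$new(devs, graph)
    ),
    fluidics_logic = list(
      connectors = c(pump = "pump", valve = "valve", flow = "flow_sensor",
                     needle = "needle"),
      make = function(devs, graph) FluidicsLogic$new(devs, graph)
    )
  )
}

# ---- logging ---------------------------------------------------------------

#' Structured run logger on the virtual clock
#'
#' Appends records (virtual timestamp, level, source role, message); never
#' throws, so logging cannot take down an experiment. Serializable to a
#' line-oriented tab-separated text file, stably ordered by timestamp then
#' insertion order.
#'
#' @export
SimLogger <- R6::R6Class("SimLogger",
  public = list(
    #' @field clock The [SimClock] supplying timestamps.
    clock = NULL,

    #' @description Create a logger bound to a clock.
    #' @param clock A [SimClock].
    initialize = function(clock) {
      self$clock <- clock
      private$t <- numeric(0)
      private$level <- character(0)
      private$source <- character(0)
      private$message <- character(0)
    },

    #' @description Append a record; errors are swallowed.
    #' @param level One of "debug", "info", "warning", "error".
    #' @param source Role name of the emitting module.
    #' @param message Message text (tabs/newlines are flattened).
    log = function(level, source, message) {
      tryCatch({
        private$t <- c(private$t, self$clock$now)
        private$level <- c(private$level, as.character(level))
        private$source <- c(private$source, as.character(source))
        private$message <- c(private$message,
                             gsub("[\t\n]+", " ", as.character(message)))
      }, error = function(e) NULL)
      invisible(self)
    },

    #' @description All records as a data frame (stable time order).
    records = function() {
      ord <- order(private$t) # radix sort: stable w.r.t. insertion order
      data.frame(t_s = private$t[ord], level = private$level[ord],
                 source = private$source[ord],
                 message = private$message[ord], stringsAsFactors = FALSE)
    },

    #' @description Write the log as tab-separated UTF-8 text, one record
    #'   per line. Always produces a file, even for an empty log.
    #' @param path Output file path.
    save = function(path) {
      r <- self$records()
      lines <- sprintf("%.6f\t%s\t%s\t%s", r$t_s, r$level, r$source, r$message)
      writeLines(lines, path, useBytes = TRUE)
      invisible(path)
    }
  ),
  private = list(t = NULL, level = NULL, source = NULL, message = NULL)
)

# ---- setup loading ---------------------------------------------------------

.check_names <- function(x, allowed, required, what) {
  nm <- names(x)
  extra <- setdiff(nm, allowed)
  if (length(extra) > 0) {
    stop(sprintf("%s: unknown key(s) %s (allowed: %s)", what,
                 paste(extra, collapse = ", "),
                 paste(allowed, collapse = ", ")))
  }
  missing <- setdiff(required, nm)
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required key(s) %s", what,
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Simulated setup graph
#'
#' The wired product of [load_setup()]: the shared clock, sample and
#' logger plus all instantiated device and logic modules keyed by role.
#' A command arbiter lets a running task take exclusive ownership of the
#' hardware; concurrent conflicting commands are rejected as busy.
#'
#' @export
HimGraph <- R6::R6Class("HimGraph",
  public = list(
    #' @field clock Shared [SimClock].
    clock = NULL,
    #' @field sample Shared [VirtualSample].
    sample = NULL,
    #' @field logger Shared [SimLogger].
    logger = NULL,
    #' @field devices Named list of device instances by role.
    devices = NULL,
    #' @field logic Named list of logic instances by role.
    logic = NULL,
    #' @field edges Data frame (from = logic role, to = device role,
    #'   connector name).
    edges = NULL,
    #' @field seed Root seed of the setup.
    seed = NULL,
    #' @field global Global section of the setup config.
    global = NULL,

    #' @description Assembled by [load_setup()]; not user-facing.
    #' @param clock,sample,logger,devices,logic,edges,seed,global See fields.
    initialize = function(clock, sample, logger, devices, logic, edges,
                          seed, global) {
      self$clock <- clock; self$sample <- sample; self$logger <- logger
      self$devices <- devices; self$logic <- logic; self$edges <- edges
      self$seed <- seed; self$global <- global
      private$owner <- NULL
    },

    #' @description Fetch a device by role (error if absent).
    #' @param role Role name.
    device = function(role) {
      if (!role %in% names(self$devices)) {
        stop("no device under role '", role, "'")
      }
      self$devices[[role]]
    },

    #' @description Fetch a logic module by role (error if absent).
    #' @param role Role name.
    logic_module = function(role) {
      if (!role %in% names(self$logic)) {
        stop("no logic module under role '", role, "'")
      }
      self$logic[[role]]
    },

    #' @description Take exclusive hardware ownership (task arbiter).
    #' @param owner Opaque token identifying the owner.
    acquire_lock = function(owner) {
      if (!is.null(private$owner) && !identical(private$owner, owner)) {
        stop("hardware busy: another task owns the setup")
      }
      private$owner <- owner
      invisible(self)
    },

    #' @description Release ownership.
    #' @param owner The token passed to `acquire_lock`.
    release_lock = function(owner) {
      if (identical(private$owner, owner)) private$owner <- NULL
      invisible(self)
    },

    #' @description Assert the caller may command hardware now.
    #' @param owner Token, or NULL for an interactive (unowned) command.
    check_available = function(owner = NULL) {
      if (!is.null(private$owner) && !identical(private$owner, owner)) {
        stop("hardware busy: an experiment task is running; ",
             "concurrent commands are disabled")
      }
      invisible(TRUE)
    },

    #' @description TRUE if a task currently owns the hardware.
    busy = function() !is.null(private$owner)
  ),
  private = list(owner = NULL)
)

#' Load a setup configuration and wire the module graph
#'
#' Parses the setup YAML (top-level keys `devices`, `logic`, `global`),
#' instantiates every declared device model and logic module, and wires
#' logic connectors to device roles. Parsing is strict: unknown top-level
#' keys, unknown models, unknown option keys, dangling connection targets
#' and interface mismatches all abort with a message naming the offending
#' role.
#'
#' @param path Path to a setup YAML file, or an already-parsed list with
#'   the same structure.
#' @return A [HimGraph].
#' @export
load_setup <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("setup file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    stop("load_setup: path must be a file path or a parsed config list")
  }
  .check_names(cfg, c("devices", "logic", "global"), "devices", "setup config")
  global <- cfg$global %||% list()
  .check_names(global, c("field_size_um", "pixel_size_um", "seed", "sample"),
               character(0), "setup config: global")
  seed <- global$seed %||% 0
  if (!is.numeric(seed) || seed < 0 || seed != round(seed)) {
    stop("setup config: global seed must be a non-negative integer")
  }

  clock <- SimClock$new()
  logger <- SimLogger$new(clock)

  sample_cfg <- global$sample %||% list()
  .check_names(sample_cfg,
               c("n_emitters", "n_probes", "drift_nm_s", "diffusion_nm2_s",
                 "surface_z_um", "brightness_photons_ms", "fiducial_fraction",
                 "z_sd_um"),
               character(0), "setup config: global$sample")
  sample <- generate_sample(
    n_emitters = sample_cfg$n_emitters %||% 50,
    field_um = global$field_size_um %||% 200,
    n_probes = sample_cfg$n_probes %||% 3,
    drift_nm_s = sample_cfg$drift_nm_s %||% 0,
    diffusion_nm2_s = sample_cfg$diffusion_nm2_s %||% 0,
    seed = seed,
    surface_z_um = sample_cfg$surface_z_um %||% 50,
    brightness_photons_ms = sample_cfg$brightness_photons_ms %||% 100,
    fiducial_fraction = sample_cfg$fiducial_fraction %||% 0.5,
    z_sd_um = sample_cfg$z_sd_um %||% 0.3
  )
  sample$bind_clock(clock)

  models <- device_models()
  devs <- list()
  for (role in names(cfg$devices)) {
    block <- cfg$devices[[role]]
    .check_names(block, c("model", "options"), "model",
                 sprintf("device '%s'", role))
    model_name <- block$model
    if (!model_name %in% names(models)) {
      stop(sprintf("device '%s': unknown model '%s'", role, model_name))
    }
    m <- models[[model_name]]
    opts <- block$options %||% list()
    .check_names(opts, m$options, character(0),
                 sprintf("device '%s' (%s) options", role, model_name))
    full_opts <- utils::modifyList(m$presets, opts)
    devs[[role]] <- m$class$new(role, clock, sample, seed, full_opts)
    logger$log("info", "registry",
               sprintf("instantiated %s under role '%s'", model_name, role))
  }
  if (!is.null(global$pixel_size_um)) {
    for (d in devs) {
      if (identical(d$interface, "camera") &&
          is.null((cfg$devices[[d$role]]$options %||% list())$pixel_size_um)) {
        d$settings$pixel_size_um <- global$pixel_size_um
      }
    }
  }

  logic_reg <- .logic_registry()
  logic <- list()
  edges <- data.frame(from = character(0), to = character(0),
                      connector = character(0), stringsAsFactors = FALSE)
  graph <- HimGraph$new(clock, sample, logger, devs, logic, edges, seed,
                        global)
  for (role in names(cfg$logic)) {
    block <- cfg$logic[[role]]
    .check_names(block, c("logic", "connect"), c("logic", "connect"),
                 sprintf("logic '%s'", role))
    logic_name <- block$logic
    if (!logic_name %in% names(logic_reg)) {
      stop(sprintf("logic '%s': unknown logic module '%s'", role, logic_name))
    }
    lr <- logic_reg[[logic_name]]
    connect <- block$connect
    .check_names(connect, names(lr$connectors), names(lr$connectors),
                 sprintf("logic '%s' connections", role))
    bound <- list()
    for (conn in names(lr$connectors)) {
      target <- connect[[conn]]
      if (!target %in% names(devs)) {
        stop(sprintf(
          "logic '%s': connection '%s' targets undeclared role '%s'",
          role, conn, target))
      }
      want <- lr$connectors[[conn]]
      got <- devs[[target]]$interface
      if (!identical(got, want)) {
        stop(sprintf(
          "logic '%s': connector '%s' requires interface '%s' but role '%s' implements '%s'",
          role, conn, want, target, got))
      }
      bound[[conn]] <- devs[[target]]
      edges <- rbind(edges, data.frame(from = role, to = target,
                                       connector = conn,
                                       stringsAsFactors = FALSE))
    }
    mod <- lr$make(bound, graph)
    mod$role <- role
    logic[[role]] <- mod
    logger$log("info", "registry",
               sprintf("wired %s under role '%s'", logic_name, role))
  }
  graph$logic <- logic
  graph$edges <- edges
  graph
}

#' Check that two setups are interchangeable for the logic layer
#'
#' Loads both configurations, runs the same scripted sequence of logic
#' operations on each, and reports the behavioral differences. For a valid
#' hardware swap the differences are limited to device-intrinsic parameters
#' (e.g. sensor dimensions); an interface mismatch surfaces as a load error.
#'
#' @param setup_a,setup_b Setup YAML paths or parsed config lists.
#' @param script Function `graph -> character vector` of behavior
#'   descriptors; the default exercises every wired logic module.
#' @return List with elements `identical` (logical), `differences`
#'   (character: lines differing between the two runs), and the two traces.
#' @export
swap_check <- function(setup_a, setup_b, script = NULL) {
  script <- script %||% .default_swap_script
  ga <- load_setup(setup_a)
  gb <- load_setup(setup_b)
  trace_a <- script(ga)
  trace_b <- script(gb)
  n <- max(length(trace_a), length(trace_b))
  a <- c(trace_a, rep("<absent>", n - length(trace_a)))
  b <- c(trace_b, rep("<absent>", n - length(trace_b)))
  diff_idx <- which(a != b)
  diffs <- if (length(diff_idx) > 0) {
    sprintf("line %d: '%s' vs '%s'", diff_idx, a[diff_idx], b[diff_idx])
  } else {
    character(0)
  }
  list(identical = length(diffs) == 0, differences = diffs,
       trace_a = trace_a, trace_b = trace_b)
}

.default_swap_script <- function(graph) {
  out <- character(0)
  emit <- function(...) out <<- c(out, sprintf(...))
  for (role in names(graph$logic)) {
    mod <- graph$logic[[role]]
    if (inherits(mod, "AcquisitionLogic")) {
      cam <- mod$devices$camera
      emit("%s: camera sensor %dx%d px", role,
           cam$settings$width_px, cam$settings$height_px)
      img <- cam$snap(mod$devices$stage, mod$devices$piezo,
                      mod$devices$lasers)
      emit("%s: snapped dark frame %dx%d", role, nrow(img), ncol(img))
      mod$devices$piezo$move_to(mod$devices$piezo$z_um + 1)
      mod$devices$piezo$wait_settled()
      emit("%s: piezo stepped and settled", role)
    } else if (inherits(mod, "FocusLogic")) {
      mod$devices$lasers$set_ir(TRUE)
      r <- mod$devices$qpd$read(mod$devices$piezo, mod$devices$lasers)
      emit("%s: qpd valid=%s", role, r$valid)
      mod$devices$lasers$set_ir(FALSE)
    } else if (inherits(mod, "FluidicsLogic")) {
      mod$devices$valve$set_position(1)
      emit("%s: valve at port %d", role, mod$devices$valve$position)
      emit("%s: flow volume %.3f ul", role, mod$devices$flow$read_volume())
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
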