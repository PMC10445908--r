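# Task engine: the task-runner state machine, experiment configuration
# validation, the end-to-end multi-cycle experiment, stop/pause semantics,
# the status-tracker file interface, and real-time pre-analysis.

# ---- state machine ---------------------------------------------------------

#' Task state-machine transition table
#'
#' States: stopped, starting, running, pausing, paused, resuming,
#' finishing. Events: start, started, pause, paused, resume, resumed,
#' finish, finished, stop_smooth, stop_emergency. `stop_emergency` is legal
#' from every non-stopped state and leads directly to stopped (safe-state
#' actions are the runner's responsibility); `stop_smooth` routes through
#' finishing so the current cycle can complete.
#'
#' @return Data frame with columns from, event, to.
#' @export
him_transition_table <- function() {
  tab <- rbind(
    c("stopped",   "start",         "starting"),
    c("starting",  "started",       "running"),
    c("running",   "pause",         "pausing"),
    c("pausing",   "paused",        "paused"),
    c("paused",    "resume",        "resuming"),
    c("resuming",  "resumed",       "running"),
    c("running",   "finish",        "finishing"),
    c("running",   "stop_smooth",   "finishing"),
    c("paused",    "stop_smooth",   "finishing"),
    c("finishing", "finished",      "stopped")
  )
  non_stopped <- c("starting", "running", "pausing", "paused", "resuming",
                   "finishing")
  tab <- rbind(tab, cbind(non_stopped, "stop_emergency", "stopped"))
  data.frame(from = tab[, 1], event = tab[, 2], to = tab[, 3],
             stringsAsFactors = FALSE)
}

#' Apply one event to a task state
#'
#' Table-driven; an undefined (state, event) pair is rejected and the
#' state is unchanged.
#'
#' @param state Current state.
#' @param event Event name.
#' @return List: `state` (new or unchanged), `accepted` (logical).
#' @export
him_transition <- function(state, event) {
  tab <- him_transition_table()
  if (!state %in% c(tab$from, "stopped")) stop("unknown state: ", state)
  if (!event %in% tab$event) stop("unknown event: ", event)
  hit <- tab[tab$from == state & tab$event == event, ]
  if (nrow(hit) == 0) {
    return(list(state = state, accepted = FALSE))
  }
  list(state = hit$to[1], accepted = TRUE)
}

# ---- experiment configuration ----------------------------------------------

#' Construct an experiment configuration
#'
#' @param task Task type: "him_full", "stack_only", "fluidics_only" or
#'   "cycle0_only".
#' @param sample_name Sample name stored in every metadata sidecar.
#' @param save_root Output directory root.
#' @param imaging An [imaging_settings()] object (z start supplied at run
#'   time by the focus logic).
#' @param roi_file Path to the ROI YAML list.
#' @param sequences Named list of injection-sequence YAML paths: cycle0,
#'   hybridization, bleaching.
#' @param probes Ordered list of `list(cycle =, name =, tray_slot =)`
#'   entries, one per cycle.
#' @param n_cycles Number of probe cycles (>= 0).
#' @param seed Root seed for the run.
#' @param below_offset_um Stack reference offset below focus (µm).
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(task = "him_full", sample_name, save_root,
                              imaging = imaging_settings(), roi_file,
                              sequences = list(), probes = list(),
                              n_cycles = 0, seed = 0,
                              below_offset_um = 1.5) {
  structure(list(task = task, sample_name = sample_name,
                 save_root = save_root, imaging = imaging,
                 roi_file = roi_file, sequences = sequences,
                 probes = probes, n_cycles = n_cycles, seed = seed,
                 below_offset_um = below_offset_um),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Keys: `task`, `sample_name`, `save_root`, `imaging` (exposure_ms,
#' channels, n_planes, dz_nm, format), `roi_file`, `sequences` (cycle0,
#' hybridization, bleaching), `probes` (list of cycle/name/tray_slot),
#' `n_cycles`, `seed`, `below_offset_um`.
#'
#' @param path YAML file.
#' @return An [experiment_config()].
#' @export
experiment_config_load <- function(path) {
  if (!file.exists(path)) stop("experiment config not found: ", path)
  doc <- yaml::read_yaml(path)
  img <- doc$imaging %||% list()
  imaging <- imaging_settings(
    exposure_ms = img$exposure_ms %||% 50,
    channels = img$channels %||% list(
      list(laser_nm = 561, intensity_pct = 30),
      list(laser_nm = 640, intensity_pct = 50)),
    n_planes = img$n_planes %||% 60,
    dz_nm = img$dz_nm %||% 250,
    format = img$format %||% "tiff")
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  experiment_config(
    task = doc$task %||% "him_full",
    sample_name = doc$sample_name %||% "",
    save_root = doc$save_root %||% ".",
    imaging = imaging,
    roi_file = resolve(doc$roi_file) %||% "",
    sequences = lapply(doc$sequences %||% list(), resolve),
    probes = doc$probes %||% list(),
    n_cycles = doc$n_cycles %||% 0,
    seed = doc$seed %||% 0,
    below_offset_um = doc$below_offset_um %||% 1.5)
}

#' Validate an experiment configuration
#'
#' Returns (never throws) the list of problems, each naming the offending
#' field; an empty result means the configuration is runnable.
#'
#' @param config An [experiment_config()].
#' @return Character vector of errors.
#' @export
validate_config <- function(config) {
  errors <- character(0)
  add <- function(field, msg) {
    errors <<- c(errors, sprintf("%s: %s", field, msg))
  }
  if (!config$task %in% c("him_full", "stack_only", "fluidics_only",
                          "cycle0_only")) {
    add("task", paste0("unknown task type '", config$task, "'"))
  }
  if (is.null(config$sample_name) || !nzchar(config$sample_name)) {
    add("sample_name", "missing")
  }
  if (is.null(config$n_cycles) || config$n_cycles < 0) {
    add("n_cycles", "must be >= 0")
  }
  img <- config$imaging
  if (is.null(img)) {
    add("imaging", "missing")
  } else {
    if (img$exposure_ms <= 0) add("exposure_ms", "must be > 0")
    if (img$n_planes < 1) add("n_planes", "must be >= 1")
    if (img$dz_nm <= 0) add("dz", "must be > 0 nm")
    if (length(img$channels) == 0) add("channels", "must be nonempty")
  }
  needs_imaging <- config$task %in% c("him_full", "stack_only", "cycle0_only")
  if (needs_imaging) {
    if (is.null(config$roi_file) || !nzchar(config$roi_file)) {
      add("roi_file", "missing")
    } else if (!file.exists(config$roi_file)) {
      add("roi_file", paste0("file not found: ", config$roi_file))
    }
  }
  needs_fluidics <- config$task %in% c("him_full", "fluidics_only",
                                       "cycle0_only")
  if (needs_fluidics) {
    for (k in c("cycle0", if (config$task == "him_full")
                c("hybridization", "bleaching"))) {
      p <- config$sequences[[k]]
      if (is.null(p)) {
        add(paste0("sequences$", k), "missing")
      } else if (!file.exists(p)) {
        add(paste0("sequences$", k), paste0("file not found: ", p))
      }
    }
  }
  if (config$task == "him_full") {
    if (length(config$probes) != config$n_cycles) {
      add("probes", sprintf("length %d but n_cycles = %d",
                            length(config$probes), config$n_cycles))
    }
    for (i in seq_along(config$probes)) {
      p <- config$probes[[i]]
      if (is.null(p$name) || !nzchar(p$name)) {
        add(sprintf("probes[%d]$name", i), "missing")
      } else if (grepl("_", p$name)) {
        add(sprintf("probes[%d]$name", i), "must not contain underscores")
      }
    }
  }
  if (!is.null(config$below_offset_um) &&
      (config$below_offset_um < 0.5 || config$below_offset_um > 5)) {
    add("below_offset_um", "implausible (expected about 1-2 um)")
  }
  errors
}

# ---- status tracker --------------------------------------------------------

#' Write a status snapshot atomically
#'
#' Serializes the snapshot to YAML via write-to-temp + rename, so a
#' polling consumer always sees a complete, parseable file. Failures are
#' logged (if a logger is supplied) and swallowed: status reporting must
#' never take down an experiment.
#'
#' @param snapshot Named list (timestamp_s, state, cycle, roi_id,
#'   fluidics, preanalysis, ...).
#' @param path Target file.
#' @param logger Optional [SimLogger] for failure reports.
#' @return TRUE if written, FALSE otherwise, invisibly.
#' @export
write_status <- function(snapshot, path, logger = NULL) {
  ok <- tryCatch(suppressWarnings({
    tmp <- tempfile("status_", tmpdir = dirname(path), fileext = ".yml")
    yaml::write_yaml(snapshot, tmp)
    if (!file.rename(tmp, path)) stop("rename failed")
    TRUE
  }), error = function(e) {
    if (!is.null(logger)) {
      logger$log("warning", "status",
                 paste("status write failed:", conditionMessage(e)))
    }
    FALSE
  })
  invisible(ok)
}

# ---- pre-analysis ----------------------------------------------------------

#' Real-time pre-analysis of an acquired stack
#'
#' Per-plane sharpness is the pixel variance of each plane; the best-focus
#' plane is the sharpness argmax (ties resolved to the lowest index, so a
#' uniform stack reports plane 0); the projection is the per-pixel maximum
#' over planes.
#'
#' @param stack Integer array `h x w x planes x channels` or
#'   `h x w x planes`.
#' @param channel 1-based channel to analyze (default first).
#' @return List: `best_plane` (0-based index), `sharpness` (per-plane
#'   variance trace), `mip` (max-intensity projection matrix).
#' @export
preanalyze_stack <- function(stack, channel = 1) {
  d <- dim(stack)
  if (is.null(d) || length(d) < 3 || d[3] == 0) {
    stop("preanalyze_stack: empty stack")
  }
  cube <- if (length(d) == 4) {
    x <- stack[, , , channel, drop = FALSE]
    dim(x) <- d[1:3]
    x
  } else {
    stack
  }
  n_p <- dim(cube)[3]
  sharp <- vapply(seq_len(n_p),
                  function(p) stats::var(as.numeric(cube[, , p])),
                  numeric(1))
  mip <- apply(cube, c(1, 2), max)
  list(best_plane = which.max(sharp) - 1L, sharpness = sharp, mip = mip)
}

# ---- task runner -----------------------------------------------------------

#' Multi-cycle experiment task
#'
#' Drives a complete sequential-imaging experiment against a wired setup
#' graph: cycle 0 (nuclear dye + fiducial injection, then per-ROI
#' reference stacks), then for each cycle a hybridization sequence, a
#' stack per ROI, and a chemical bleaching sequence. The task owns the
#' hardware while running (concurrent commands are rejected as busy),
#' tracks its state through the transition table, writes status snapshots,
#' and honors smooth (cycle-boundary) and emergency (immediate, lasers off,
#' pump off) stop requests as well as pause at ROI boundaries.
#'
#' Hooks (all optional, called with the task as first argument) allow a
#' supervising script to observe or interrupt the run: `after_roi(task,
#' cycle, roi_id)`, `after_cycle(task, cycle)`, `while_paused(task)`.
#'
#' @export
HimTask <- R6::R6Class("HimTask",
  public = list(
    #' @field graph The [HimGraph] to run against.
    graph = NULL,
    #' @field config The validated [experiment_config()].
    config = NULL,
    #' @field state Current task state.
    state = "stopped",
    #' @field hooks Named list of hook functions.
    hooks = NULL,
    #' @field status_path Status snapshot file (NULL disables).
    status_path = NULL,
    #' @field report Run report (populated by `run()`).
    report = NULL,

    #' @description Create a task.
    #' @param graph,config,hooks,status_path See fields.
    initialize = function(graph, config, hooks = list(),
                          status_path = NULL) {
      self$graph <- graph
      self$config <- config
      self$hooks <- hooks
      self$status_path <- status_path
      private$token <- new.env()
    },

    #' @description Request a stop.
    #' @param mode "smooth" (complete the current cycle) or "emergency"
    #'   (immediate halt, lasers and pump off).
    request_stop = function(mode = c("smooth", "emergency")) {
      mode <- match.arg(mode)
      if (self$state == "stopped") return(invisible(self)) # no-op ack
      private$stop_request <- mode
      invisible(self)
    },

    #' @description Request a pause at the next ROI boundary.
    request_pause = function() {
      if (self$state == "running") private$pause_request <- TRUE
      invisible(self)
    },

    #' @description Request resumption from a pause.
    request_resume = function() {
      private$resume_request <- TRUE
      invisible(self)
    },

    #' @description Execute the experiment; returns the run report.
    run = function() {
      cfg <- self$config
      errs <- validate_config(cfg)
      if (length(errs) > 0) {
        stop("experiment config invalid: ", paste(errs, collapse = "; "))
      }
      g <- self$graph
      g$acquire_lock(private$token)
      on.exit(g$release_lock(private$token), add = TRUE)
      private$stop_request <- NULL
      private$pause_request <- FALSE
      private$files <- character(0)
      private$status_seq <- list()
      private$fault <- NULL
      private$apply_event("start")
      private$apply_event("started")
      result <- tryCatch({
        private$run_body()
        "completed"
      }, him_emergency_stop = function(c) "emergency_stop",
         error = function(e) {
        private$fault <- conditionMessage(e)
        g$logger$log("error", "task", private$fault)
        "fault"
      })
      private$safe_state(all_off = !identical(result, "completed"))
      if (self$state != "stopped") {
        if (self$state == "running") private$apply_event("finish")
        if (self$state == "finishing") private$apply_event("finished")
        if (self$state != "stopped") self$state <- "stopped"
      }
      private$snapshot(cycle = private$last_cycle, roi_id = NA)
      self$report <- list(
        outcome = result,
        files = private$files,
        status_seq = private$status_seq,
        fault = private$fault,
        final_state = self$state,
        n_cycles_completed = private$cycles_done
      )
      self$report
    }
  ),
  private = list(
    token = NULL, stop_request = NULL, pause_request = FALSE,
    resume_request = FALSE, files = NULL, status_seq = NULL, fault = NULL,
    last_cycle = 0, cycles_done = 0, fluidics_status = NULL,
    preanalysis = NULL,

    apply_event = function(event) {
      tr <- him_transition(self$state, event)
      if (!tr$accepted) {
        stop(sprintf("illegal task event '%s' in state '%s'", event,
                     self$state))
      }
      self$state <- tr$state
      self$graph$logger$log("info", "task",
                            sprintf("state -> %s", self$state))
    },

    emergency = function() {
      private$safe_state(all_off = TRUE)
      if (self$state != "stopped") {
        tr <- him_transition(self$state, "stop_emergency")
        if (tr$accepted) self$state <- tr$state else self$state <- "stopped"
      }
      self$graph$logger$log("warning", "task", "EMERGENCY STOP")
      cond <- structure(class = c("him_emergency_stop", "condition"),
                        list(message = "emergency stop", call = NULL))
      stop(cond)
    },

    safe_state = function(all_off = TRUE) {
      if (!all_off) return(invisible(NULL))
      g <- self$graph
      for (d in g$devices) {
        if (identical(d$interface, "lasers")) d$all_off()
        if (identical(d$interface, "pump")) d$pressure_mbar <- 0
      }
      invisible(NULL)
    },

    check_interrupts = function(boundary) {
      # boundary: "roi" or "cycle"
      req <- private$stop_request
      if (identical(req, "emergency")) private$emergency()
      if (boundary == "cycle" && identical(req, "smooth")) {
        return("stop")
      }
      if (boundary == "roi" && private$pause_request &&
          self$state == "running") {
        private$pause_request <- FALSE
        private$apply_event("pause")
        private$apply_event("paused")
        private$snapshot(cycle = private$last_cycle, roi_id = NA)
        if (!is.null(self$hooks$while_paused)) self$hooks$while_paused(self)
        if (identical(private$stop_request, "emergency")) private$emergency()
        if (identical(private$stop_request, "smooth")) {
          private$apply_event("stop_smooth")
          return("stop_after_cycle")
        }
        private$resume_request <- FALSE
        private$apply_event("resume")
        private$apply_event("resumed")
      }
      "continue"
    },

    abort_poll = function() {
      function(t_s) identical(private$stop_request, "emergency")
    },

    snapshot = function(cycle, roi_id) {
      snap <- list(
        timestamp_s = self$graph$clock$now,
        state = self$state,
        cycle = cycle,
        roi_id = if (is.na(roi_id)) NULL else roi_id,
        fluidics = private$fluidics_status,
        preanalysis = private$preanalysis
      )
      private$status_seq[[length(private$status_seq) + 1L]] <- snap
      if (!is.null(self$status_path)) {
        write_status(snap, self$status_path, self$graph$logger)
      }
      invisible(snap)
    },

    run_fluidics = function(seq_path, tray = NULL, probe = NULL) {
      fl <- self$graph$logic_module("fluidics")
      seq <- sequence_load(seq_path)
      if (!is.null(probe)) {
        if (is.null(tray) || !probe %in% names(tray)) {
          stop("probe '", probe, "' absent from the delivery tray layout")
        }
      }
      rep <- fl$run_sequence(seq, tray = tray,
                             should_abort = private$abort_poll(),
                             .owner = private$token)
      last <- if (length(rep$steps) > 0) rep$steps[[length(rep$steps)]] else NULL
      private$fluidics_status <- list(
        sequence = seq$name,
        step = if (!is.null(last)) last$product else NA,
        flow_ul_min = if (!is.null(last)) last$mean_flow_ul_min else NA,
        delivered_ul = rep$total_delivered_ul)
      if (rep$fault) stop("fluidics fault during sequence '", seq$name, "'")
      if (rep$aborted && identical(private$stop_request, "emergency")) {
        private$emergency()
      }
      rep
    },

    acquire_roi = function(roi, cycle, probe) {
      g <- self$graph
      foc <- g$logic_module("focus")
      acq <- g$logic_module("acquisition")
      stage <- acq$devices$stage
      piezo <- acq$devices$piezo
      stage$move_to(roi$x_um, roi$y_um)
      stage$wait_settled()
      sp <- foc$find_focus(below_offset_um = self$config$below_offset_um,
                           .owner = private$token)
      piezo$move_to(sp$reference_z_um)
      piezo$wait_settled()
      settings <- self$config$imaging
      settings$z_start_um <- sp$reference_z_um
      plan <- plan_stack(settings, travel_um = piezo$travel_um)
      out <- acq$acquire(plan, settings, .owner = private$token)
      audit <- audit_events(out$events)
      if (!audit$ok) {
        stop("synchronization audit failed for ROI ", roi$id, ": ",
             paste(audit$problems, collapse = "; "))
      }
      cal <- foc$calibration
      md <- stack_metadata(
        sample_name = self$config$sample_name,
        stub = out$metadata_stub,
        autofocus = list(setpoint_v = sp$setpoint_v,
                         kp = focus_pid_defaults()$kp,
                         ki = focus_pid_defaults()$ki,
                         kd = focus_pid_defaults()$kd,
                         slope_v_per_um = cal$slope_v_per_um,
                         precision_nm = cal$precision_nm),
        cycle = cycle, probe = probe, roi_id = roi$id,
        seed = self$config$seed)
      files <- write_stack(out$stack, self$config$save_root, md,
                           format = settings$format)
      private$files <- c(private$files, files)
      pre <- preanalyze_stack(out$stack)
      private$preanalysis <- list(best_plane = pre$best_plane,
                                  peak_sharpness = max(pre$sharpness),
                                  roi_id = roi$id)
      private$snapshot(cycle = cycle, roi_id = roi$id)
      invisible(files)
    },

    run_body = function() {
      cfg <- self$config
      g <- self$graph
      tray <- list()
      for (p in cfg$probes) {
        if (!is.null(p$tray_slot)) tray[[p$name]] <- as.integer(p$tray_slot)
      }
      if (!dir.exists(cfg$save_root)) {
        dir.create(cfg$save_root, recursive = TRUE)
      }

      # --- cycle 0: dye + fiducial injection, calibration, reference stacks
      private$last_cycle <- 0
      if (cfg$task %in% c("him_full", "cycle0_only", "fluidics_only")) {
        g$logger$log("info", "task", "cycle 0: injection")
        private$run_fluidics(cfg$sequences$cycle0)
        private$snapshot(cycle = 0, roi_id = NA)
      }
      if (cfg$task == "fluidics_only") return(invisible(NULL))

      rois <- roi_load(cfg$roi_file)
      if (nrow(rois) == 0) stop("ROI list is empty")

      foc <- g$logic_module("focus")
      acq <- g$logic_module("acquisition")
      stage <- acq$devices$stage
      stage$move_to(rois$x_um[1], rois$y_um[1])
      stage$wait_settled()
      foc$devices$lasers$set_ir(TRUE)
      cal <- foc$calibrate(.owner = private$token)
      if (!cal$valid) {
        stop(sprintf(
          "autofocus calibration invalid (monotonic=%s, precision=%.1f nm)",
          cal$monotonic, cal$precision_nm))
      }
      foc$mark_focus(.owner = private$token)

      for (i in seq_len(nrow(rois))) {
        if (private$check_interrupts("roi") != "continue") break
        private$acquire_roi(rois[i, ], cycle = 0, probe = "DAPI")
        if (!is.null(self$hooks$after_roi)) {
          self$hooks$after_roi(self, 0, rois$id[i])
        }
      }
      if (identical(private$stop_request, "emergency")) private$emergency()

      # --- cycles 1..n: hybridization -> per-ROI stacks -> bleaching
      n_cycles <- if (cfg$task %in% c("him_full")) cfg$n_cycles else 0
      for (cycle in seq_len(n_cycles)) {
        if (private$check_interrupts("cycle") != "continue") break
        private$last_cycle <- cycle
        probe <- cfg$probes[[cycle]]$name
        g$logger$log("info", "task",
                     sprintf("cycle %d: hybridization of %s", cycle, probe))
        private$run_fluidics(cfg$sequences$hybridization, tray = tray,
                             probe = probe)
        g$sample$set_active_probe(probe)
        private$snapshot(cycle = cycle, roi_id = NA)
        roi_done <- 0
        for (i in seq_len(nrow(rois))) {
          st <- private$check_interrupts("roi")
          if (st == "stop_after_cycle") break
          private$acquire_roi(rois[i, ], cycle = cycle, probe = probe)
          roi_done <- roi_done + 1
          if (!is.null(self$hooks$after_roi)) {
            self$hooks$after_roi(self, cycle, rois$id[i])
          }
          if (identical(private$stop_request, "emergency")) {
            private$emergency()
          }
        }
        g$logger$log("info", "task", sprintf("cycle %d: bleaching", cycle))
        private$run_fluidics(cfg$sequences$bleaching)
        g$sample$set_active_probe(NA_character_)
        private$cycles_done <- cycle
        private$snapshot(cycle = cycle, roi_id = NA)
        if (!is.null(self$hooks$after_cycle)) {
          self$hooks$after_cycle(self, cycle)
        }
      }
      invisible(NULL)
    }
  )
)

#' Run a complete experiment task
#'
#' Convenience wrapper: builds a [HimTask], runs it, and returns the run
#' report (outcome, written files, status sequence, fault, final state).
#'
#' @param config An [experiment_config()] (or path to its YAML file).
#' @param graph A wired [HimGraph] from [load_setup()].
#' @param hooks Optional hook list (see [HimTask]).
#' @param status_path Optional status snapshot file.
#' @return The run report list.
#' @export
run_him_task <- function(config, graph, hooks = list(),
                         status_path = NULL) {
  if (is.character(config)) config <- experiment_config_load(config)
  task <- HimTask$new(graph, config, hooks = hooks,
                      status_path = status_path)
  task$run()
}
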