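# Injection sequences and their execution against the simulated fluidics
# plant under PID flow control with volume-triggered step advancement.

#' Default PID gains for the flow regulator
#'
#' Error in µl/min, output a pump pressure setpoint in mbar, limited to the
#' pump's working range.
#'
#' @param out_max Upper output (pressure) limit in mbar.
#' @param period_s Loop period (s); 0.1 s virtual time by default.
#' @return A [pid_params()] object.
#' @export
fluidics_pid_defaults <- function(out_max = 1000, period_s = 0.1) {
  pid_params(kp = 0.8, ki = 0.5, kd = 0, out_min = 0, out_max = out_max,
             integral_clamp = 2000, period_s = period_s)
}

#' Construct one injection step
#'
#' @param product Product name (e.g. "hybridization buffer").
#' @param valve Valve port to select (integer).
#' @param volume_ul Target volume (µl, >= 0; 0 means incubation-only step).
#' @param flow_ul_min Target flow rate (µl/min; must be > 0 if volume > 0).
#' @param incubation_s Incubation after delivery (s, >= 0).
#' @param tray_slot Optional 3-axis needle tray slot for cycle-specific
#'   probes, integer triple.
#' @return List of class `injection_step`.
#' @export
injection_step <- function(product, valve, volume_ul, flow_ul_min = 0,
                           incubation_s = 0, tray_slot = NULL) {
  structure(list(product = as.character(product),
                 valve = as.integer(valve),
                 volume_ul = as.numeric(volume_ul),
                 flow_ul_min = as.numeric(flow_ul_min),
                 incubation_s = as.numeric(incubation_s),
                 tray_slot = if (!is.null(tray_slot)) as.integer(tray_slot)),
            class = "injection_step")
}

#' Construct an injection sequence
#'
#' @param name Sequence name (e.g. "hybridization", "bleaching", "cycle0").
#' @param steps List of [injection_step()]s.
#' @return List of class `injection_sequence`.
#' @export
injection_sequence <- function(name, steps = list()) {
  if (!nzchar(name)) stop("injection sequence needs a nonempty name")
  structure(list(name = name, steps = steps), class = "injection_sequence")
}

#' Validate an injection sequence against hardware limits
#'
#' Never throws: returns a report with `errors` (each citing the step index
#' and field) and `warnings`. The sequence is executable iff `errors` is
#' empty.
#'
#' @param seq An [injection_sequence()].
#' @param n_ports Valve port count.
#' @param max_flow_ul_min Pump flow capability (µl/min).
#' @return List of class `validation_report`: errors, warnings, ok.
#' @export
validate_sequence <- function(seq, n_ports = 8, max_flow_ul_min = 2000) {
  errors <- character(0)
  warnings <- character(0)
  if (!inherits(seq, "injection_sequence")) {
    errors <- c(errors, "not an injection_sequence object")
  } else {
    if (!nzchar(seq$name %||% "")) errors <- c(errors, "name: empty")
    if (length(seq$steps) == 0) {
      warnings <- c(warnings, "sequence has no steps")
    }
    for (i in seq_along(seq$steps)) {
      s <- seq$steps[[i]]
      at <- function(field, msg) sprintf("step %d, field %s: %s", i, field, msg)
      if (is.null(s$product) || !nzchar(s$product)) {
        errors <- c(errors, at("product", "missing or empty"))
      }
      if (is.null(s$valve) || s$valve < 1 || s$valve > n_ports ||
          s$valve != round(s$valve)) {
        errors <- c(errors, at("valve",
          sprintf("must be an integer in 1..%d", n_ports)))
      }
      if (is.null(s$volume_ul) || s$volume_ul < 0) {
        errors <- c(errors, at("volume", "must be >= 0"))
      } else if (s$volume_ul > 0) {
        if (is.null(s$flow_ul_min) || s$flow_ul_min <= 0) {
          errors <- c(errors, at("flow", "must be > 0 when volume > 0"))
        } else if (s$flow_ul_min > max_flow_ul_min) {
          errors <- c(errors, at("flow",
            sprintf("exceeds pump capability of %g ul/min", max_flow_ul_min)))
        }
      }
      if (!is.null(s$incubation_s) && s$incubation_s < 0) {
        errors <- c(errors, at("incubation", "must be >= 0"))
      }
      if (!is.null(s$tray_slot) &&
          (length(s$tray_slot) != 3 || any(s$tray_slot < 0))) {
        errors <- c(errors, at("tray_slot", "must be 3 nonnegative indices"))
      }
    }
  }
  structure(list(errors = errors, warnings = warnings,
                 ok = length(errors) == 0),
            class = "validation_report")
}

#' Save an injection sequence as YAML
#'
#' Schema: top-level `name` and `steps`, each step with keys `product`,
#' `valve`, `tray_slot` (optional), `volume_ul`, `flow_ul_min`,
#' `incubation_s`.
#'
#' @param seq An [injection_sequence()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
sequence_save <- function(seq, path) {
  steps <- lapply(seq$steps, function(s) {
    e <- list(product = s$product, valve = s$valve,
              volume_ul = s$volume_ul, flow_ul_min = s$flow_ul_min,
              incubation_s = s$incubation_s)
    if (!is.null(s$tray_slot)) e$tray_slot <- as.integer(s$tray_slot)
    e
  })
  yaml::write_yaml(list(name = seq$name, steps = steps), path)
  invisible(path)
}

#' Load an injection sequence from YAML
#'
#' Missing `incubation_s` defaults to 0; missing `product`, `valve`,
#' `volume_ul` or `flow_ul_min` (for a delivering step) is rejected citing
#' the field.
#'
#' @param path YAML file.
#' @return An [injection_sequence()].
#' @export
sequence_load <- function(path) {
  if (!file.exists(path)) stop("injection sequence file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$name)) stop("injection sequence file: missing field 'name'")
  steps <- lapply(seq_along(doc$steps), function(i) {
    s <- doc$steps[[i]]
    for (k in c("product", "valve", "volume_ul")) {
      if (is.null(s[[k]])) {
        stop(sprintf("injection sequence step %d: missing field '%s'", i, k))
      }
    }
    if ((s$volume_ul %||% 0) > 0 && is.null(s$flow_ul_min)) {
      stop(sprintf("injection sequence step %d: missing field 'flow_ul_min'",
                   i))
    }
    injection_step(s$product, s$valve, s$volume_ul,
                   s$flow_ul_min %||% 0, s$incubation_s %||% 0,
                   if (!is.null(s$tray_slot)) as.integer(s$tray_slot))
  })
  injection_sequence(doc$name, steps)
}

#' Fluidics logic module
#'
#' Wired to the pump, valve, flow sensor and needle positioner. Executes
#' injection steps under PID flow control: the loop reads the flow sensor,
#' updates the pump pressure setpoint, and advances the step when the
#' integrated volume reaches the target, followed by a zero-flow
#' incubation. A step that never reaches 10% of its target flow within the
#' fault timeout is reported as a blockage fault with the pump stopped.
#'
#' @export
FluidicsLogic <- R6::R6Class("FluidicsLogic",
  public = list(
    #' @field role Role name assigned by the registry.
    role = NULL,
    #' @field devices Named list: pump, valve, flow, needle.
    devices = NULL,
    #' @field graph Owning [HimGraph].
    graph = NULL,
    #' @field fault_timeout_s Blockage fault timeout (virtual s).
    fault_timeout_s = 30,

    #' @description Wired by the registry.
    #' @param devices,graph See fields.
    initialize = function(devices, graph) {
      self$devices <- devices
      self$graph <- graph
      devices$flow$bind_pump(devices$pump)
    },

    #' @description Execute one injection step under PID flow control.
    #' @param step An [injection_step()].
    #' @param pid [pid_params()]; default [fluidics_pid_defaults()] bounded
    #'   by the pump's pressure limit.
    #' @param settle_skip_s Initial window excluded from the mean-flow
    #'   figure (controller rise time), seconds.
    #' @param should_abort Optional function `(t_s) -> logical` polled every
    #'   loop tick; TRUE stops the pump and aborts the step.
    #' @param .owner Arbiter token.
    #' @return Step report: product, delivered_ul, mean_flow_ul_min,
    #'   duration_s, incubation_s, fault, aborted.
    run_step = function(step, pid = NULL, settle_skip_s = 15,
                        should_abort = NULL, .owner = NULL) {
      self$graph$check_available(.owner)
      pump <- self$devices$pump
      flow <- self$devices$flow
      clock <- self$graph$clock
      pid <- pid %||% fluidics_pid_defaults(out_max = pump$p_max_mbar)
      log <- function(msg) {
        self$graph$logger$log("info", self$role %||% "fluidics", msg)
      }
      self$devices$valve$set_position(step$valve)
      log(sprintf("valve -> port %d (%s)", step$valve, step$product))
      if (!is.null(step$tray_slot)) {
        self$devices$needle$move_to(step$tray_slot)
        log(sprintf("needle -> slot %s",
                    paste(step$tray_slot, collapse = ",")))
      }
      t0 <- clock$now
      delivered <- 0
      mean_flow <- 0
      fault <- FALSE
      aborted <- FALSE
      if (step$volume_ul > 0) {
        pump$reset_volume()
        st <- pid_state()
        flow_sum <- 0; flow_n <- 0L
        reached_10pct <- FALSE
        repeat {
          measured <- flow$read_flow()
          if (measured >= 0.1 * step$flow_ul_min) reached_10pct <- TRUE
          if (clock$now - t0 > settle_skip_s) {
            flow_sum <- flow_sum + measured
            flow_n <- flow_n + 1L
          }
          upd <- pid_step(pid, st, step$flow_ul_min - measured,
                          pid$period_s)
          st <- upd$state
          pump$set_pressure(min(max(upd$output, 0), pump$p_max_mbar))
          clock$advance(pid$period_s)
          if (flow$read_volume() >= step$volume_ul) break
          if (!is.null(should_abort) && isTRUE(should_abort(clock$now))) {
            aborted <- TRUE
            log("abort requested: pump off")
            break
          }
          if (!reached_10pct && clock$now - t0 > self$fault_timeout_s) {
            fault <- TRUE
            log(sprintf(
              "FAULT: flow never reached 10%% of %g ul/min within %g s",
              step$flow_ul_min, self$fault_timeout_s))
            break
          }
        }
        pump$set_pressure(0)
        delivered <- flow$read_volume()
        mean_flow <- if (flow_n > 0) flow_sum / flow_n else NA_real_
      }
      duration <- clock$now - t0
      if (!fault && !aborted && step$incubation_s > 0) {
        log(sprintf("incubation %g s", step$incubation_s))
        clock$advance(step$incubation_s)
      }
      list(product = step$product, delivered_ul = delivered,
           mean_flow_ul_min = mean_flow, duration_s = duration,
           incubation_s = if (fault || aborted) 0 else step$incubation_s,
           fault = fault, aborted = aborted)
    },

    #' @description Execute an injection sequence step by step.
    #' @param seq An [injection_sequence()]; must validate cleanly.
    #' @param tray Optional named list mapping product names to tray slots;
    #'   a step whose product is listed gets its needle position from here.
    #' @param pid [pid_params()] for every step.
    #' @param should_abort Optional `(t_s) -> logical` abort poll.
    #' @param .owner Arbiter token.
    #' @return Sequence report: name, steps (list of step reports),
    #'   aborted, fault, total_delivered_ul.
    run_sequence = function(seq, tray = NULL, pid = NULL,
                            should_abort = NULL, .owner = NULL) {
      self$graph$check_available(.owner)
      rep <- validate_sequence(seq, n_ports = self$devices$valve$n_ports,
                               max_flow_ul_min = self$devices$pump$k_flow *
                                 self$devices$pump$p_max_mbar)
      if (!rep$ok) {
        stop("injection sequence '", seq$name, "' invalid: ",
             paste(rep$errors, collapse = "; "))
      }
      reports <- list()
      aborted <- FALSE
      fault <- FALSE
      for (i in seq_along(seq$steps)) {
        s <- seq$steps[[i]]
        if (is.null(s$tray_slot) && !is.null(tray) &&
            !is.null(s$product) && s$product %in% names(tray)) {
          s$tray_slot <- tray[[s$product]]
        }
        r <- self$run_step(s, pid = pid, should_abort = should_abort,
                           .owner = .owner)
        reports[[i]] <- r
        if (r$fault) { fault <- TRUE; break }
        if (r$aborted) { aborted <- TRUE; break }
        if (!is.null(should_abort) &&
            isTRUE(should_abort(self$graph$clock$now))) {
          aborted <- TRUE
          break
        }
      }
      self$devices$pump$set_pressure(0)
      list(name = seq$name, steps = reports, aborted = aborted,
           fault = fault,
           total_delivered_ul = sum(vapply(reports, `[[`, numeric(1),
                                           "delivered_ul")))
    }
  )
)
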