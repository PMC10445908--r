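# Simulated hardware devices behind abstract interfaces.
#
# Each device implements the same interface a real vendor driver would
# (camera, light source, xy stage, z piezo, autofocus sensor, valve, pump,
# flow sensor, needle positioner) but responds according to a physical
# model, observing the shared VirtualSample and elapsing on the SimClock.
# Every device draws its noise from its own RNG substream keyed by role
# name, so setups are reproducible device-by-device.

#' Base class for simulated devices
#'
#' Holds the wiring shared by all simulated hardware: role name, virtual
#' clock, the sample under the objective, and the device's private RNG
#' substream. The `interface` field names the abstract contract the device
#' implements; the registry checks it when wiring logic to hardware.
#'
#' @export
SimDevice <- R6::R6Class("SimDevice",
  public = list(
    #' @field role Role name the device was instantiated under.
    role = NULL,
    #' @field interface Abstract interface name (e.g. "camera").
    interface = NA_character_,
    #' @field clock The shared [SimClock].
    clock = NULL,
    #' @field sample The shared [VirtualSample] (if the device observes it).
    sample = NULL,

    #' @description Wire the device into a setup.
    #' @param role Role name.
    #' @param clock Shared clock.
    #' @param sample Shared sample (may be NULL for blind devices).
    #' @param seed Root seed; the device derives substream `role`.
    #' @param options Named list of model options (validated upstream).
    initialize = function(role, clock, sample = NULL, seed = 0,
                          options = list()) {
      self$role <- role
      self$clock <- clock
      self$sample <- sample
      private$rng <- rng_stream(derive_seed(seed, role))
      private$configure(options)
    }
  ),
  private = list(
    rng = NULL,
    configure = function(options) invisible(NULL)
  )
)

# ---- light sources ---------------------------------------------------------

#' Simulated laser bank
#'
#' Four visible excitation lines (405/488/561/640 nm) with intensity in
#' percent, plus the 785 nm infrared autofocus laser as an on/off switch.
#'
#' @export
SimLaserBank <- R6::R6Class("SimLaserBank", inherit = SimDevice,
  public = list(
    #' @field interface Implements "lasers".
    interface = "lasers",
    #' @field intensity Named numeric, percent per line ("405".."640").
    intensity = c("405" = 0, "488" = 0, "561" = 0, "640" = 0),
    #' @field ir_785_on Infrared autofocus laser switch.
    ir_785_on = FALSE,

    #' @description Set one line's intensity.
    #' @param line_nm One of 405, 488, 561, 640.
    #' @param percent Intensity in `[0, 100]`.
    set_intensity = function(line_nm, percent) {
      key <- as.character(line_nm)
      if (!key %in% names(self$intensity)) {
        stop("unknown laser line: ", line_nm, " nm (have ",
             paste(names(self$intensity), collapse = "/"), ")")
      }
      if (percent < 0 || percent > 100) {
        stop("laser intensity must be in [0, 100] %, got ", percent)
      }
      self$intensity[key] <- percent
      invisible(self)
    },

    #' @description Switch the 785 nm infrared laser.
    #' @param on Logical.
    set_ir = function(on) { self$ir_785_on <- isTRUE(on); invisible(self) },

    #' @description Set all visible lines to 0 and switch the IR laser off.
    all_off = function() {
      self$intensity[] <- 0
      self$ir_785_on <- FALSE
      invisible(self)
    },

    #' @description Visible lines currently at nonzero intensity.
    #' @return Numeric vector of line wavelengths (nm).
    active_lines = function() {
      as.numeric(names(self$intensity)[self$intensity > 0])
    }
  )
)

# ---- motion ----------------------------------------------------------------

#' Simulated XY sample-positioning stage
#'
#' Travel of +/- 10 000 µm per axis; a commanded move lands on the target
#' but the `settled` flag only turns true after the settle time has elapsed
#' on the virtual clock. Moving to the current position settles instantly.
#'
#' @export
SimStage <- R6::R6Class("SimStage", inherit = SimDevice,
  public = list(
    #' @field interface Implements "stage_xy".
    interface = "stage_xy",
    #' @field x_um,y_um Current position (µm).
    x_um = 0,
    #' @field y_um See `x_um`.
    y_um = 0,
    #' @field travel_um Symmetric travel limit per axis (µm).
    travel_um = 10000,
    #' @field settle_s Settle time after a move (virtual seconds).
    settle_s = 0.05,

    #' @description Command a move; rejects out-of-travel targets.
    #' @param x_um,y_um Target (µm); NULL keeps the current value.
    move_to = function(x_um = NULL, y_um = NULL) {
      tx <- if (is.null(x_um)) self$x_um else x_um
      ty <- if (is.null(y_um)) self$y_um else y_um
      if (abs(tx) > self$travel_um || abs(ty) > self$travel_um) {
        stop(sprintf(
          "stage target (%.1f, %.1f) outside travel limits [%.0f, %.0f] um",
          tx, ty, -self$travel_um, self$travel_um))
      }
      if (tx == self$x_um && ty == self$y_um) return(invisible(self))
      self$x_um <- tx
      self$y_um <- ty
      private$deadline <- self$clock$now + self$settle_s
      invisible(self)
    },

    #' @description TRUE once the settle time has elapsed since the last move.
    settled = function() self$clock$now >= private$deadline,

    #' @description Advance the clock until the stage is settled.
    wait_settled = function() {
      dt <- private$deadline - self$clock$now
      if (dt > 0) self$clock$advance(dt)
      invisible(self)
    }
  ),
  private = list(
    deadline = -Inf,
    configure = function(options) {
      if (!is.null(options$settle_s)) self$settle_s <- options$settle_s
      if (!is.null(options$travel_um)) self$travel_um <- options$travel_um
    }
  )
)

#' Simulated objective z piezo
#'
#' Travel 0-100 µm, increasing toward the sample. Same settle semantics as
#' the XY stage but with a shorter settle time suited to 250 nm steps.
#'
#' @export
SimPiezo <- R6::R6Class("SimPiezo", inherit = SimDevice,
  public = list(
    #' @field interface Implements "piezo_z".
    interface = "piezo_z",
    #' @field z_um Current axial position (µm).
    z_um = 50,
    #' @field travel_um Travel range `c(min, max)` (µm).
    travel_um = c(0, 100),
    #' @field settle_s Settle time (virtual seconds).
    settle_s = 0.02,

    #' @description Command an axial move; rejects out-of-travel targets.
    #' @param z_um Target (µm).
    move_to = function(z_um) {
      if (z_um < self$travel_um[1] || z_um > self$travel_um[2]) {
        stop(sprintf("piezo target %.3f um outside travel [%g, %g] um",
                     z_um, self$travel_um[1], self$travel_um[2]))
      }
      if (z_um == self$z_um) return(invisible(self))
      self$z_um <- z_um
      private$deadline <- self$clock$now + self$settle_s
      invisible(self)
    },

    #' @description TRUE once settled on the virtual clock.
    settled = function() self$clock$now >= private$deadline,

    #' @description Advance the clock until settled.
    wait_settled = function() {
      dt <- private$deadline - self$clock$now
      if (dt > 0) self$clock$advance(dt)
      invisible(self)
    },

    #' @description Clamp a target into the travel range.
    #' @param z_um Proposed target (µm).
    clamp = function(z_um) {
      min(max(z_um, self$travel_um[1]), self$travel_um[2])
    }
  ),
  private = list(
    deadline = -Inf,
    configure = function(options) {
      if (!is.null(options$settle_s)) self$settle_s <- options$settle_s
      if (!is.null(options$z_um)) self$z_um <- options$z_um
    }
  )
)

# ---- camera ----------------------------------------------------------------

#' Render one camera frame from the virtual sample
#'
#' Image formation: for every emitter visible under the active laser line,
#' an isotropic Gaussian spot whose width grows with defocus as
#' `sigma(dz) = sigma0 * sqrt(1 + (dz / z_R)^2)`, with
#' `dz = piezo_z - (surface_z + emitter_z)`. Expected photons per spot are
#' `brightness * exposure * intensity/100`; pixel counts are
#' `offset + gain * Poisson(photons) + Gaussian read noise`, rounded and
#' clamped to the 16-bit range.
#'
#' @param sample A [VirtualSample].
#' @param stage_x_um,stage_y_um Stage position: sample coordinates imaged at
#'   the sensor center (µm).
#' @param piezo_z_um Objective axial position (µm).
#' @param laser_nm Active excitation line (numeric, nm) or NA for none.
#' @param intensity_pct Laser intensity in percent.
#' @param settings Named list: exposure_ms, gain, width_px, height_px,
#'   read_noise, offset, pixel_size_um, sigma0_px, z_r_um.
#' @param rng Optional [rng_stream()] supplying shot/read noise.
#' @param noise If FALSE, return the noise-free expectation
#'   (offset + gain * expected photons) as a numeric matrix.
#' @return Integer matrix (height x width, row-major, pixel `[1,1]` top-left)
#'   of counts, or a numeric matrix when `noise = FALSE`.
#' @export
render_frame <- function(sample, stage_x_um, stage_y_um, piezo_z_um,
                         laser_nm, intensity_pct, settings, rng = NULL,
                         noise = TRUE) {
  if (settings$exposure_ms <= 0) stop("exposure must be > 0 ms")
  w <- settings$width_px; h <- settings$height_px
  expected <- matrix(0, nrow = h, ncol = w)
  vis <- if (is.na(laser_nm) || intensity_pct <= 0) {
    sample$emitters[0, , drop = FALSE]
  } else {
    sample$visible_emitters(laser_nm)
  }
  px <- settings$pixel_size_um
  if (nrow(vis) > 0) {
    for (i in seq_len(nrow(vis))) {
      # sensor center maps to the stage position; +x right, +y down
      cx <- (vis$x_um[i] - stage_x_um) / px + (w + 1) / 2
      cy <- (vis$y_um[i] - stage_y_um) / px + (h + 1) / 2
      dz <- piezo_z_um - (sample$surface_z_um + vis$z_um[i])
      sigma <- settings$sigma0_px * sqrt(1 + (dz / settings$z_r_um)^2)
      photons <- vis$brightness[i] * settings$exposure_ms * intensity_pct / 100
      half <- ceiling(5 * sigma)
      x_lo <- max(1, floor(cx - half)); x_hi <- min(w, ceiling(cx + half))
      y_lo <- max(1, floor(cy - half)); y_hi <- min(h, ceiling(cy + half))
      if (x_lo > x_hi || y_lo > y_hi) next
      xs <- x_lo:x_hi
      ys <- y_lo:y_hi
      gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
      gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
      spot <- photons / (2 * pi * sigma^2) * outer(gy, gx)
      expected[ys, xs] <- expected[ys, xs] + spot
    }
  }
  if (!noise) {
    return(settings$offset + settings$gain * expected)
  }
  stopifnot(!is.null(rng))
  img <- rng_draw(rng, {
    counts <- settings$offset +
      settings$gain * stats::rpois(length(expected), lambda = expected) +
      stats::rnorm(length(expected), 0, settings$read_noise)
    counts
  })
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)), nrow = h)
  img
}

#' Simulated scientific camera
#'
#' Observes the virtual sample through the current stage/piezo/laser state.
#' Exposure elapses on the virtual clock. Frames are rejected if the stage
#' or piezo has not settled, or if more than one visible laser line is on
#' (the synchronization contract the acquisition logic must uphold).
#'
#' @export
SimCamera <- R6::R6Class("SimCamera", inherit = SimDevice,
  public = list(
    #' @field interface Implements "camera".
    interface = "camera",
    #' @field settings Camera settings list (see [render_frame()]).
    settings = NULL,

    #' @description Set exposure time.
    #' @param exposure_ms Exposure in milliseconds (> 0).
    set_exposure = function(exposure_ms) {
      if (exposure_ms <= 0) stop("exposure must be > 0 ms")
      self$settings$exposure_ms <- exposure_ms
      invisible(self)
    },

    #' @description Acquire one frame.
    #' @param stage A [SimStage]; must be settled.
    #' @param piezo A [SimPiezo]; must be settled.
    #' @param lasers A [SimLaserBank]; at most one visible line on.
    #' @param noise Pass FALSE for the noise-free expectation image.
    snap = function(stage, piezo, lasers, noise = TRUE) {
      if (!stage$settled()) stop("camera trigger with unsettled stage")
      if (!piezo$settled()) stop("camera trigger with unsettled piezo")
      active <- lasers$active_lines()
      if (length(active) > 1) {
        stop("camera exposure with ", length(active),
             " visible laser lines on; at most one allowed")
      }
      line <- if (length(active) == 1) active else NA_real_
      pct <- if (length(active) == 1) {
        lasers$intensity[[as.character(line)]]
      } else 0
      img <- render_frame(self$sample, stage$x_um, stage$y_um, piezo$z_um,
                          line, pct, self$settings, rng = private$rng,
                          noise = noise)
      self$clock$advance(self$settings$exposure_ms / 1000)
      img
    }
  ),
  private = list(
    configure = function(options) {
      self$settings <- list(
        exposure_ms = 50, gain = 2, width_px = 512, height_px = 512,
        read_noise = 1.5, offset = 100, pixel_size_um = 0.1,
        sigma0_px = 1.3, z_r_um = 0.4
      )
      for (k in names(options)) self$settings[[k]] <- options[[k]]
    }
  )
)

# ---- autofocus sensor ------------------------------------------------------

#' Simulated quadrant photodiode (QPD) autofocus sensor
#'
#' Reads the reflection of the 785 nm infrared laser: near focus the signal
#' is linear in the objective-sample distance,
#' `signal = gain * (piezo_z - surface_z) + offset + noise`. The reading is
#' only valid while the IR laser is on; with the laser off the sensor
#' returns `valid = FALSE` (a value, never an error).
#'
#' @export
SimQPD <- R6::R6Class("SimQPD", inherit = SimDevice,
  public = list(
    #' @field interface Implements "qpd".
    interface = "qpd",
    #' @field gain_v_per_um Response slope (V/µm).
    gain_v_per_um = 0.5,
    #' @field offset_v Signal at zero defocus (V).
    offset_v = 0,
    #' @field noise_v Gaussian read noise RMS (V).
    noise_v = 0,

    #' @description Read the sensor.
    #' @param piezo A [SimPiezo].
    #' @param lasers A [SimLaserBank] (gates validity on `ir_785_on`).
    #' @return List: signal_v, valid, t_s.
    read = function(piezo, lasers) {
      if (!lasers$ir_785_on) {
        return(list(signal_v = NA_real_, valid = FALSE, t_s = self$clock$now))
      }
      dz <- piezo$z_um - self$sample$surface_z_um
      sig <- self$gain_v_per_um * dz + self$offset_v
      if (self$noise_v > 0) {
        sig <- sig + rng_draw(private$rng, stats::rnorm(1, 0, self$noise_v))
      }
      list(signal_v = sig, valid = TRUE, t_s = self$clock$now)
    }
  ),
  private = list(
    configure = function(options) {
      for (k in c("gain_v_per_um", "offset_v", "noise_v")) {
        if (!is.null(options[[k]])) self[[k]] <- options[[k]]
      }
    }
  )
)

# ---- fluidics --------------------------------------------------------------

#' Simulated pressure pump with first-order flow plant
#'
#' The flow responds to the pressure setpoint as a first-order system:
#' `flow -> k_flow * pressure` with time constant `tau_s`, stepped exactly
#' (exponential discretization) on every clock advance. Delivered volume is
#' the trapezoidal integral of the true (noise-free) flow trace. A blocked
#' line is modeled by `k_flow = 0`.
#'
#' @export
SimPump <- R6::R6Class("SimPump", inherit = SimDevice,
  public = list(
    #' @field interface Implements "pump".
    interface = "pump",
    #' @field k_flow Plant gain ((µl/min)/mbar).
    k_flow = 2,
    #' @field tau_s Plant time constant (s).
    tau_s = 2,
    #' @field pressure_mbar Current pressure setpoint (mbar).
    pressure_mbar = 0,
    #' @field p_max_mbar Pump pressure limit (mbar).
    p_max_mbar = 1000,
    #' @field flow_ul_min True instantaneous flow (µl/min).
    flow_ul_min = 0,
    #' @field volume_ul Trapezoidal integral of the true flow (µl).
    volume_ul = 0,

    #' @description Register the plant on the clock.
    #' @param role,clock,sample,seed,options See [SimDevice].
    initialize = function(role, clock, sample = NULL, seed = 0,
                          options = list()) {
      super$initialize(role, clock, sample, seed, options)
      clock$on_advance(function(dt) self$step(dt), name = role)
    },

    #' @description Set the pressure setpoint; rejected outside `[0, p_max]`.
    #' @param p_mbar Setpoint (mbar).
    set_pressure = function(p_mbar) {
      if (p_mbar < 0 || p_mbar > self$p_max_mbar) {
        stop(sprintf("pump pressure %.1f mbar outside limits [0, %g] mbar",
                     p_mbar, self$p_max_mbar))
      }
      self$pressure_mbar <- p_mbar
      invisible(self)
    },

    #' @description Advance the plant by `dt` seconds (exact discretization).
    #' @param dt Time step (s), > 0.
    step = function(dt) {
      if (dt < 0) stop("pump step: dt must be >= 0")
      if (dt == 0) return(invisible(self))
      target <- self$k_flow * self$pressure_mbar
      f0 <- self$flow_ul_min
      f1 <- target + (f0 - target) * exp(-dt / self$tau_s)
      self$flow_ul_min <- f1
      self$volume_ul <- self$volume_ul + (f0 + f1) / 2 * dt / 60
      invisible(self)
    },

    #' @description Zero the volume integrator (start of an injection step).
    reset_volume = function() { self$volume_ul <- 0; invisible(self) }
  ),
  private = list(
    configure = function(options) {
      for (k in c("k_flow", "tau_s", "p_max_mbar")) {
        if (!is.null(options[[k]])) self[[k]] <- options[[k]]
      }
    }
  )
)

#' Simulated flow-rate sensor
#'
#' Reports the pump's true flow plus Gaussian sensor noise, and exposes the
#' pump's integrated volume. The integrated volume tracks the true flow, not
#' the noisy readings, mirroring a thermal flow unit's onboard integrator.
#'
#' @export
SimFlowSensor <- R6::R6Class("SimFlowSensor", inherit = SimDevice,
  public = list(
    #' @field interface Implements "flow_sensor".
    interface = "flow_sensor",
    #' @field noise_ul_min Gaussian read noise RMS (µl/min).
    noise_ul_min = 1,
    #' @field pump The [SimPump] this sensor is plumbed to.
    pump = NULL,

    #' @description Attach the sensor to a pump.
    #' @param pump A [SimPump].
    bind_pump = function(pump) { self$pump <- pump; invisible(self) },

    #' @description Read the (noisy) flow rate in µl/min.
    read_flow = function() {
      stopifnot(!is.null(self$pump))
      f <- self$pump$flow_ul_min
      if (self$noise_ul_min > 0) {
        f <- f + rng_draw(private$rng, stats::rnorm(1, 0, self$noise_ul_min))
      }
      max(f, 0)
    },

    #' @description Integrated volume since the last reset (µl).
    read_volume = function() {
      stopifnot(!is.null(self$pump))
      self$pump$volume_ul
    }
  ),
  private = list(
    configure = function(options) {
      if (!is.null(options$noise_ul_min)) {
        self$noise_ul_min <- options$noise_ul_min
      }
    }
  )
)

#' Simulated modular valve positioner
#' @export
SimValve <- R6::R6Class("SimValve", inherit = SimDevice,
  public = list(
    #' @field interface Implements "valve".
    interface = "valve",
    #' @field n_ports Number of ports.
    n_ports = 8,
    #' @field position Current port (1..n_ports).
    position = 1,

    #' @description Switch to a port.
    #' @param port Integer in 1..n_ports.
    set_position = function(port) {
      if (port < 1 || port > self$n_ports || port != round(port)) {
        stop(sprintf("valve port %s outside 1..%d", format(port), self$n_ports))
      }
      self$position <- as.integer(port)
      invisible(self)
    }
  ),
  private = list(
    configure = function(options) {
      if (!is.null(options$n_ports)) self$n_ports <- options$n_ports
    }
  )
)

#' Simulated 3-axis needle positioner (probe delivery tray)
#' @export
SimNeedle <- R6::R6Class("SimNeedle", inherit = SimDevice,
  public = list(
    #' @field interface Implements "needle".
    interface = "needle",
    #' @field slot Current tray slot, integer triple.
    slot = c(0L, 0L, 0L),

    #' @description Move to a tray slot.
    #' @param slot Integer vector of length 3.
    move_to = function(slot) {
      if (length(slot) != 3 || any(slot < 0)) {
        stop("needle slot must be 3 nonnegative indices")
      }
      self$slot <- as.integer(slot)
      self$clock$advance(0.5) # travel time between tray positions
      invisible(self)
    }
  )
)

#' Simulated emission filter wheel
#' @export
SimFilterWheel <- R6::R6Class("SimFilterWheel", inherit = SimDevice,
  public = list(
    #' @field interface Implements "filter_wheel".
    interface = "filter_wheel",
    #' @field n_positions Number of filter positions.
    n_positions = 6,
    #' @field position Current position (1..n_positions).
    position = 1,

    #' @description Rotate to a filter position.
    #' @param pos Integer in 1..n_positions.
    set_position = function(pos) {
      if (pos < 1 || pos > self$n_positions) {
        stop("filter position outside 1..", self$n_positions)
      }
      self$position <- as.integer(pos)
      self$clock$advance(0.1)
      invisible(self)
    }
  ),
  private = list(
    configure = function(options) {
      if (!is.null(options$n_positions)) self$n_positions <- options$n_positions
    }
  )
)
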