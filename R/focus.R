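# Autofocus logic: calibration of the QPD response against the piezo,
# PID focus stabilization, local focus search per ROI, and definition of
# the 3D-stack reference position.

#' Default PID gains for the focus lock
#'
#' Output is a per-iteration piezo correction in nm, limited to +/- 1000 nm
#' so a spurious reading can never slew the objective across its range.
#'
#' @param period_s Loop period in seconds.
#' @return A [pid_params()] object.
#' @export
focus_pid_defaults <- function(period_s = 0.1) {
  pid_params(kp = 0.6, ki = 0.2, kd = 0, out_min = -1000, out_max = 1000,
             integral_clamp = 5000, period_s = period_s)
}

#' Construct a calibration result
#'
#' Validity rule: `valid` iff the ramp response is monotonic AND the
#' precision (RMS residual of the linear signal-vs-z fit, converted to nm
#' through the fitted slope) is below 30 nm.
#'
#' @param slope_v_per_um Fitted slope (V/µm).
#' @param offset_v Fitted intercept (V).
#' @param precision_nm RMS fit residual / |slope|, in nm.
#' @param monotonic Logical: consecutive signal differences share one sign.
#' @param ramp Data frame with columns `z_um`, `signal_v`.
#' @return List of class `CalibrationResult`.
#' @export
calibration_result <- function(slope_v_per_um, offset_v, precision_nm,
                               monotonic, ramp) {
  stopifnot(precision_nm >= 0)
  structure(list(
    slope_v_per_um = slope_v_per_um,
    offset_v = offset_v,
    precision_nm = precision_nm,
    monotonic = isTRUE(monotonic),
    valid = isTRUE(monotonic) && precision_nm < 30,
    ramp = ramp
  ), class = "CalibrationResult")
}

#' Export a calibration result as a YAML audit record
#'
#' @param cal A `CalibrationResult`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
calibration_to_yaml <- function(cal, path) {
  stopifnot(inherits(cal, "CalibrationResult"))
  yaml::write_yaml(list(
    slope_v_per_um = cal$slope_v_per_um,
    offset_v = cal$offset_v,
    precision_nm = cal$precision_nm,
    monotonic = cal$monotonic,
    valid = cal$valid,
    ramp = list(z_um = cal$ramp$z_um, signal_v = cal$ramp$signal_v)
  ), path)
  invisible(path)
}

#' Fit a calibration from a measured ramp table
#'
#' Least-squares fit of signal versus z; exposed separately so a recorded
#' ramp (e.g. re-loaded from the YAML audit file) can be re-analyzed.
#'
#' @param z_um Piezo positions (µm).
#' @param signal_v QPD signals (V).
#' @return A `CalibrationResult`.
#' @export
fit_calibration <- function(z_um, signal_v) {
  if (length(z_um) < 3) stop("calibration needs at least 3 ramp points")
  fit <- stats::lm(signal_v ~ z_um)
  slope <- unname(stats::coef(fit)[2])
  offset <- unname(stats::coef(fit)[1])
  rms_v <- sqrt(mean(stats::residuals(fit)^2))
  precision_nm <- if (slope == 0) Inf else rms_v / abs(slope) * 1000
  d <- diff(signal_v)
  monotonic <- all(d > 0) || all(d < 0)
  calibration_result(slope, offset, precision_nm, monotonic,
                     data.frame(z_um = z_um, signal_v = signal_v))
}

#' Autofocus logic module
#'
#' Wired to a QPD sensor, the z piezo and the laser bank. Holds the latest
#' calibration and focus setpoint; all motion and sensing elapse on the
#' virtual clock.
#'
#' @export
FocusLogic <- R6::R6Class("FocusLogic",
  public = list(
    #' @field role Role name assigned by the registry.
    role = NULL,
    #' @field devices Named list: qpd, piezo, lasers.
    devices = NULL,
    #' @field graph Owning [HimGraph] (command arbiter, logger).
    graph = NULL,
    #' @field calibration Latest `CalibrationResult` or NULL.
    calibration = NULL,
    #' @field setpoint Latest focus setpoint (list: setpoint_v, focal_z_um,
    #'   reference_z_um, below_offset_um) or NULL.
    setpoint = NULL,

    #' @description Wired by the registry.
    #' @param devices,graph See fields.
    initialize = function(devices, graph) {
      self$devices <- devices
      self$graph <- graph
    },

    #' @description Run the autofocus calibration ramp.
    #'
    #' Sweeps the piezo over `ramp_um` (default a quick 2 µm ramp) in
    #' `n_steps` equidistant points centered on the current position,
    #' moving upward, reading the QPD at each settled position, then
    #' returns to the start. Requires the 785 nm laser on.
    #' @param ramp_um Total ramp span (µm).
    #' @param n_steps Number of ramp points (>= 3).
    #' @param .owner Arbiter token (internal).
    #' @return A `CalibrationResult`.
    calibrate = function(ramp_um = 2, n_steps = 21, .owner = NULL) {
      self$graph$check_available(.owner)
      if (!self$devices$lasers$ir_785_on) {
        stop("autofocus calibration requires the 785 nm laser on")
      }
      if (n_steps < 3) stop("calibration needs n_steps >= 3")
      piezo <- self$devices$piezo
      z0 <- piezo$z_um
      zs <- seq(z0 - ramp_um / 2, z0 + ramp_um / 2, length.out = n_steps)
      if (zs[1] < piezo$travel_um[1] || zs[n_steps] > piezo$travel_um[2]) {
        stop("calibration ramp exceeds piezo travel")
      }
      sig <- numeric(n_steps)
      for (i in seq_len(n_steps)) {
        piezo$move_to(zs[i])
        piezo$wait_settled()
        r <- self$devices$qpd$read(piezo, self$devices$lasers)
        if (!r$valid) stop("QPD reading invalid during calibration ramp")
        sig[i] <- r$signal_v
      }
      piezo$move_to(z0)
      piezo$wait_settled()
      cal <- fit_calibration(zs, sig)
      self$calibration <- cal
      self$graph$logger$log("info", self$role %||% "focus", sprintf(
        "calibration: slope %.4f V/um, precision %.2f nm, %s",
        cal$slope_v_per_um, cal$precision_nm,
        if (cal$valid) "valid" else "INVALID"))
      cal
    },

    #' @description Store the current QPD signal as the focus setpoint.
    #' Averages a few readings to suppress sensor noise.
    #' @param n_avg Readings to average.
    #' @param .owner Arbiter token.
    #' @return The setpoint signal (V).
    mark_focus = function(n_avg = 5, .owner = NULL) {
      self$graph$check_available(.owner)
      sig <- vapply(seq_len(n_avg), function(i) {
        r <- self$devices$qpd$read(self$devices$piezo, self$devices$lasers)
        if (!r$valid) stop("cannot mark focus: QPD invalid (785 nm laser off?)")
        r$signal_v
      }, numeric(1))
      v <- mean(sig)
      self$setpoint <- list(setpoint_v = v,
                            focal_z_um = self$devices$piezo$z_um,
                            reference_z_um = NA_real_,
                            below_offset_um = NA_real_)
      v
    },

    #' @description Local focus search and stack reference definition.
    #'
    #' Iteratively drives the piezo until the QPD signal returns to the
    #' stored setpoint, then places the stack reference `below_offset_um`
    #' below the focal plane (default within the customary 1-2 µm band).
    #' @param below_offset_um Offset below focus for the stack start (µm).
    #' @param tol_nm Convergence tolerance on the focus error (nm).
    #' @param max_iter Iteration cap.
    #' @param n_avg QPD readings averaged per iteration.
    #' @param .owner Arbiter token.
    #' @return Focus setpoint list (setpoint_v, focal_z_um, reference_z_um,
    #'   below_offset_um).
    find_focus = function(below_offset_um = 1.5, tol_nm = 10, max_iter = 50,
                          n_avg = 5, .owner = NULL) {
      self$graph$check_available(.owner)
      cal <- self$calibration
      if (is.null(cal) || !cal$valid) {
        stop("focus search refused: no valid autofocus calibration")
      }
      if (is.null(self$setpoint)) {
        stop("focus search refused: no stored focus setpoint (mark_focus first)")
      }
      piezo <- self$devices$piezo
      target_v <- self$setpoint$setpoint_v
      for (iter in seq_len(max_iter)) {
        sig <- mean(vapply(seq_len(n_avg), function(i) {
          r <- self$devices$qpd$read(piezo, self$devices$lasers)
          if (!r$valid) stop("QPD invalid during focus search")
          r$signal_v
        }, numeric(1)))
        err_um <- (target_v - sig) / cal$slope_v_per_um
        if (abs(err_um) * 1000 < tol_nm) break
        piezo$move_to(piezo$clamp(piezo$z_um + err_um))
        piezo$wait_settled()
      }
      focal_z <- piezo$z_um
      ref_z <- focal_z - below_offset_um
      if (ref_z < piezo$travel_um[1] || ref_z > piezo$travel_um[2]) {
        stop(sprintf("stack reference %.2f um outside piezo travel", ref_z))
      }
      self$setpoint <- list(setpoint_v = target_v, focal_z_um = focal_z,
                            reference_z_um = ref_z,
                            below_offset_um = below_offset_um)
      self$setpoint
    },

    #' @description Closed-loop focus stabilization.
    #'
    #' Runs QPD -> PID -> piezo at the loop period on the virtual clock for
    #' `duration_s`, against the stored setpoint. The PID operates in nm;
    #' piezo targets are clamped into travel. Refuses to run without a
    #' valid calibration.
    #' @param duration_s Lock duration (virtual s).
    #' @param params [pid_params()]; default [focus_pid_defaults()].
    #' @param setpoint_v Signal setpoint; default the stored one.
    #' @param .owner Arbiter token.
    #' @return Data frame trace: t_s, error_nm, z_um.
    lock = function(duration_s, params = focus_pid_defaults(),
                    setpoint_v = NULL, .owner = NULL) {
      self$graph$check_available(.owner)
      cal <- self$calibration
      if (is.null(cal) || !cal$valid) {
        stop("focus lock refused: no valid autofocus calibration")
      }
      if (is.null(setpoint_v)) {
        if (is.null(self$setpoint)) stop("focus lock: no setpoint available")
        setpoint_v <- self$setpoint$setpoint_v
      }
      piezo <- self$devices$piezo
      n <- max(1L, floor(duration_s / params$period_s))
      st <- pid_state()
      t_out <- err_out <- z_out <- numeric(n)
      for (i in seq_len(n)) {
        r <- self$devices$qpd$read(piezo, self$devices$lasers)
        if (!r$valid) stop("focus lock: QPD invalid (785 nm laser off?)")
        err_nm <- (setpoint_v - r$signal_v) / cal$slope_v_per_um * 1000
        t_out[i] <- self$graph$clock$now
        err_out[i] <- err_nm
        z_out[i] <- piezo$z_um
        upd <- pid_step(params, st, err_nm, params$period_s)
        st <- upd$state
        piezo$move_to(piezo$clamp(piezo$z_um + upd$output / 1000))
        self$graph$clock$advance(params$period_s)
      }
      data.frame(t_s = t_out, error_nm = err_out, z_um = z_out)
    }
  )
)
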