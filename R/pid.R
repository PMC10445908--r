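# Discrete PID controller in positional form, shared by the autofocus lock
# and the fluidics flow regulator.

#' PID parameter set
#'
#' Positional-form discrete PID with output clamping and anti-windup: the
#' integral is advanced by `error * dt` only when the unclamped output lies
#' within the output limits; while the output saturates the integral is
#' frozen. The integral accumulator is additionally clamped to
#' `[-integral_clamp, integral_clamp]`.
#'
#' @param kp Proportional gain.
#' @param ki Integral gain (1/s).
#' @param kd Derivative gain (s).
#' @param out_min,out_max Output limits (ordered).
#' @param integral_clamp Magnitude bound on the integral accumulator.
#' @param period_s Nominal loop period (s, > 0).
#' @return A list of class `pid_params`.
#' @export
pid_params <- function(kp, ki = 0, kd = 0, out_min = -Inf, out_max = Inf,
                       integral_clamp = Inf, period_s = 0.1) {
  if (period_s <= 0) stop("pid_params: loop period must be > 0")
  if (out_min > out_max) stop("pid_params: output limits must be ordered")
  structure(list(kp = kp, ki = ki, kd = kd, out_min = out_min,
                 out_max = out_max, integral_clamp = integral_clamp,
                 period_s = period_s),
            class = "pid_params")
}

#' Fresh PID controller state
#'
#' @return List with zeroed integral and previous error.
#' @export
pid_state <- function() {
  list(integral = 0, prev_error = 0)
}

#' One PID update
#'
#' Computes `raw = kp * e + ki * (I + e * dt) + kd * (e - e_prev) / dt`.
#' If `raw` is within the output limits the integral advances to
#' `I + e * dt` (clamped) and the output is `raw`; otherwise the output is
#' clamped to the violated limit and the integral stays frozen.
#'
#' @param params A [pid_params()] object.
#' @param state Controller state from [pid_state()] or a previous call.
#' @param error Current error (setpoint minus measurement), in signal units.
#' @param dt Time since the previous update (s, > 0).
#' @return List with `output` (clamped correction) and `state` (updated).
#' @export
pid_step <- function(params, state, error, dt) {
  if (dt <= 0) stop("pid_step: dt must be > 0")
  i_cand <- state$integral + error * dt
  i_cand <- min(max(i_cand, -params$integral_clamp), params$integral_clamp)
  deriv <- (error - state$prev_error) / dt
  raw <- params$kp * error + params$ki * i_cand + params$kd * deriv
  if (raw < params$out_min || raw > params$out_max) {
    out <- min(max(raw, params$out_min), params$out_max)
    # anti-windup: saturated, integral frozen
    new_int <- state$integral
  } else {
    out <- raw
    new_int <- i_cand
  }
  list(output = out, state = list(integral = new_int, prev_error = error))
}
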